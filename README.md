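# ammtools

Analysis tools for the two-lane mechanism of electrogenic ammonium
transport through Amt/Mep/Rh-family transporters (bacterial AmtB,
Nitrosomonas Rh50, the human Rhesus factors). In this mechanism NH4+ is
sequestered and deprotonated at the periplasmic face; the proton then
travels along two transient water wires — a periplasmic wire (PWW, from
D160 to the twin-His motif H168/H318) and a cytoplasmic wire (CWW, from
the twin-His motif to the cytoplasm) — while neutral NH3 crosses the
hydrophobic pore in parallel, recombining to NH4+ at the cytoplasmic pH.

The package implements, as tested reusable components, the computational
chain used to characterise that mechanism:

- **Pore hydration** (`occupancy`, `countRegionWaters`,
  `wireIsContinuous`, `compareStates`): per-frame water counts in
  anchored cylindrical regions of an MD trajectory, O–O hydrogen-bond
  chain continuity, and the occupancy fraction
  φ(τ) = #frames with ≥ τ waters / #frames (per subunit, mean and max
  over subunits; τ = 3 by default).
- **Pore-pathway profiling** (`findPoreProfile`, `windowSeedPoints`):
  maximal-inscribed-sphere radius r(z) = min_i(|p − x_i| − vdW_i) along
  the channel axis by seeded simulated annealing, plus window seeding at
  fixed spacing for umbrella sampling.
- **Free energies** (`wham`, `bayesianBootstrap`, `barrier`, `pkaToDg`):
  1-D potential of mean force from umbrella windows by the weighted
  histogram analysis method with Dirichlet-weight Bayesian-bootstrap
  errors; proton-translocation profiles from per-site pKa or ΔG values
  via ΔG_i = ln(10)·R·T·(pKa_ref − pKa_i).
- **SSME electrophysiology** (`fitDecay`, `classifyTransport`, `fitMM`,
  `solventEffect`): one-phase exponential decay y = y0 + A1·e^(−x/t1)
  fitted by Levenberg–Marquardt; transport-vs-binding classification from
  the lipid-to-protein-ratio dependence of the decay rate
  (r = rate(LPR 5)/rate(LPR 10), transport iff r ≥ 1.2); Michaelis–Menten
  kinetics I = Imax·c/(Km + c) with non-saturation detection; heavy-water
  (D2O) amplitude comparisons.
- **Synthetic data** (`genToyPoreTrajectory`, `genUmbrellaSamples`,
  `genCurrentTrace`, `genMMSeries`): seeded generators with known ground
  truth for every input — Markov-chain pore hydration, Metropolis
  umbrella samples on tabulated potentials, exponential-decay current
  traces, saturating and non-saturating amplitude series.
- **Pipeline** (`runPipeline`, `defaultRunConfig`): validated YAML
  configuration, stage execution in dependency order, JSON + Markdown
  reports.

Packaged reference tables (under `inst/extdata/`): per-site
proton-translocation free energies along the AmtB water wires, and the
SSME decay-rate summary for AmtB variants and NeRh50 at LPR 10 and 5.

## Worked example

```r
library(ammtools)

## a synthetic pore trajectory whose cytoplasmic wire is occupied by >= 3
## waters with stationary probability 0.79 (the DE tautomer condition)
spec <- ToyPoreSpec(nFrames = 5000, seed = 42, tautomerLabel = "DE",
                    occupancyChain = list(
                      PWW = twoStateChain(c(0, 3), 0.10),
                      CWW = twoStateChain(c(2, 4), 0.79)))
traj <- genToyPoreTrajectory(spec)
occupancy(traj, toyPoreRegions(spec)$CWW, tau = 3)
#> WireOccupancyResult: region CWW, tautomer DE, tau = 3
#>  5000 frames x 1 subunit(s); phi mean = 0.770, max = 0.770

## proton-translocation barrier from the packaged site table
barrier(loadProtonSites())
#> $deltaG
#> [1] 18.5
#> $z
#> [1] 0.6
#> $label
#> [1] "wat8"

## transport vs binding from the LPR dependence of SSME decay rates
calls <- classifyTransport(loadDecayRateTable())
head(calls[, c("variant", "substrate", "rate_lpr10", "rate_lpr5",
               "ratio", "call")], 4)
#>   variant substrate rate_lpr10 rate_lpr5    ratio       call
#> 1 AmtB-WT       NH4       13.4      18.7 1.395522  transport
#> 2 AmtB-WT         K         NA        NA       NA no_current
#> 3   D160A       NH4       21.6      24.3 1.125000    binding
#> 4   D160A         K         NA        NA       NA no_current
```

The occupancy estimate (0.770) recovers the engineered stationary
occupancy 0.79 to within Monte-Carlo error; the proton path peaks at
18.5 kJ/mol at site wat8 just above the twin-His motif; the wild-type
NH4+ current decays 1.40× faster at LPR 5 than at LPR 10 and is
therefore called a full transport cycle, while the D160A variant
(LPR-independent decay) is called binding-only.

## Vignette

`vignettes/two-lane-analysis.Rmd` describes the models and estimators,
the choices of defaults and tolerances, what the synthetic generators do
and do not emulate, and known limitations.
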