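---
title: "Methods: pore hydration, free-energy profiles and SSME kinetics"
author: "ammtools"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: pore hydration, free-energy profiles and SSME kinetics}
  %\VignetteEncoding{UTF-8}
---

# Scope

Electrogenic ammonium transporters of the Amt/Mep/Rh family move NH4+
across the membrane by splitting it: the substrate is deprotonated near
the periplasmic binding region, the proton is relayed through two
transient water wires bridged by the conserved twin-His motif, and
neutral NH3 diffuses through the hydrophobic pore to be reprotonated at
the cytoplasmic pH. ammtools implements the quantitative analyses this
picture rests on: water-wire occupancy statistics from MD trajectories,
pore-pathway profiling and umbrella-window seeding, WHAM free-energy
reconstruction with Bayesian-bootstrap errors, proton-translocation
profiles from per-site pKa or free-energy values, and the analysis of
solid-supported membrane electrophysiology (SSME) transients. Production
molecular dynamics itself, and microscopic pKa computation, are upstream
of this package: it consumes their outputs (trajectories, pull-coordinate
series, site tables) and ships generators that emulate those outputs
with known ground truth.

# Water-wire occupancy

A wire region is the finite cylinder between the centroids of two anchor
atom selections — for the periplasmic wire (PWW) the D160 carboxylate
above and the H168 sidechain below; for the cytoplasmic wire (CWW) the
twin-His motif above and the cytoplasmic exit below. The structures of
these proteins do not define the compartment boundaries geometrically,
so the region is parameterised: radial cutoff from the anchor-to-anchor
axis (default 6.0 Å, wide enough to cover the lumen without reaching the
lipid-facing surface) and axial padding beyond the anchor planes
(default 1.0 Å). Boundaries are closed: a water exactly on the cutoff
counts. Waters are identified by residue name (HOH/SOL/TIP3/WAT) and
oxygen atom only, since hydrogen naming varies between engines; each
water is mapped to the periodic image nearest the region centroid before
testing, which is exact as long as regions never approach half the box —
true for any realistic pore.

The occupancy fraction is phi(tau) = (#frames with count >= tau) /
(#frames), per subunit, with tau = 3 waters per subunit as the default
cutoff for calling a water chain complete. Because the aggregation of
per-subunit fractions into a single number can be done several ways, the
result object reports all three: per-subunit values, their mean (used
for state-to-state comparisons), and their maximum (the "up to"
statistic for transiently hydrated wires). phi is non-increasing in tau
by construction, and this is enforced by property tests.

Chain continuity is a separate, stricter question: an undirected graph
over the region's water oxygens plus both anchor sets, with edges
between nodes at most d_link apart, must connect the anchors. d_link
defaults to 3.5 Å, the usual O–O hydrogen-bond distance heuristic;
donor–acceptor angles are deliberately not evaluated, because a
continuity criterion based on oxygen positions alone is what per-frame
water counts can support. Occupancy uses the count criterion only;
continuity is reported separately rather than folded into phi.

# Pore profiling and window seeding

The pathway finder reports, at stations spaced `step` (default 0.5 Å)
along the pore axis, the in-plane centre maximising the inscribed-sphere
radius min_i(|p − x_i| − vdW_i) over all atoms — the classic
channel-mapping construction. The optimiser is simulated annealing (200
proposals per station, geometric cooling, proposal width shrinking from
1.0 to 0.02 Å) restarted from the previous station's centre, followed by
a deterministic Nelder–Mead polish; with a fixed seed the result is
bit-reproducible. The initial temperature (0.3 in radius units) is kept
well below the cost of penetrating a wall of atoms, so the walk tracks
the channel instead of tunnelling through a single-atom wall and
escaping the structure — the failure mode of an over-hot anneal.
Stations whose maximisation is unbounded (degenerate structures, open
mouths) are capped at `maxRadius` (default 10 Å) and flagged. Van der
Waals radii come from the Bondi table with a per-element override;
solvent is stripped before profiling (flag-controlled), and a
residue-number exclusion list generalises the trick of mutating a bulky
gate residue to alanine for the profiling run only. Tests verify the
profiler against analytic cylinder and hourglass geometries and against
exhaustive 0.05 Å in-plane grid search.

Umbrella-window seeds are linear interpolations of the profile centres
at exact `spacing` intervals (default 0.5 Å, the protocol's window
spacing), endpoints included; a spacing wider than the profile collapses
to a single midpoint with a warning.

# Umbrella sampling and WHAM

Windows carry a harmonic z restraint quoted in kJ/mol/nm² (the pull-code
convention; 1 kJ/mol/nm² = 0.01 kJ/mol/Å², and this conversion is
unit-tested) and, as metadata, the in-plane flat-bottom restraint
(radius 5 Å, 400 kJ/mol/nm²) used when sampling a 3-D pore. The
flat-bottom term is constant in z, so it contributes no z-dependent bias
and is excluded from the 1-D WHAM bias; it is retained on the object so
provenance survives.

WHAM iterates the self-consistent equations on binned histograms (bin
width 0.1 Å by default; bias evaluated at bin centres) until the largest
change in the window free energies falls below `tol` (default 1e-8
kJ/mol, far below any quantity of interest), with a hard iteration cap
(1e5) whose breach is an error reporting the residual — never a silent
partial result. Bins with zero total counts are flagged NA and never
interpolated. Coverage is checked pairwise: adjacent windows (ordered by
restraint centre) must share at least one occupied bin, otherwise the
run aborts naming the gap; stray single samples in the tails are allowed
to leave isolated empty bins, which surface as NA. A periodic flag wraps
the bias distance over the grid span (or an explicit period) for
periodic coordinates. Profiles are min-anchored (min W = 0) by default;
site-style first-point anchoring is available through the barrier
operations, since both conventions are in common use.

Uncertainties come from the Bayesian bootstrap: each replicate draws
Dirichlet(1, ..., 1) weights over every window's samples, re-solves WHAM
(warm-started from the unweighted solution), re-anchors the replicate,
and the pointwise standard deviation across replicates is reported.
Re-anchoring before the sd matters: the additive constant of a PMF is
arbitrary and must not inflate the error band. One replicate yields sd
identically zero; more than 10% failed replicates is an error. The
default of 200 replicates matches the protocol the package emulates.

Two caveats the tests make explicit: the Bayesian bootstrap treats
samples as exchangeable, so autocorrelated samples (e.g. raw Metropolis
chains) understate the uncertainty unless thinned first — the coverage
test thins by the estimated autocorrelation length; and a restraint
softer than the negative curvature of a barrier top lets samples slide
off the barrier, leaving it undersampled. The synthetic protocol uses
1000 kJ/mol/nm², comfortably stiffer than the barriers it samples.

Correctness is established three ways on synthetic data: closed forms
(flat and harmonic potentials), exact Boltzmann quadrature of the
ground-truth potential binned on the same grid (double-well barrier
recovery within 1 kJ/mol at 41 windows x 8000 samples), and a
cross-implementation check against an independently written binless MBAR
estimator (convex-objective minimisation over pooled samples), which
agrees with the binned WHAM profile within 0.2 kJ/mol over all
well-sampled bins.

# Proton-translocation profiles

Per-site pKa values convert to translocation free energies by
dG_i = ln(10)·R·T·(pKa_ref − pKa_i) at T = 310 K (R = 0.0083145
kJ/mol/K); the reference site is exactly zero and swapping site and
reference negates the value. Barriers over site lists reference the
first site of the (optionally z-restricted) list, or a named site — the
convention of the packaged table, where the periplasmic bulk water wat1
is the zero. Ties at the maximum break toward smaller z. The packaged
AmtB site table spans wat1–wat8 (periplasmic wire) and wat9–wat12
(cytoplasmic wire), z relative to the H168 sidechain; its global maximum
(18.5 kJ/mol at wat8, z = 0.6 Å) sits at the periplasmic end of the
twin-His bridge while the cytoplasmic wire's maximum is 17.3 kJ/mol at
wat9. Both are reported side by side by `wireBarriers()`; the package
does not arbitrate between "global" and "per-wire" readings of the
barrier.

# SSME transient analysis

The decay model is y = y0 + A1·exp(−x/t1), with x measured from the peak
apex. The apex is the signed extremum matching the trace's dominant
polarity (currents may be negative-going depending on sensor
convention); the baseline is the median of the trailing 5% of samples,
the noise floor its standard deviation; the fit window ends where the
running-median-smoothed trace stays within twice the noise of the
baseline (noiseless traces use the full tail). Fitting is
Levenberg–Marquardt least squares; the decay rate is 1/t1, the
definition consistent with rate tables quoted in 1/s. A fitted |A1|
below twice the noise floor flags the trace as flat (no resolvable
transient) rather than reporting a spurious rate. Wald confidence
intervals for t1 use the fit covariance on the t distribution; their
~95% coverage is verified by Monte Carlo.

Transport-vs-binding classification rests on the physics of
proteoliposome recordings: a full transport cycle runs down its driving
gradient faster when more transporters are present per liposome (lower
LPR), so its current decays faster at LPR 5 than LPR 10, while a
binding-only pre-steady-state current is LPR-independent. The decision
statistic is the ratio r = rate(LPR 5)/rate(LPR 10) with threshold 1.2:
on the packaged rate table this threshold separates every
transport-competent condition (minimum ratio ≈ 1.25) from every
binding-only condition (maximum ratio ≈ 1.15) with margin on both
sides, which is why a simple ratio rule was chosen over interval-overlap
or t-test rules — those misclassify at least one condition each on the
same table. Conditions with no recorded transient propagate as
`no_current`.

Kinetics: amplitudes are normalised to the largest tested concentration
(the 200 mM pulse = 1.0 convention), then fitted to I = Imax·c/(Km + c)
by Levenberg–Marquardt on the residual function directly, with several
Km starting values because the saturated (Km → 0) and non-saturating
(Km → ∞) limits sit at opposite ends of a shallow valley. Saturation is
declared only when the fitted Km lies within the tested range and its
upper confidence bound is finite and moderate (≤ 4× the top tested
concentration); otherwise Km is reported as not measurable — the honest
call for a series that is linear over the tested range. A perfectly
interpolating fit (zero residual) gets zero standard errors rather than
a singular-matrix failure.

Solvent comparisons (D2O vs H2O) report the ratio of mean peak
amplitudes with a bootstrap percentile interval and a qualitative tag:
abolished (ratio < 0.1), unchanged (interval contains 1), reduced
otherwise. Deuteron hopping is ~30% slower per water molecule, so a
transporter whose cycle requires multi-water proton relay loses its
current in heavy water; one that translocates the ion directly does not.

# Synthetic data: what it does and does not emulate

The generators provide every input with known ground truth and byte
reproducibility under a fixed seed (the RNG state is saved and restored
around every generator, so they never perturb user randomness).

- The toy pore is a cylinder of wall pseudo-atoms (vdW 1.7 Å, so the
  accessible radius is analytic) with anchor markers at the region
  boundaries and per-region water counts evolving by a Markov chain
  (default: two-state chains with persistence 0.8, i.e. frame-to-frame
  second eigenvalue 0.8). The default conditions mirror the study's
  hydration statistics: CWW stationary occupancy 0.79 in the DE tautomer
  and 0.12 in ED; PWW 0.23 in ED; the DE-state PWW, for which no
  headline fraction is stated, defaults to 0.10 — transient occupancy
  below the CWW's, consistent with "more transiently occupied". Waters
  not currently in a region are parked in the bulk outside the radial
  cutoff so all frames share one topology. What this does not emulate:
  real water dynamics (no diffusion, no hydrogen bonds), protein
  flexibility, or correlated occupancy between regions — so passing
  tests demonstrate correct counting, thresholds and statistics, not
  force-field realism.
- Umbrella samples come from a Metropolis walk on the tabulated
  potential plus bias, with step size auto-tuned to 30–50% acceptance
  during burn-in (robust across window stiffnesses) and hard walls at
  the grid ends. Samples are therefore autocorrelated like real MD
  pull data; tests that need independence thin the chains and the
  stationary-error tests inflate the binomial standard error by the
  chain's integrated autocorrelation, sqrt((1+lambda)/(1-lambda)).
- Current traces are the exact decay model plus Gaussian noise
  (optionally with a finite rise time so apex detection is exercised);
  amplitude series are exact Michaelis–Menten or exactly linear
  (non-saturating mode). Sensor drift, capacitive artefacts and solution
  exchange kinetics are not modelled.

Default sample sizes were chosen so every estimator's statistical error
is well inside its tolerance while the whole suite runs in minutes on
one CPU: 10^4-frame trajectories for stationary-fraction recovery (3
standard errors including the autocorrelation factor), 41 windows × 8000
samples for the double-well PMF, 100 seeded repetitions for coverage
checks, replicated concentration series (24 replicates per
concentration, emulating 8 sensors × 3 measurements) for the noisy
kinetics recovery property.

# Numerical and design choices

- Units: Å, ps, kJ/mol, K internally; force constants accepted in
  kJ/mol/nm²; GRO files (nm) converted on read/write; R = 0.0083145
  kJ/mol/K; T defaults to 310 K.
- Trajectory I/O: PDB and DCD via bio3d; GRO parsed in-package
  (single- and multi-frame; no installed R package reads it). Water
  residue numbers in generated PDB stay below the four-digit resSeq
  limit.
- WHAM bins whose total count is zero are NA, flagged, never
  interpolated; the profile validity object enforces min W = 0 under
  min-anchoring.
- Barrier ties break toward smaller z everywhere.
- The degenerate single-atom "structure" profiles to the capped radius
  with the cap flagged, rather than erroring, so batch runs survive
  pathological inputs visibly.
- The pipeline stamps every run with the configuration hash and seed,
  writes each stage's numbers to that stage's `summary.json`, and the
  final report only collates those files — it computes nothing itself,
  so every reported number is traceable to a stage output.

# Limitations

- The hydration analysis is purely geometric; it cannot distinguish a
  hydrogen-bonded wire from a coincidental alignment of waters beyond
  the O–O distance criterion.
- 1-D WHAM only; no 2-D reaction coordinates and no MBAR production
  path (MBAR exists in the test suite as an independent cross-check).
- The pore profiler optimises per-station in-plane centres along a
  straight axis; strongly curved channels would need a curved-axis
  generalisation.
- SSME analysis stops at the lifetime criterion; no equivalent-circuit
  deconvolution or pre-steady-state/steady-state decomposition.
- The packaged site and rate tables are inputs to the package's
  operations, not outputs of them; recomputing them requires the
  upstream simulations and recordings.
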