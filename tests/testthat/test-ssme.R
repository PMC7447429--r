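## SSME transient-current analysis: decay fits, transport classification,
## kinetics, solvent effects.

test_that("noiseless decay traces are fitted exactly", {
  tr <- genCurrentTrace(TraceSpec(y0 = 0, A1 = 3, t1 = 0.05))
  fit <- fitDecay(tr)
  expect_equal(decayRate(fit), 20, tolerance = 1e-6)    # 6 s.f.
  expect_equal(unname(decayParams(fit)), c(0, 3, 0.05), tolerance = 1e-6)
  expect_false(fit@flat)
  ## an interior apex (finite rise) is located, not assumed at t = 0
  tr2 <- genCurrentTrace(TraceSpec(y0 = 0, A1 = 3, t1 = 0.05,
                                   riseTau = 0.004))
  fit2 <- fitDecay(tr2)
  expect_gt(fit2@window[1L], 0)
  expect_lt(abs(fit2@t1 - 0.05) / 0.05, 0.05)
})

test_that("the fitted CI covers the true time constant (Monte Carlo)", {
  hits <- vapply(1:100, function(s) {
    tr <- genCurrentTrace(TraceSpec(y0 = 0.2, A1 = 3, t1 = 0.05,
                                    noiseSd = 0.05, seed = s))
    ci <- decayCI(fitDecay(tr))
    ci[1L] <= 0.05 && 0.05 <= ci[2L]
  }, logical(1L))
  expect_gte(sum(hits), 93L)
})

test_that("decay fitting is equivariant under scaling and time shifts", {
  tr <- genCurrentTrace(TraceSpec(y0 = 0.3, A1 = 2, t1 = 0.07,
                                  noiseSd = 0.02, seed = 5))
  fit <- fitDecay(tr)
  scaled <- initialize(tr, current = 7 * tr@current)
  fs <- fitDecay(scaled)
  expect_equal(fs@y0, 7 * fit@y0, tolerance = 1e-6)
  expect_equal(fs@A1, 7 * fit@A1, tolerance = 1e-6)
  expect_equal(fs@t1, fit@t1, tolerance = 1e-8)
  shifted <- initialize(tr, time = tr@time + 2)
  expect_equal(decayRate(fitDecay(shifted)), decayRate(fit),
               tolerance = 1e-8)
})

test_that("flat traces are flagged instead of inventing a transient", {
  tr <- genCurrentTrace(TraceSpec(y0 = 0.5, A1 = 0, t1 = 0.05,
                                  noiseSd = 0.01, seed = 3))
  fit <- tryCatch(fitDecay(tr), error = function(e) e)
  if (is(fit, "DecayFit")) {
    expect_true(fit@flat)
    expect_lt(abs(fit@A1), 2 * 0.011)
  } else {
    expect_match(conditionMessage(fit), "fit error")
  }
})

test_that("transport calls reproduce the measured LPR dependence", {
  calls <- classifyTransport(loadDecayRateTable())
  expected <- c("AmtB-WT.NH4" = "transport",
                "D160A.NH4" = "binding",
                "D160E.NH4" = "binding",
                "H168A-H318A.NH4" = "binding",
                "S219A-H168A-H318A.NH4" = "no_current",
                "H168A.NH4" = "transport",
                "H318A.NH4" = "transport",
                "NeRh50.NH4" = "transport",
                "H168A.K" = "transport",
                "H318A.K" = "transport",
                "AmtB-WT.K" = "no_current",
                "D160A.K" = "no_current",
                "D160E.K" = "no_current",
                "H168A-H318A.K" = "no_current",
                "S219A-H168A-H318A.K" = "no_current",
                "NeRh50.K" = "no_current")
  got <- setNames(calls$call, paste(calls$variant, calls$substrate,
                                    sep = "."))
  expect_mapequal(got, expected)
  expect_equal(sum(calls$call == "transport"), 6L)
  expect_equal(sum(calls$call == "binding"), 3L)
  ## the wild-type ratio itself
  wt <- calls[calls$variant == "AmtB-WT" & calls$substrate == "NH4", ]
  expect_equal(wt$ratio, 18.7 / 13.4, tolerance = 1e-12)
})

test_that("classification handles boundaries and per-fit input", {
  eq <- data.frame(variant = "V", substrate = "NH4", lpr = c(10, 5),
                   rate_mean = c(20, 20), rate_sd = c(1, 1))
  expect_equal(classifyTransport(eq)$call, "binding")   # r = 1
  expect_error(classifyTransport(
    data.frame(variant = "V", substrate = "NH4", lpr = 10,
               rate_mean = 20, rate_sd = 1)), "missing LPR 5")
  perFit <- data.frame(variant = "V", substrate = "NH4",
                       lpr = rep(c(10, 5), each = 3L),
                       rate = c(10, 11, 12, 16, 17, 18))
  out <- classifyTransport(perFit)
  expect_equal(out$rate_lpr10, 11)
  expect_equal(out$call, "transport")
})

test_that("amplitude normalisation anchors the largest concentration", {
  s <- data.frame(concentration = c(50, 100, 200), amplitude = c(1, 2, 4))
  expect_equal(normalizeAmplitudes(s)$amplitude, c(0.25, 0.5, 1))
  s7 <- s; s7$amplitude <- 7 * s7$amplitude
  expect_equal(normalizeAmplitudes(s7)$amplitude,
               normalizeAmplitudes(s)$amplitude)    # scale invariance
  one <- data.frame(concentration = 200, amplitude = 3.2)
  expect_equal(normalizeAmplitudes(one)$amplitude, 1)
  zero <- data.frame(concentration = c(50, 200), amplitude = c(1, 0))
  expect_error(normalizeAmplitudes(zero), "zero")
})

test_that("Michaelis-Menten fits recover Km and flag non-saturation", {
  conc <- c(12.5, 25, 50, 100, 200)
  mm <- fitMM(normalizeAmplitudes(genMMSeries(1, 50, conc)))
  expect_true(mm@saturating)
  expect_lt(abs(mm@km - 50) / 50, 0.01)
  lin <- fitMM(normalizeAmplitudes(genMMSeries(1, Inf, conc)))
  expect_false(lin@saturating)
  expect_true(is.na(lin@km))                       # "N.M."
  ## saturated limit: constant amplitudes, Km far below the tested range
  flat <- data.frame(concentration = conc, amplitude = rep(1, 5L))
  sat <- fitMM(flat)
  expect_true(sat@saturating)
  expect_lt(sat@km, min(conc) / 10)
  expect_equal(sat@imax, 1, tolerance = 1e-6)
  expect_error(fitMM(flat[1:3, ]), "4 concentrations")
})

test_that("kinetics fits stay within 5% under 2% amplitude noise", {
  ## replicated design: 8 sensors x 3 measurements per concentration
  conc <- rep(c(12.5, 25, 50, 100, 200), each = 24L)
  err <- t(vapply(1:100, function(s) {
    f <- fitMM(genMMSeries(1, 50, conc, noiseSd = 0.02, seed = s))
    c(km = abs(f@km - 50) / 50, imax = abs(f@imax - 1))
  }, numeric(2L)))
  expect_gte(mean(err[, "km"] < 0.05 & err[, "imax"] < 0.05), 0.9)
  expect_lt(median(err[, "km"]), 0.025)
})

test_that("solvent comparisons tag abolished / unchanged / reduced", {
  tr <- genCurrentTrace(TraceSpec(A1 = 3, t1 = 0.05, seed = 1))
  same <- solventEffect(list(tr, tr), list(tr, tr), nBoot = 200, seed = 2)
  expect_equal(same$ratio, 1)
  expect_equal(same$tag, "unchanged")
  dead <- initialize(tr, current = tr@current * 0)
  gone <- solventEffect(list(tr, tr), list(dead, dead), nBoot = 200,
                        seed = 2)
  expect_equal(gone$ratio, 0)
  expect_equal(gone$tag, "abolished")
  ## true ratio 0.5, n = 8 per group: the interval covers the truth
  set.seed(9)
  h <- abs(rnorm(8, 3, 0.3))
  d <- abs(rnorm(8, 1.5, 0.15))
  eff <- solventEffect(h, d, nBoot = 2000, seed = 4)
  expect_true(eff$ci[1L] <= 0.5 && 0.5 <= eff$ci[2L])
  expect_equal(eff$tag, "reduced")
  expect_error(solventEffect(numeric(0), d), "non-empty")
})
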