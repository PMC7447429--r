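## WHAM reconstruction against closed forms and Boltzmann quadrature;
## Bayesian-bootstrap behaviour.

flatSpec <- function() PmfSpec(seq(-3, 3, length.out = 121), rep(0, 121))

test_that("a flat potential reconstructs as a constant profile", {
  wins <- genUmbrellaSamples(flatSpec(), c(-1, 1), kz = 100,
                             nSamples = 4000, burnIn = 1000, seed = 10)
  prof <- bayesianBootstrap(wins, nBoot = 50, seed = 11, binWidth = 0.2)
  ok <- is.finite(prof@W)
  central <- sum((prof@W * prof@details$counts)[ok]) /
    sum(prof@details$counts[ok])
  expect_true(all(abs(prof@W[ok] - central) <=
                  3 * prof@sd[ok] + 0.35))
})

test_that("a harmonic well is recovered within 0.5 kJ/mol RMSE", {
  z <- seq(-6, 6, length.out = 601)
  spec <- PmfSpec(z, z^2, temperature = 310)      # kappa = 2 kJ/mol/A^2
  wins <- genUmbrellaSamples(spec, seq(-4, 4, 0.5), kz = 1000,
                             nSamples = 2000, burnIn = 500, seed = 20)
  prof <- wham(wins, binWidth = 0.1)
  edges <- c(prof@z - 0.05, tail(prof@z, 1L) + 0.05)
  Wex <- exactBinnedPMF(spec, edges)
  well <- abs(prof@z) <= 3 & is.finite(prof@W)
  expect_lt(sqrt(mean((prof@W - Wex)[well]^2)), 0.5)
})

test_that("a double-well barrier is recovered within 1 kJ/mol", {
  spec <- doubleWellSpec(height = 10, a = 5, zRange = c(-7.5, 7.5))
  wins <- genUmbrellaSamples(spec, seq(-7, 7, 0.5), kz = 1000,
                             nSamples = 2000, burnIn = 500, seed = 21)
  prof <- wham(wins, binWidth = 0.1)
  edges <- c(prof@z - 0.05, tail(prof@z, 1L) + 0.05)
  Wex <- exactBinnedPMF(spec, edges)
  bEst <- barrier(prof, zRange = c(-5, 0))$deltaG
  bEx <- binnedBarrier(prof@z, Wex, c(-5, 0))
  expect_lt(abs(bEst - bEx), 1)
})

test_that("the profile is invariant to window order and grid shifts", {
  spec <- doubleWellSpec(height = 6, a = 3, zRange = c(-5, 5))
  wins <- genUmbrellaSamples(spec, seq(-4, 4, 1), kz = 500,
                             nSamples = 1500, burnIn = 400, seed = 30)
  prof <- wham(wins, binWidth = 0.1)
  perm <- wham(wins[c(5, 1, 9, 3, 7, 2, 8, 4, 6)], binWidth = 0.1)
  expect_equal(perm@W, prof@W, tolerance = 1e-6)
  shifted <- lapply(wins, function(w)
    initialize(w, center = w@center + 3, samples = w@samples + 3))
  profS <- wham(shifted, binWidth = 0.1)
  expect_equal(profS@z, prof@z + 3, tolerance = 1e-9)
  expect_equal(profS@W, prof@W, tolerance = 1e-9)
})

test_that("bootstrap sd is zero for one replicate and seed-stable", {
  wins <- genUmbrellaSamples(flatSpec(), c(-1, 1), kz = 200,
                             nSamples = 1000, burnIn = 300, seed = 40)
  p1 <- bayesianBootstrap(wins, nBoot = 1, seed = 1)
  expect_true(all(p1@sd == 0))
  p2 <- bayesianBootstrap(wins, nBoot = 20, seed = 7)
  p3 <- bayesianBootstrap(wins, nBoot = 20, seed = 7)
  expect_identical(p2@sd, p3@sd)
  p4 <- bayesianBootstrap(wins, nBoot = 20, seed = 8)
  expect_false(identical(p2@sd, p4@sd))
})

test_that("bootstrap sd shrinks as windows gain samples", {
  z <- seq(-4, 4, length.out = 401)
  spec <- PmfSpec(z, 0.5 * z^2, temperature = 310)
  med <- vapply(c(250, 500, 1000, 2000, 4000), function(n) {
    wins <- genUmbrellaSamples(spec, seq(-3, 3, 1), kz = 500,
                               nSamples = n, burnIn = 300, seed = 50 + n)
    prof <- bayesianBootstrap(wins, nBoot = 30, seed = 51, binWidth = 0.2)
    median(prof@sd[is.finite(prof@W)])
  }, numeric(1L))
  expect_true(all(diff(med) < 0))
})

test_that("non-overlapping windows raise a coverage error naming the gap", {
  spec <- PmfSpec(seq(-6, 6, length.out = 241), rep(0, 241))
  wins <- genUmbrellaSamples(spec, c(-4, 4), kz = 1e5, nSamples = 500,
                             burnIn = 200, seed = 60)
  expect_error(wham(wins, binWidth = 0.1), "do not overlap")
})

test_that("hitting the iteration cap reports the residual", {
  wins <- genUmbrellaSamples(flatSpec(), c(-1, 1), kz = 200,
                             nSamples = 500, burnIn = 200, seed = 61)
  expect_error(wham(wins, binWidth = 0.2, maxIter = 2),
               "did not converge")
})

test_that("bootstrap sd brackets the profile error at the barrier top", {
  ## scaled-down coverage check: 50 independent repetitions of a small
  ## double-well reconstruction; the error of W at the barrier-top bin
  ## should fall within 2 bootstrap sd in at least 90% of runs. The
  ## Metropolis chains are thinned before bootstrapping: the Bayesian
  ## bootstrap treats samples as exchangeable, so autocorrelated draws
  ## would understate the uncertainty.
  spec <- doubleWellSpec(height = 6, a = 3, zRange = c(-5, 5))
  thin <- function(w, by)
    initialize(w, samples = windowSamples(w)[seq(1, length(w@samples), by)])
  hits <- vapply(1:50, function(rep) {
    wins <- genUmbrellaSamples(spec, seq(-4.5, 4.5, 0.75), kz = 1000,
                               nSamples = 4000, burnIn = 300,
                               seed = 100 + rep)
    wins <- lapply(wins, thin, by = 8L)
    prof <- bayesianBootstrap(wins, nBoot = 50, seed = 200 + rep,
                              binWidth = 0.25)
    edges <- c(prof@z - 0.125, tail(prof@z, 1L) + 0.125)
    Wex <- exactBinnedPMF(spec, edges)
    i0 <- which.min(abs(prof@z))        # barrier top at z = 0
    abs(prof@W[i0] - Wex[i0]) <= 2 * prof@sd[i0]
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})
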