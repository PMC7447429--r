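## Water counting, wire continuity and occupancy statistics, checked
## against brute-force geometry, hand-built chains and the generator's
## Markov ground truth.

## a minimal trajectory with explicit water positions and two anchor
## atoms on the z axis at z = 0 (bottom) and z = zTop (top)
handBuiltFrame <- function(waterXYZ, zTop = 10) {
  n <- nrow(waterXYZ)
  topo <- data.frame(
    eleno = seq_len(n + 2L),
    elety = c(rep("O", n), "AX", "AX"),
    resid = c(rep("HOH", n), "ANC", "ANC"),
    resno = c(seq_len(n), 991L, 992L),
    chain = "A", elesy = c(rep("O", n), "X", "X"),
    stringsAsFactors = FALSE)
  xyz <- rbind(waterXYZ, c(0, 0, zTop), c(0, 0, 0))
  new("Trajectory", topology = topo,
      xyz = matrix(as.numeric(t(xyz)), nrow = 1L),
      time = 0, box = matrix(0, 1L, 3L))
}

handRegion <- function(radialCutoff = 6, zPad = 1) {
  WireRegion("test", anchorTop = list(resno = 991L),
             anchorBottom = list(resno = 992L),
             radialCutoff = radialCutoff, zPad = zPad)
}

test_that("an empty region counts zero waters and is not continuous", {
  tr <- handBuiltFrame(matrix(numeric(0), 0L, 3L))
  expect_equal(unname(countRegionWaters(tr, handRegion())), 0L)
  expect_false(wireIsContinuous(tr, handRegion(), dLink = 3.5))
})

test_that("region counting respects closed boundaries", {
  ## one water exactly on the radial cutoff, one just outside, one at the
  ## padded z boundary
  w <- rbind(c(6, 0, 5), c(6.01, 0, 5), c(0, 0, 11.0), c(0, 0, 11.6))
  tr <- handBuiltFrame(w)
  expect_equal(unname(countRegionWaters(tr, handRegion(6, 1))), 2L)
})

test_that("counts agree with brute force on every frame of a toy run", {
  spec <- ToyPoreSpec(nFrames = 50, seed = 31,
                      occupancyChain = list(
                        PWW = twoStateChain(c(1, 3), 0.4),
                        CWW = twoStateChain(c(2, 4), 0.7)))
  tr <- genToyPoreTrajectory(spec)
  regs <- toyPoreRegions(spec)
  for (nm in c("PWW", "CWW")) {
    pkg <- vapply(1:50, function(f)
      countRegionWaters(tr, regs[[nm]], f)[[1L]], integer(1L))
    bf <- vapply(1:50, function(f)
      bruteForceRegionCount(tr, spec, nm, f), integer(1L))
    expect_identical(pkg, bf)
    expect_identical(pkg, as.integer(tr@metadata$counts[[paste0("1.", nm)]]))
  }
})

test_that("wire continuity matches a breadth-first-search oracle", {
  ## 4 waters spaced 2.8 A bridging anchors 14 A apart
  chain <- cbind(0, 0, c(2.8, 5.6, 8.4, 11.2))
  tr <- handBuiltFrame(chain, zTop = 14)
  reg <- handRegion()
  expect_true(wireIsContinuous(tr, reg, dLink = 3.5))
  ## oracle: explicit distance matrix over anchors + waters
  pts <- rbind(c(0, 0, 14), c(0, 0, 0), chain)
  D <- as.matrix(dist(pts))
  expect_true(bfsConnected(D, 1L, 2L, 3.5))
  ## removing the middle water leaves a 5.6 A gap
  broken <- chain[-2L, , drop = FALSE]
  tr2 <- handBuiltFrame(broken, zTop = 14)
  expect_false(wireIsContinuous(tr2, reg, dLink = 3.5))
  D2 <- as.matrix(dist(rbind(c(0, 0, 14), c(0, 0, 0), broken)))
  expect_false(bfsConnected(D2, 1L, 2L, 3.5))
})

test_that("continuity across separated anchors implies waters present", {
  ## anchors 14 A apart with dLink 3.5: an empty region cannot connect
  for (k in 0:3) {
    w <- if (k == 0L) matrix(numeric(0), 0L, 3L)
         else cbind(0, 0, seq(2.8, by = 2.8, length.out = k))
    tr <- handBuiltFrame(w, zTop = 14)
    if (wireIsContinuous(tr, handRegion(), dLink = 3.5))
      expect_gte(k, 1L)
  }
  expect_true(TRUE)  # property loop above is the assertion
})

test_that("occupancy handles threshold extremes and empty input", {
  spec <- ToyPoreSpec(nFrames = 30, seed = 2,
                      occupancyChain = list(PWW = fixedChain(0),
                                            CWW = fixedChain(4)))
  tr <- genToyPoreTrajectory(spec)
  reg <- toyPoreRegions(spec)$CWW
  expect_equal(occupancyFraction(occupancy(tr, reg, tau = 3)), 1.0)
  expect_equal(occupancyFraction(occupancy(tr, reg, tau = 0)), 1.0)
  expect_equal(occupancyFraction(occupancy(tr, toyPoreRegions(spec)$PWW,
                                           tau = 0)), 1.0)
  expect_error(occupancy(tr, reg, tau = -1), "tau")
})

test_that("occupancy recovers an engineered stationary fraction", {
  spec <- ToyPoreSpec(nFrames = 4000, seed = 77,
                      occupancyChain = list(
                        PWW = fixedChain(0),
                        CWW = twoStateChain(c(2, 3), 0.3)))
  tr <- genToyPoreTrajectory(spec)
  occ <- occupancy(tr, toyPoreRegions(spec)$CWW, tau = 3)
  expect_lt(abs(occupancyFraction(occ) - 0.3), 3 * markovSE(0.3, 4000, 0.8))
})

test_that("phi(tau) is non-increasing in tau (property over random runs)", {
  set.seed(404)
  for (i in 1:100) {
    counts <- matrix(sample(0:6, 60, replace = TRUE), ncol = 3L)
    res <- new("WireOccupancyResult", counts = counts, region = "CWW",
               tautomer = "DE", threshold = 0,
               phi = colMeans(counts >= 0), phiMean = 1, phiMax = 1,
               time = seq_len(nrow(counts)))
    phis <- vapply(0:7, function(tau)
      occupancyFraction(rethreshold(res, tau)), numeric(1L))
    expect_true(all(diff(phis) <= 1e-12))
  }
})

test_that("state comparison orders DE above ED and sees zero self-diff", {
  mk <- function(p, tautomer, region, seed) {
    spec <- ToyPoreSpec(nFrames = 800, seed = seed,
                        tautomerLabel = tautomer,
                        occupancyChain = list(
                          PWW = fixedChain(0),
                          CWW = twoStateChain(c(2, 4), p)))
    occupancy(genToyPoreTrajectory(spec),
              toyPoreRegions(spec)[[region]], tau = 3)
  }
  de <- mk(0.8, "DE", "CWW", 51)
  ed <- mk(0.1, "ED", "CWW", 52)
  tab <- compareStates(list(de, ed))
  expect_equal(nrow(tab), 2L)
  expect_gt(tab$phiMean[tab$tautomer == "DE"],
            tab$phiMean[tab$tautomer == "ED"])
  expect_equal(attr(tab, "contrast")$phiMeanDiff,
               de@phiMean - ed@phiMean)
  ## identical inputs in both groups -> zero difference
  ed2 <- initialize(de, tautomer = "ED")
  tab2 <- compareStates(list(de, ed2))
  expect_equal(attr(tab2, "contrast")$phiMeanDiff, 0)
  ## single-result groups echo their inputs
  tab3 <- compareStates(list(de))
  expect_equal(tab3$phiMean, de@phiMean)
  expect_error(compareStates(list()), "empty")
})
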