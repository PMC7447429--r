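## Pore profiler: analytic geometries, exhaustive grid-search agreement,
## rigid-motion invariance, determinism, window seeding.

test_that("an ideal cylinder profiles at its analytic radius", {
  cyl <- cylinderStructure(radius = 2, length = 20)
  prof <- findPoreProfile(cyl, zRange = c(1, 19), step = 1, seed = 5)
  st <- poreStations(prof)
  expect_lt(max(abs(st$radius - 2)), 0.05)
  expect_lt(max(abs(c(st$x, st$y))), 0.05)
  expect_false(any(st$capped))
})

test_that("an hourglass profiles its waist radius at the waist z", {
  hg <- hourglassStructure(waistRadius = 1, mouthRadius = 3, length = 20)
  prof <- findPoreProfile(hg, zRange = c(2, 18), step = 0.5, seed = 5)
  st <- poreStations(prof)
  expect_lt(abs(min(st$radius) - 1), 0.05)
  expect_lt(abs(st$z[which.min(st$radius)] - 10), 0.5 + 1e-9)
})

test_that("annealing matches exhaustive in-plane grid search", {
  hg <- hourglassStructure(waistRadius = 1, mouthRadius = 3, length = 20)
  prof <- findPoreProfile(hg, zRange = c(6, 14), step = 1, seed = 9)
  st <- poreStations(prof)
  coords <- frameCoords(hg)
  radii <- rep(1.7, nrow(coords))
  for (z in c(6, 10, 13)) {
    gs <- gridSearchRadius(coords, radii, z, c(-2, 2), c(-2, 2))
    expect_lt(abs(st$radius[st$z == z] - gs$radius), 0.1)
  }
})

test_that("profiles are invariant under rigid rotation and translation", {
  cyl <- cylinderStructure(radius = 2, length = 20)
  prof <- findPoreProfile(cyl, zRange = c(2, 18), step = 2, seed = 5)
  th <- 0.6
  Rx <- matrix(c(1, 0, 0,
                 0, cos(th), -sin(th),
                 0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  co <- sweep(frameCoords(cyl) %*% t(Rx), 2L, c(3, -4, 7), `+`)
  rot <- new("Trajectory", topology = topology(cyl),
             xyz = matrix(as.numeric(t(co)), 1L), time = 0,
             box = matrix(0, 1L, 3L))
  prot <- findPoreProfile(rot, axis = Rx %*% c(0, 0, 1),
                          zRange = NULL, step = 2, seed = 5)
  expect_lt(abs(mean(poreStations(prot)$radius) -
                mean(poreStations(prof)$radius)), 0.05)
  expect_lt(max(poreStations(prot)$radius) - min(poreStations(prot)$radius),
            0.1)
})

test_that("profiling is bit-identical under one seed", {
  cyl <- cylinderStructure(radius = 2, length = 12)
  p1 <- findPoreProfile(cyl, zRange = c(2, 10), step = 1, seed = 33)
  p2 <- findPoreProfile(cyl, zRange = c(2, 10), step = 1, seed = 33)
  expect_identical(poreStations(p1), poreStations(p2))
})

test_that("a single-atom structure is capped at maxRadius and flagged", {
  topo <- data.frame(eleno = 1L, elety = "C", resid = "XXX", resno = 1L,
                     chain = "A", elesy = "C", stringsAsFactors = FALSE)
  single <- new("Trajectory", topology = topo,
                xyz = matrix(c(0, 0, 5), 1L), time = 0,
                box = matrix(0, 1L, 3L))
  prof <- findPoreProfile(single, zRange = c(5, 6), step = 1, seed = 1)
  st <- poreStations(prof)
  expect_true(all(st$capped))
  expect_equal(st$radius, c(10, 10))
})

test_that("solvent stripping and residue exclusion widen the pore", {
  spec <- ToyPoreSpec(nFrames = 1, seed = 4,
                      occupancyChain = list(PWW = fixedChain(3),
                                            CWW = fixedChain(3)))
  tr <- genToyPoreTrajectory(spec)
  ## the toy pore's on-axis anchor markers (resno 1-4) are excluded the
  ## same way a blocking gate residue would be
  withSolv <- findPoreProfile(tr, zRange = c(4, 10), step = 2, seed = 1,
                              stripSolvent = FALSE, excludeResno = 1:4)
  stripped <- findPoreProfile(tr, zRange = c(4, 10), step = 2, seed = 1,
                              stripSolvent = TRUE, excludeResno = 1:4)
  expect_gte(min(poreStations(stripped)$radius) + 1e-9,
             min(poreStations(withSolv)$radius))
  expect_lt(max(abs(poreStations(stripped)$radius - spec@poreRadius)), 0.05)
  ## a bulky gate ring narrows the waist; excluding its residue number
  ## for the run restores the open pore (the gate-to-alanine trick)
  cyl <- cylinderStructure(radius = 2, length = 20)
  nR <- 24L
  th <- seq(0, 2 * pi, length.out = nR + 1L)[-(nR + 1L)]
  ring <- cbind((1 + 1.7) * cos(th), (1 + 1.7) * sin(th), 10)
  topo <- rbind(topology(cyl),
                data.frame(eleno = nrow(topology(cyl)) + seq_len(nR),
                           elety = "C", resid = "GAT", resno = 9999L,
                           chain = "W", elesy = "C"))
  gated <- new("Trajectory", topology = topo,
               xyz = cbind(cyl@xyz, matrix(as.numeric(t(ring)), 1L)),
               time = 0, box = matrix(0, 1L, 3L))
  blocked <- findPoreProfile(gated, zRange = c(8, 12), step = 1, seed = 2)
  expect_lt(abs(min(poreStations(blocked)$radius) - 1), 0.05)
  open <- findPoreProfile(gated, zRange = c(8, 12), step = 1, seed = 2,
                          excludeResno = 9999L)
  expect_lt(max(abs(poreStations(open)$radius - 2)), 0.05)
})

test_that("window seed points span the profile at exact spacing", {
  st <- data.frame(z = c(0, 1), x = c(0, 0), y = c(0, 0),
                   radius = c(2, 2), capped = FALSE)
  prof <- new("PoreProfile", stations = st, axis = c(0, 0, 1), step = 1)
  expect_equal(windowSeedPoints(prof, 0.5)$z, c(0, 0.5, 1))
  ## the span used for the proton-pathway windows: [-14, 6] at 0.5 A
  st2 <- data.frame(z = c(-14, 6), x = c(0.5, 0.5), y = c(-1, -1),
                    radius = 2, capped = FALSE)
  prof2 <- new("PoreProfile", stations = st2, axis = c(0, 0, 1), step = 20)
  seeds <- windowSeedPoints(prof2, 0.5)
  expect_equal(nrow(seeds), 41L)
  expect_equal(seeds$x, rep(0.5, 41L))   # straight axis -> constant x, y
  expect_equal(seeds$y, rep(-1, 41L))
  expect_warning(mid <- windowSeedPoints(prof, 5), "midpoint")
  expect_equal(mid$z, 0.5)
})
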