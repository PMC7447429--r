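## Synthetic-data generators. Every input the pipeline consumes can be
## produced here with known ground truth and full seed determinism, so all
## downstream stages are testable without external trajectory or
## electrophysiology data.

#' ToyPoreSpec: specification of a synthetic pore trajectory
#'
#' Describes a cylindrical toy pore whose walls are pseudo-atoms on a
#' cylindrical lattice and whose per-region water counts evolve by a
#' Markov chain, emulating the transiently hydrated periplasmic and
#' cytoplasmic water-wire compartments of an ammonium transporter.
#'
#' @slot poreLength pore length along z (Angstrom).
#' @slot poreRadius accessible (inscribed) pore radius (Angstrom); wall
#'   pseudo-atom centres sit at poreRadius + 1.7 so that the analytic
#'   inscribed radius after van der Waals subtraction equals poreRadius.
#' @slot wallSpacing lattice spacing of wall pseudo-atoms (Angstrom).
#' @slot regionBounds named list of z-intervals (Angstrom) for the
#'   periplasmic-like and cytoplasmic-like compartments.
#' @slot occupancyChain named list (same names) of Markov chains: each a
#'   list with integer \code{states} (water counts) and transition matrix
#'   \code{P} (rows sum to 1 within 1e-12), one step per frame.
#' @slot tautomerLabel "DE" or "ED" twin-His protonation tag.
#' @slot nFrames number of frames.
#' @slot frameStrideTime time between frames (ps).
#' @slot nSubunits number of independent pore copies (subunits/chains).
#' @slot seed RNG seed.
#' @exportClass ToyPoreSpec
setClass("ToyPoreSpec",
  representation(poreLength = "numeric", poreRadius = "numeric",
                 wallSpacing = "numeric", regionBounds = "list",
                 occupancyChain = "list", tautomerLabel = "character",
                 nFrames = "numeric", frameStrideTime = "numeric",
                 nSubunits = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    for (fld in c("poreLength", "poreRadius", "wallSpacing",
                  "frameStrideTime"))
      if (slot(object, fld) <= 0 || !is.finite(slot(object, fld)))
        msg <- c(msg, sprintf("field '%s' must be a positive distance", fld))
    if (object@nFrames < 1) msg <- c(msg, "field 'nFrames' must be >= 1")
    if (object@nSubunits < 1) msg <- c(msg, "field 'nSubunits' must be >= 1")
    if (!object@tautomerLabel %in% c("DE", "ED"))
      msg <- c(msg, "field 'tautomerLabel' must be \"DE\" or \"ED\"")
    if (is.null(names(object@regionBounds)) ||
        !identical(sort(names(object@regionBounds)),
                   sort(names(object@occupancyChain))))
      msg <- c(msg, paste("fields 'regionBounds' and 'occupancyChain' must",
                          "be named lists with matching names"))
    for (nm in names(object@regionBounds)) {
      b <- object@regionBounds[[nm]]
      if (length(b) != 2L || b[1] >= b[2] || b[1] < 0 ||
          b[2] > object@poreLength)
        msg <- c(msg, sprintf(
          "field 'regionBounds[%s]' must be an increasing interval inside [0, poreLength]",
          nm))
      ch <- object@occupancyChain[[nm]]
      if (!is.list(ch) || is.null(ch$states) || is.null(ch$P))
        msg <- c(msg, sprintf(
          "field 'occupancyChain[%s]' must be a list(states, P)", nm))
      else {
        P <- ch$P
        if (!is.matrix(P) || nrow(P) != ncol(P) ||
            nrow(P) != length(ch$states))
          msg <- c(msg, sprintf(
            "field 'occupancyChain[%s]' transition matrix does not match states",
            nm))
        else if (any(abs(rowSums(P) - 1) > 1e-12) || any(P < 0))
          msg <- c(msg, sprintf(
            "field 'occupancyChain[%s]' rows must be probabilities summing to 1 (tol 1e-12)",
            nm))
        if (any(ch$states < 0) || any(ch$states != floor(ch$states)))
          msg <- c(msg, sprintf(
            "field 'occupancyChain[%s]' states must be non-negative integers",
            nm))
      }
    }
    if (length(msg)) msg else TRUE
  })

## van der Waals radius given to every wall pseudo-atom; fixed so the
## inscribed radius of the toy cylinder is analytic
.WALL_VDW <- 1.7

#' Construct a ToyPoreSpec
#'
#' @param poreLength,poreRadius,wallSpacing cylinder geometry (Angstrom).
#' @param regionBounds named list of z-intervals for the water-wire
#'   compartments (defaults: a periplasmic-like "PWW" and a
#'   cytoplasmic-like "CWW").
#' @param occupancyChain named list of Markov chains (\code{states},
#'   \code{P}); see \code{\link{twoStateChain}}.
#' @param tautomerLabel "DE" or "ED".
#' @param nFrames,frameStrideTime,nSubunits,seed see class slots.
#' @return a validated \linkS4class{ToyPoreSpec}.
#' @export
ToyPoreSpec <- function(poreLength = 30, poreRadius = 4, wallSpacing = 2,
                        regionBounds = list(PWW = c(18, 28),
                                            CWW = c(2, 12)),
                        occupancyChain = list(
                          PWW = twoStateChain(c(0, 3), 0.10),
                          CWW = twoStateChain(c(2, 4), 0.79)),
                        tautomerLabel = "DE", nFrames = 1000,
                        frameStrideTime = 100, nSubunits = 1, seed = 1) {
  new("ToyPoreSpec", poreLength = poreLength, poreRadius = poreRadius,
      wallSpacing = wallSpacing, regionBounds = regionBounds,
      occupancyChain = occupancyChain, tautomerLabel = tautomerLabel,
      nFrames = nFrames, frameStrideTime = frameStrideTime,
      nSubunits = nSubunits, seed = seed)
}

#' Two-state Markov chain on water counts with a given stationary split
#'
#' Builds the transition matrix of a two-state chain over counts
#' \code{states = c(low, high)} whose stationary probability of the high
#' state is \code{pHigh}. \code{persistence} sets the second eigenvalue
#' (frame-to-frame memory): transition rates are
#' \code{a = (1 - persistence) * pHigh}, \code{b = (1 - persistence) *
#' (1 - pHigh)}, so higher persistence means slower mixing.
#'
#' @param states two non-negative integer water counts.
#' @param pHigh stationary probability of \code{states[2]}.
#' @param persistence second eigenvalue of the chain, in [0, 1).
#' @return list(states, P) usable in \code{\link{ToyPoreSpec}}.
#' @export
twoStateChain <- function(states = c(2, 4), pHigh = 0.5, persistence = 0.8) {
  stopifnot(length(states) == 2L, pHigh >= 0, pHigh <= 1,
            persistence >= 0, persistence < 1)
  a <- (1 - persistence) * pHigh        # low -> high
  b <- (1 - persistence) * (1 - pHigh)  # high -> low
  P <- matrix(c(1 - a, a, b, 1 - b), nrow = 2L, byrow = TRUE)
  list(states = as.integer(states), P = P)
}

#' Degenerate one-state chain (fixed water count)
#' @param state the fixed count.
#' @return list(states, P).
#' @export
fixedChain <- function(state) {
  list(states = as.integer(state), P = matrix(1, 1L, 1L))
}

## simulate a state-index path of length n, starting from state index 1
.simulateChain <- function(chain, n) {
  k <- length(chain$states)
  idx <- integer(n)
  s <- 1L
  if (k == 1L) return(rep(1L, n))
  cumP <- t(apply(chain$P, 1L, cumsum))
  u <- runif(n)
  for (i in seq_len(n)) {
    s <- which(u[i] <= cumP[s, ])[1L]
    idx[i] <- s
  }
  idx
}

#' Generate a toy pore trajectory with Markov-chain water occupancy
#'
#' Builds a trajectory whose wall pseudo-atoms form a cylinder (vdW radius
#' 1.7 A, so the inscribed pore radius is analytic), whose anchor
#' pseudo-atoms mark each region's top and bottom planes, and whose
#' per-region water counts evolve by the specified Markov chain. Waters
#' currently "in" a region are placed uniformly inside the region cylinder;
#' the remaining water slots are parked radially outside the pore (bulk),
#' so every frame shares one topology. Identical seeds reproduce identical
#' trajectories bit-for-bit.
#'
#' @param spec a \linkS4class{ToyPoreSpec}.
#' @return a \linkS4class{Trajectory}; metadata carries the spec (ground
#'   truth) and the tautomer label. Use \code{\link{toyPoreRegions}} for
#'   matching \linkS4class{WireRegion} definitions.
#' @export
genToyPoreTrajectory <- function(spec) {
  stopifnot(is(spec, "ToyPoreSpec"))
  validObject(spec)
  L <- spec@poreLength
  Rwall <- spec@poreRadius + .WALL_VDW
  nSub <- as.integer(spec@nSubunits)
  nF <- as.integer(spec@nFrames)
  offset <- 2 * (Rwall + 6) + 8     # subunit-to-subunit x spacing
  regions <- names(spec@regionBounds)

  ## wall lattice for one subunit
  zRings <- seq(0, L, by = spec@wallSpacing)
  nPer <- max(6L, ceiling(2 * pi * Rwall / spec@wallSpacing))
  theta <- seq(0, 2 * pi, length.out = nPer + 1L)[-(nPer + 1L)]
  wall1 <- cbind(x = rep(Rwall * cos(theta), length(zRings)),
                 y = rep(Rwall * sin(theta), length(zRings)),
                 z = rep(zRings, each = nPer))

  topo <- list(); static <- list()
  waterSlot <- list()  # per subunit/region: atom indices of water slots
  atomCount <- 0L
  addAtoms <- function(n, elety, resid, resno, chain, elesy) {
    data.frame(eleno = atomCount + seq_len(n), elety = elety, resid = resid,
               resno = resno, chain = chain, elesy = elesy,
               stringsAsFactors = FALSE)
  }
  for (su in seq_len(nSub)) {
    ch <- LETTERS[su]
    dx <- (su - 1L) * offset
    ## walls
    topo[[length(topo) + 1L]] <-
      addAtoms(nrow(wall1), "C", "WAL", seq_len(nrow(wall1)) + 1000L, "W", "C")
    atomCount <- atomCount + nrow(wall1)
    static[[length(static) + 1L]] <- sweep(wall1, 2L, c(-dx, 0, 0))
    ## anchors: one atom on the axis at each region boundary plane
    for (j in seq_along(regions)) {
      b <- spec@regionBounds[[j]]
      topo[[length(topo) + 1L]] <-
        addAtoms(2L, "AX", "ANC", c(2L * j - 1L, 2L * j), ch, "X")
      atomCount <- atomCount + 2L
      static[[length(static) + 1L]] <-
        cbind(x = c(dx, dx), y = c(0, 0), z = c(b[2], b[1]))  # top, bottom
    }
    ## water slots (maximum count per region)
    for (j in seq_along(regions)) {
      nmax <- max(spec@occupancyChain[[j]]$states)
      if (nmax > 0L) {
        ## resno kept under 9999: PDB resSeq is a four-digit field
        topo[[length(topo) + 1L]] <-
          addAtoms(nmax, "O", "HOH", seq_len(nmax) + 2000L * j, ch, "O")
        waterSlot[[paste(su, regions[j], sep = ".")]] <-
          atomCount + seq_len(nmax)
        atomCount <- atomCount + nmax
        static[[length(static) + 1L]] <-
          matrix(NA_real_, nmax, 3L)  # filled per frame
      }
    }
  }
  topo <- do.call(rbind, topo)
  topo$eleno <- seq_len(nrow(topo))
  base <- do.call(rbind, static)

  xyz <- matrix(NA_real_, nF, 3L * nrow(topo))
  counts <- list()
  withSeed(spec@seed, {
    for (su in seq_len(nSub)) {
      dx <- (su - 1L) * offset
      for (j in seq_along(regions)) {
        chain <- spec@occupancyChain[[j]]
        key <- paste(su, regions[j], sep = ".")
        path <- chain$states[.simulateChain(chain, nF)]
        counts[[key]] <- path
        slots <- waterSlot[[key]]
        if (is.null(slots)) next
        b <- spec@regionBounds[[j]]
        nmax <- length(slots)
        park <- cbind(dx + Rwall + 6, 0, mean(b))  # bulk, outside the pore
        for (f in seq_len(nF)) {
          k <- path[f]
          pos <- matrix(rep(park, each = nmax), nmax, 3L)
          if (k > 0L) {
            r <- spec@poreRadius * sqrt(runif(k))
            th <- runif(k, 0, 2 * pi)
            pos[seq_len(k), ] <- cbind(dx + r * cos(th), r * sin(th),
                                       runif(k, b[1], b[2]))
          }
          cols <- rep((slots - 1L) * 3L, each = 3L) + 1:3
          xyz[f, cols] <- t(pos)
        }
      }
    }
  })
  ## static atoms identical across frames
  staticIdx <- which(topo$resid != "HOH")
  cols <- rep((staticIdx - 1L) * 3L, each = 3L) + 1:3
  xyz[, cols] <- matrix(rep(as.numeric(t(base[staticIdx, ])), each = nF),
                        nrow = nF)
  ext <- offset * nSub + 4 * (Rwall + 10)
  box <- matrix(rep(c(ext, ext, L + 20), each = nF), nF, 3L)
  new("Trajectory", topology = topo, xyz = xyz,
      time = (seq_len(nF) - 1) * spec@frameStrideTime, box = box,
      metadata = list(tautomer = spec@tautomerLabel, spec = spec,
                      counts = counts))
}

#' WireRegion definitions matching a toy pore spec
#'
#' @param spec the \linkS4class{ToyPoreSpec} used for generation.
#' @param radialCutoff region radius; defaults to the spec's pore radius so
#'   the region cylinder covers exactly the water placement volume.
#' @return named list of \linkS4class{WireRegion}.
#' @export
toyPoreRegions <- function(spec, radialCutoff = spec@poreRadius) {
  regions <- names(spec@regionBounds)
  out <- lapply(seq_along(regions), function(j)
    new("WireRegion", name = regions[j],
        anchorTop = list(resid = "ANC", resno = 2L * j - 1L),
        anchorBottom = list(resid = "ANC", resno = 2L * j),
        radialCutoff = radialCutoff, zPad = 0.5))
  names(out) <- regions
  out
}

## ---------------------------------------------------------------------
## umbrella-sampling generator

#' PmfSpec: tabulated ground-truth potential for umbrella-sampling tests
#'
#' @slot z strictly increasing grid (Angstrom).
#' @slot U potential on the grid (kJ/mol), finite everywhere.
#' @slot temperature K.
#' @exportClass PmfSpec
setClass("PmfSpec",
  representation(z = "numeric", U = "numeric", temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@z) < 2L || any(diff(object@z) <= 0))
      msg <- c(msg, "field 'z' must be a strictly increasing grid")
    if (length(object@U) != length(object@z) || !all(is.finite(object@U)))
      msg <- c(msg, "field 'U' must be finite on the whole grid")
    if (object@temperature <= 0)
      msg <- c(msg, "field 'temperature' must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname PmfSpec-class
#' @param z,U,temperature see slots.
#' @export
PmfSpec <- function(z, U, temperature = 310) {
  new("PmfSpec", z = z, U = U, temperature = temperature)
}

#' Symmetric quartic double-well potential spec
#'
#' U(z) = height * ((z^2 - a^2)^2 / a^4): minima at +-a (U = 0), central
#' barrier of exactly \code{height} at z = 0.
#'
#' @param height barrier height (kJ/mol).
#' @param a half-distance between the wells (Angstrom).
#' @param zRange tabulation range (Angstrom).
#' @param n grid points.
#' @param temperature K.
#' @return a \linkS4class{PmfSpec}.
#' @export
doubleWellSpec <- function(height = 10, a = 5, zRange = c(-10, 10),
                           n = 801, temperature = 310) {
  z <- seq(zRange[1], zRange[2], length.out = n)
  PmfSpec(z, height * ((z^2 - a^2)^2 / a^4), temperature)
}

#' Generate umbrella-window samples on a known potential
#'
#' For each restraint centre, draws from the biased Boltzmann density
#' proportional to exp(-beta * (U(z) + k/2 (z - z0)^2)) by a Metropolis
#' walk whose step size is auto-tuned to 30-50 percent acceptance during
#' burn-in. The first \code{burnIn} draws are discarded. Proposals outside
#' the tabulated range are rejected (hard walls at the grid ends).
#'
#' @param pmf a \linkS4class{PmfSpec} (ground truth).
#' @param centers restraint centres z0 (Angstrom), all within the grid.
#' @param kz harmonic force constant along z (kJ/mol/nm^2; the MD pull-code
#'   convention, default 1000).
#' @param nSamples retained draws per window.
#' @param burnIn discarded initial draws (also the tuning phase).
#' @param seed RNG seed; identical seeds reproduce identical streams.
#' @param flatBottom in-plane flat-bottom restraint carried as metadata
#'   (contributes no z-dependent bias); default radius 5 A, 400 kJ/mol/nm^2.
#' @return list of \linkS4class{UmbrellaWindow}.
#' @export
genUmbrellaSamples <- function(pmf, centers, kz = 1000, nSamples = 8000,
                               burnIn = 2000, seed = 1,
                               flatBottom = list(radius = 5, k = 400)) {
  stopifnot(is(pmf, "PmfSpec"))
  validObject(pmf)
  .assertScalarPositive(kz, "kz")
  rng <- range(pmf@z)
  if (any(centers < rng[1] | centers > rng[2]))
    stop("restraint centers must lie within the potential's z range [",
         rng[1], ", ", rng[2], "]")
  beta <- 1 / (.RGAS * pmf@temperature)
  kA <- kz * .KNM2_TO_A2
  Uf <- approxfun(pmf@z, pmf@U)
  withSeed(seed, {
    lapply(centers, function(z0) {
      bu <- function(z) {
        if (z < rng[1] || z > rng[2]) return(Inf)
        beta * (Uf(z) + 0.5 * kA * (z - z0)^2)
      }
      s <- .metropolis1d(bu, z0, nSamples, burnIn)
      new("UmbrellaWindow", center = z0, k = kz, flatBottom = flatBottom,
          samples = s, temperature = pmf@temperature)
    })
  })
}

## 1-D Metropolis walk with acceptance-tuned step size during burn-in
.metropolis1d <- function(bu, z0, n, burnIn, step0 = 1.0) {
  z <- z0
  u <- bu(z)
  if (!is.finite(u)) stop("starting point has infinite energy")
  step <- step0
  out <- numeric(n)
  acc <- 0L
  block <- 0L
  total <- burnIn + n
  for (i in seq_len(total)) {
    zp <- z + runif(1L, -step, step)
    up <- bu(zp)
    if (is.finite(up) && (up <= u || runif(1L) < exp(u - up))) {
      z <- zp; u <- up; acc <- acc + 1L
    }
    block <- block + 1L
    if (i <= burnIn && block == 50L) {
      r <- acc / 50
      if (r < 0.3) step <- max(step * 0.8, 1e-3)
      else if (r > 0.5) step <- min(step * 1.25, 20)
      acc <- 0L; block <- 0L
    }
    if (i > burnIn) out[i - burnIn] <- z
  }
  out
}

## ---------------------------------------------------------------------
## SSME generators

#' TraceSpec: specification of a synthetic SSME transient current
#'
#' Model: y(t) = y0 + A1 * exp(-t / t1) + N(0, noiseSd^2), the one-phase
#' exponential decay used to analyse solid-supported membrane
#' electrophysiology transients.
#'
#' @slot y0 current offset (nA).
#' @slot A1 amplitude (nA).
#' @slot t1 time constant (s), > 0.
#' @slot noiseSd Gaussian noise sd (nA).
#' @slot duration trace length (s), > 0.
#' @slot sampleRate Hz, > 0.
#' @slot riseTau optional apex rise time constant (s); 0 gives the pure
#'   decay starting at its apex.
#' @slot seed RNG seed.
#' @exportClass TraceSpec
setClass("TraceSpec",
  representation(y0 = "numeric", A1 = "numeric", t1 = "numeric",
                 noiseSd = "numeric", duration = "numeric",
                 sampleRate = "numeric", riseTau = "numeric",
                 seed = "numeric"),
  prototype(riseTau = 0),
  validity = function(object) {
    msg <- character()
    if (object@t1 <= 0) msg <- c(msg, "field 't1' must be > 0")
    if (object@sampleRate <= 0) msg <- c(msg, "field 'sampleRate' must be > 0")
    if (object@duration <= 0) msg <- c(msg, "field 'duration' must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "field 'noiseSd' must be >= 0")
    if (object@riseTau < 0) msg <- c(msg, "field 'riseTau' must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname TraceSpec-class
#' @param y0,A1,t1,noiseSd,duration,sampleRate,riseTau,seed see slots.
#' @export
TraceSpec <- function(y0 = 0, A1 = 3, t1 = 0.05, noiseSd = 0,
                      duration = 1, sampleRate = 1000, riseTau = 0,
                      seed = 1) {
  new("TraceSpec", y0 = y0, A1 = A1, t1 = t1, noiseSd = noiseSd,
      duration = duration, sampleRate = sampleRate, riseTau = riseTau,
      seed = seed)
}

#' Generate a synthetic SSME transient current
#'
#' @param spec a \linkS4class{TraceSpec}.
#' @param metadata extra metadata entries (variant, substrate, lpr, ...)
#'   merged into the trace metadata.
#' @return a \linkS4class{CurrentTrace}; metadata$groundTruth records the
#'   generating parameters.
#' @export
genCurrentTrace <- function(spec, metadata = list()) {
  stopifnot(is(spec, "TraceSpec"))
  validObject(spec)
  t <- seq(0, spec@duration, by = 1 / spec@sampleRate)
  y <- spec@y0 + spec@A1 * exp(-t / spec@t1)
  if (spec@riseTau > 0) y <- spec@y0 +
      (y - spec@y0) * (1 - exp(-t / spec@riseTau))
  if (spec@noiseSd > 0)
    y <- withSeed(spec@seed, y + rnorm(length(t), 0, spec@noiseSd))
  md <- c(metadata,
          list(groundTruth = list(y0 = spec@y0, A1 = spec@A1, t1 = spec@t1,
                                  noiseSd = spec@noiseSd,
                                  riseTau = spec@riseTau, seed = spec@seed)))
  new("CurrentTrace", time = t, current = y, metadata = md)
}

#' Generate an amplitude-vs-concentration series
#'
#' Saturating mode follows the Michaelis-Menten form
#' \code{imax * c / (km + c)}; the non-saturating mode (km = Inf) returns
#' amplitudes linear in concentration, reaching \code{imax} at the largest
#' tested concentration — mimicking transport that shows no saturation in
#' the tested range.
#'
#' @param imax maximal amplitude (nA).
#' @param km Michaelis constant (mM), or Inf for the non-saturating mode.
#' @param concentrations tested concentrations (mM), non-negative.
#' @param noiseSd Gaussian noise sd (nA).
#' @param seed RNG seed.
#' @return data.frame(concentration, amplitude) with attribute
#'   "groundTruth".
#' @export
genMMSeries <- function(imax, km, concentrations, noiseSd = 0, seed = 1) {
  if (any(concentrations < 0))
    stop("concentrations must be non-negative")
  if (!is.numeric(km) || length(km) != 1L || is.na(km) || km <= 0)
    stop("'km' must be a positive number or Inf (non-saturating mode)")
  if (max(concentrations) <= 0)
    stop("at least one concentration must be positive")
  amp <- if (is.infinite(km)) imax * concentrations / max(concentrations)
         else imax * concentrations / (km + concentrations)
  if (noiseSd > 0)
    amp <- withSeed(seed, amp + rnorm(length(amp), 0, noiseSd))
  out <- data.frame(concentration = concentrations, amplitude = amp)
  attr(out, "groundTruth") <- list(imax = imax, km = km, noiseSd = noiseSd,
                                   seed = seed)
  out
}
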