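## Maximal-inscribed-sphere pore profiler. At each station along the pore
## axis the in-plane centre maximises (distance to the nearest atom centre
## minus that atom's van der Waals radius) via seeded simulated annealing
## started from the previous station's centre, followed by a local
## Nelder-Mead polish. This is the classic channel-mapping construction
## used to seed umbrella windows along the most likely transfer route.

## Bondi van der Waals radii (Angstrom) by element; anything unknown falls
## back to carbon.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
            S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, X = 1.70)

.vdwRadii <- function(topology, override = NULL) {
  ele <- toupper(trimws(topology$elesy))
  ele[!nzchar(ele)] <- toupper(substr(trimws(topology$elety[!nzchar(ele)]),
                                      1L, 1L))
  tab <- .BONDI
  if (!is.null(override)) tab[names(override)] <- override
  r <- tab[ele]
  r[is.na(r)] <- tab[["X"]]
  unname(r)
}

## rotation matrix mapping unit vector v onto +z (Rodrigues)
.rotToZ <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c <- sum(v * z)
  if (abs(c - 1) < 1e-12) return(diag(3))
  if (abs(c + 1) < 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
          v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

#' Map the pore radius profile of a structure
#'
#' At stations spaced \code{step} along \code{axis}, finds the in-plane
#' centre maximising the inscribed-sphere radius
#' \code{min_i (|p - x_i| - vdw_i)} by simulated annealing (geometric
#' cooling, \code{annealSteps} proposals per station, restarted from the
#' previous station's centre) plus a Nelder-Mead polish. Stations whose
#' maximisation is unbounded (e.g. degenerate structures) are capped at
#' \code{maxRadius} and flagged.
#'
#' @param traj a \linkS4class{Trajectory}; frame \code{frame} is profiled.
#' @param zRange interval along the axis to profile (Angstrom); defaults
#'   to the structure's extent.
#' @param startPoint optional in-plane (x, y) starting centre for the
#'   first station; defaults to the structure's centroid.
#' @param axis pore axis direction (default +z); coordinates are rotated
#'   so profiling always runs along z.
#' @param step station spacing (Angstrom, default 0.5).
#' @param seed RNG seed for the annealing (bit-reproducible).
#' @param frame frame index.
#' @param vdw named vector of van der Waals radii overriding the built-in
#'   Bondi table (names are element symbols).
#' @param excludeResno residue numbers excluded from the run (e.g. a bulky
#'   gate sidechain removed only for pathway finding).
#' @param stripSolvent drop water residues before profiling (default TRUE).
#' @param maxRadius cap on the reported radius (Angstrom, default 10).
#' @param annealSteps annealing proposals per station (default 200).
#' @return a \linkS4class{PoreProfile}.
#' @export
findPoreProfile <- function(traj, zRange = NULL, startPoint = NULL,
                            axis = c(0, 0, 1), step = 0.5, seed = 1,
                            frame = 1L, vdw = NULL, excludeResno = NULL,
                            stripSolvent = TRUE, maxRadius = 10,
                            annealSteps = 200L) {
  stopifnot(is(traj, "Trajectory"))
  .assertScalarPositive(step, "step")
  axis <- as.numeric(axis)
  top <- traj@topology
  keep <- rep(TRUE, nrow(top))
  if (stripSolvent) keep <- keep & !(top$resid %in% .WATER_RESNAMES)
  if (!is.null(excludeResno)) keep <- keep & !(top$resno %in% excludeResno)
  if (!any(keep)) stop("no atoms left to profile")
  coords <- frameCoords(traj, frame)[keep, , drop = FALSE]
  radii <- .vdwRadii(top[keep, , drop = FALSE], vdw)
  Rm <- .rotToZ(axis)
  coords <- coords %*% t(Rm)
  if (is.null(zRange)) zRange <- range(coords[, 3L])
  zs <- seq(zRange[1], zRange[2], by = step)
  if (length(zs) < 1L) stop("empty z range")
  center <- if (is.null(startPoint)) colMeans(coords)[1:2]
            else as.numeric(startPoint)[1:2]
  maxVdw <- max(radii)

  ## inscribed radius at p = (x, y, z) against the pre-sliced atom set
  out <- data.frame(z = zs, x = NA_real_, y = NA_real_,
                    radius = NA_real_, capped = FALSE)
  withSeed(seed, {
    for (si in seq_along(zs)) {
      z <- zs[si]
      slab <- abs(coords[, 3L] - z) <= maxRadius + maxVdw
      if (!any(slab)) {
        out$x[si] <- center[1L]; out$y[si] <- center[2L]
        out$radius[si] <- maxRadius; out$capped[si] <- TRUE
        next
      }
      ax <- coords[slab, 1L]; ay <- coords[slab, 2L]; az <- coords[slab, 3L]
      ar <- radii[slab]
      f <- function(p) {
        r2 <- (p[1L] - ax)^2 + (p[2L] - ay)^2 + (z - az)^2
        min(min(sqrt(r2) - ar), maxRadius)
      }
      ## annealing: geometric cooling from the previous station's centre.
      ## The initial temperature is kept well below the wall-penetration
      ## cost so the walk tracks the channel instead of tunnelling through
      ## a single-atom wall and escaping outside the structure.
      p <- center
      fp <- f(p)
      Temp <- 0.3
      sigma <- 1.0
      for (it in seq_len(annealSteps)) {
        q <- p + rnorm(2L, 0, sigma)
        fq <- f(q)
        if (fq >= fp || runif(1L) < exp((fq - fp) / Temp)) {
          p <- q; fp <- fq
        }
        Temp <- Temp * 0.97
        sigma <- max(sigma * 0.985, 0.02)
      }
      ## local polish (deterministic)
      op <- optim(p, function(q) -f(q), method = "Nelder-Mead",
                  control = list(reltol = 1e-10, maxit = 400L))
      if (-op$value >= fp) { p <- op$par; fp <- -op$value }
      capped <- fp >= maxRadius - 1e-9
      out$x[si] <- p[1L]; out$y[si] <- p[2L]
      out$radius[si] <- min(fp, maxRadius); out$capped[si] <- capped
      center <- p
    }
  })
  if (all(out$radius < 0))
    stop("pore blocked: inscribed radius negative at every station")
  out$radius <- pmax(out$radius, 0)
  new("PoreProfile", stations = out, axis = axis / sqrt(sum(axis^2)),
      step = step)
}

#' Seed points for umbrella windows along a pore profile
#'
#' Interpolates the profile centres linearly at exact \code{spacing}
#' intervals spanning the profile's z range, endpoints included — the
#' window-placement rule of the umbrella protocol (default 0.5 Angstrom).
#'
#' @param profile a \linkS4class{PoreProfile}.
#' @param spacing window spacing (Angstrom, default 0.5).
#' @return data.frame(z, x, y); if \code{spacing} exceeds the profile's z
#'   range, a single midpoint with a warning.
#' @export
windowSeedPoints <- function(profile, spacing = 0.5) {
  stopifnot(is(profile, "PoreProfile"))
  .assertScalarPositive(spacing, "spacing")
  st <- profile@stations
  if (!nrow(st)) stop("empty profile")
  zlo <- min(st$z); zhi <- max(st$z)
  if (spacing > zhi - zlo) {
    warning("spacing exceeds the profile z range; returning the midpoint")
    zs <- (zlo + zhi) / 2
  } else {
    zs <- seq(zlo, zhi, by = spacing)
    if (zhi - zs[length(zs)] > 1e-9) zs <- c(zs, zhi)
  }
  if (nrow(st) == 1L) {
    return(data.frame(z = zs, x = st$x, y = st$y))
  }
  ord <- order(st$z)
  data.frame(z = zs,
             x = approx(st$z[ord], st$x[ord], xout = zs, rule = 2)$y,
             y = approx(st$z[ord], st$y[ord], xout = zs, rule = 2)$y)
}

#' Write a pore profile and its seed points as TSV
#'
#' @param profile a \linkS4class{PoreProfile}.
#' @param stem output stem; writes \code{<stem>_profile.tsv} and
#'   \code{<stem>_seeds.tsv}.
#' @param spacing seed-point spacing (Angstrom).
#' @return invisibly, the seed-point data.frame.
#' @export
writePoreProfile <- function(profile, stem, spacing = 0.5) {
  write.table(profile@stations, paste0(stem, "_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seeds <- windowSeedPoints(profile, spacing)
  write.table(seeds, paste0(stem, "_seeds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(seeds)
}

## Convenience builders for analytically known test geometries -----------

#' Ideal cylinder / hourglass wall structures with analytic pore radius
#'
#' Builds single-frame structures of wall pseudo-atoms (vdW radius 1.7 A)
#' whose inscribed pore radius is known analytically: a straight cylinder
#' of accessible radius \code{radius}, or an hourglass whose accessible
#' radius varies linearly from \code{mouthRadius} at both ends to
#' \code{waistRadius} at the mid-plane.
#'
#' @param radius accessible cylinder radius (Angstrom).
#' @param length wall length along z (Angstrom).
#' @param spacing wall lattice spacing (Angstrom).
#' @return a one-frame \linkS4class{Trajectory}.
#' @export
cylinderStructure <- function(radius = 2, length = 20, spacing = 0.5) {
  .wallStructure(function(z) radius, length, spacing)
}

#' @rdname cylinderStructure
#' @param waistRadius,mouthRadius accessible radii at the mid-plane and the
#'   ends (Angstrom).
#' @export
hourglassStructure <- function(waistRadius = 1, mouthRadius = 3,
                               length = 20, spacing = 0.5) {
  half <- length / 2
  .wallStructure(function(z)
    waistRadius + (mouthRadius - waistRadius) * abs(z - half) / half,
    length, spacing)
}

.wallStructure <- function(radiusAt, length, spacing) {
  zs <- seq(0, length, by = spacing)
  pts <- do.call(rbind, lapply(zs, function(z) {
    Rc <- radiusAt(z) + .WALL_VDW
    n <- max(8L, ceiling(2 * pi * Rc / spacing))
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(Rc * cos(th), Rc * sin(th), z)
  }))
  topo <- data.frame(eleno = seq_len(nrow(pts)), elety = "C",
                     resid = "WAL", resno = seq_len(nrow(pts)),
                     chain = "W", elesy = "C", stringsAsFactors = FALSE)
  new("Trajectory", topology = topo,
      xyz = matrix(as.numeric(t(pts)), nrow = 1L),
      time = 0, box = matrix(0, 1L, 3L))
}
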