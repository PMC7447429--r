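## Weighted histogram analysis method (WHAM) for 1-D umbrella sampling,
## with Bayesian-bootstrap uncertainties. The self-consistent equations
## are iterated on binned histograms; the harmonic bias is evaluated at
## bin centres. Force constants follow the MD pull-code convention
## (kJ/mol/nm^2) and are converted to Angstrom units internally
## (1 kJ/mol/nm^2 = 0.01 kJ/mol/A^2). The in-plane flat-bottom restraint
## carried by windows contributes no z-dependent bias and is treated as
## metadata only.

## shared precomputation: grid, per-window bin indices, bias factors
.whamPrep <- function(windows, binWidth = 0.1, nBins = NULL,
                      periodic = FALSE, period = NULL) {
  stopifnot(length(windows) >= 2L)
  for (w in windows) validObject(w)
  temps <- vapply(windows, function(w) w@temperature, numeric(1L))
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  kT <- .RGAS * temps[1L]
  allz <- unlist(lapply(windows, function(w) w@samples))
  lo <- min(allz); hi <- max(allz)
  if (!is.null(nBins)) {
    edges <- seq(lo, hi, length.out = nBins + 1L)
    binWidth <- edges[2L] - edges[1L]
  } else {
    nb <- max(2L, ceiling((hi - lo) / binWidth))
    edges <- seq(lo, lo + nb * binWidth, by = binWidth)
  }
  nb <- length(edges) - 1L
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  if (periodic && is.null(period)) period <- edges[length(edges)] - edges[1L]
  binIdx <- lapply(windows, function(w) {
    i <- findInterval(w@samples, edges, rightmost.closed = TRUE)
    pmin.int(pmax.int(i, 1L), nb)
  })
  N <- vapply(windows, function(w) length(w@samples), numeric(1L))
  C <- t(vapply(windows, function(w) {
    d <- centers - w@center
    if (periodic) d <- d - period * round(d / period)
    exp(-(0.5 * w@k * .KNM2_TO_A2 * d^2) / kT)
  }, numeric(nb)))
  list(edges = edges, centers = centers, binIdx = binIdx, N = N, C = C,
       kT = kT, binWidth = binWidth, nb = nb,
       temperature = temps[1L], periodic = periodic)
}

## self-consistent solve given per-window bin histograms H (K x B)
.whamSolve <- function(prep, H, tol = 1e-8, maxIter = 1e5, f0 = NULL) {
  Htot <- colSums(H)
  f <- f0 %||% numeric(length(prep$N))       # dimensionless (units of kT)
  C <- prep$C
  Ng <- prep$N
  resid <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- drop(crossprod(C, Ng * exp(f)))
    P <- ifelse(denom > 0, Htot / denom, 0)
    Z <- drop(C %*% P)
    fnew <- -log(Z)
    fnew <- fnew - fnew[1L]
    resid <- max(abs(fnew - f)) * prep$kT
    f <- fnew
    if (resid < tol) break
    if (it >= maxIter)
      stop(sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
        as.integer(maxIter), resid))
  }
  list(P = P, f = f, iterations = it, residual = resid, Htot = Htot)
}

.whamHistogram <- function(prep, weights = NULL) {
  K <- length(prep$N)
  H <- matrix(0, K, prep$nb)
  for (k in seq_len(K)) {
    if (is.null(weights)) {
      H[k, ] <- tabulate(prep$binIdx[[k]], nbins = prep$nb)
    } else {
      sums <- rowsum(weights[[k]], prep$binIdx[[k]])
      acc <- numeric(prep$nb)
      acc[as.integer(rownames(sums))] <- sums
      H[k, ] <- prep$N[k] * acc
    }
  }
  H
}

## histogram coverage check: every pair of adjacent windows (by restraint
## centre) must share at least one occupied bin, otherwise the combined
## profile has a sampling gap. (Empty bins from stray tail samples are
## tolerated; they surface as flagged NA bins, never interpolated.)
.checkCoverage <- function(prep, H) {
  if (sum(colSums(H) > 0) < 2L) stop("histograms cover fewer than two bins")
  centers <- vapply(seq_len(nrow(H)), function(k)
    prep$centers[which.max(H[k, ])], numeric(1L))
  ord <- order(centers)
  for (i in seq_len(length(ord) - 1L)) {
    a <- ord[i]; b <- ord[i + 1L]
    if (!any(H[a, ] > 0 & H[b, ] > 0)) {
      hiA <- max(prep$centers[H[a, ] > 0])
      loB <- min(prep$centers[H[b, ] > 0])
      stop(sprintf(
        "window histograms do not overlap: gap between z = %.3f and z = %.3f",
        hiA, loB))
    }
  }
  invisible(TRUE)
}

#' Reconstruct a 1-D PMF from umbrella windows by WHAM
#'
#' Iterates the self-consistent WHAM equations on binned window
#' histograms until the largest change in the window free-energy shifts
#' falls below \code{tol}. The profile is anchored so its minimum is zero;
#' bins with zero total counts are flagged (NA), never interpolated.
#'
#' @param windows list of \linkS4class{UmbrellaWindow} (>= 2, jointly
#'   covering the grid; a gap raises a coverage error naming the interval).
#' @param binWidth histogram bin width (Angstrom, default 0.1).
#' @param nBins alternatively, an explicit bin count.
#' @param tol convergence tolerance on the window free energies (kJ/mol).
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param periodic treat the coordinate as periodic (minimum-image bias
#'   over \code{period}, defaulting to the grid span).
#' @param period explicit period (Angstrom) when \code{periodic}.
#' @return a \linkS4class{PMFProfile} (sd all zero until
#'   \code{\link{bayesianBootstrap}} is run).
#' @export
wham <- function(windows, binWidth = 0.1, nBins = NULL, tol = 1e-8,
                 maxIter = 1e5, periodic = FALSE, period = NULL) {
  prep <- .whamPrep(windows, binWidth, nBins, periodic, period)
  H <- .whamHistogram(prep)
  .checkCoverage(prep, H)
  sol <- .whamSolve(prep, H, tol, maxIter)
  .profileFromSolution(prep, sol)
}

.profileFromSolution <- function(prep, sol) {
  W <- rep(NA_real_, prep$nb)
  pos <- sol$P > 0
  W[pos] <- -prep$kT * log(sol$P[pos])
  W <- W - min(W, na.rm = TRUE)
  new("PMFProfile", z = prep$centers, W = W,
      sd = numeric(prep$nb), reference = "anchor-min",
      emptyBins = !pos,
      details = list(f = sol$f * prep$kT, iterations = sol$iterations,
                     residual = sol$residual,
                     temperature = prep$temperature,
                     binWidth = prep$binWidth, counts = sol$Htot))
}

#' Bayesian-bootstrap uncertainty of a WHAM profile
#'
#' Each bootstrap replicate reweights every window's samples with
#' Dirichlet(1, ..., 1) weights, re-solves WHAM, re-anchors the replicate
#' profile (so the arbitrary additive constant does not inflate the
#' error), and the pointwise standard deviation across replicates is
#' reported.
#'
#' @param windows list of \linkS4class{UmbrellaWindow}.
#' @param nBoot bootstrap replicates (default 200).
#' @param seed RNG seed (bit-reproducible).
#' @param ... passed to \code{\link{wham}} (binWidth, tol, periodic, ...).
#' @return the base \linkS4class{PMFProfile} with its \code{sd} slot
#'   filled; more than 10 percent failed replicates is an error.
#' @export
bayesianBootstrap <- function(windows, nBoot = 200, seed = 1, ...) {
  args <- list(...)
  prep <- .whamPrep(windows, args$binWidth %||% 0.1, args$nBins,
                    isTRUE(args$periodic), args$period)
  tol <- args$tol %||% 1e-8
  maxIter <- args$maxIter %||% 1e5
  H <- .whamHistogram(prep)
  .checkCoverage(prep, H)
  base <- .whamSolve(prep, H, tol, maxIter)
  profile <- .profileFromSolution(prep, base)
  if (nBoot < 1L) stop("nBoot must be >= 1")
  if (nBoot == 1L) {
    profile@sd <- numeric(prep$nb)
    return(profile)
  }
  reps <- matrix(NA_real_, nBoot, prep$nb)
  failures <- 0L
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      weights <- lapply(prep$N, function(n) {
        w <- rexp(n)
        w / sum(w)
      })
      Hb <- .whamHistogram(prep, weights)
      sol <- tryCatch(
        .whamSolve(prep, Hb, tol, maxIter, f0 = base$f),
        error = function(e) NULL)
      if (is.null(sol)) { failures <- failures + 1L; next }
      Wb <- rep(NA_real_, prep$nb)
      pos <- sol$P > 0
      Wb[pos] <- -prep$kT * log(sol$P[pos])
      reps[b, ] <- Wb - min(Wb, na.rm = TRUE)
    }
  })
  if (failures > 0.1 * nBoot)
    stop(sprintf("%d of %d bootstrap replicates failed", failures, nBoot))
  profile@sd <- apply(reps, 2L, sd, na.rm = TRUE)
  profile@sd[is.na(profile@sd)] <- 0
  profile
}

#' @describeIn barrier barrier of a PMF profile: max(W) minus W at the
#'   first grid point of the (optionally restricted) range; ties broken
#'   toward smaller z. Empty bins are skipped.
#' @param zRange optional c(lo, hi) restriction (Angstrom).
#' @export
setMethod("barrier", "PMFProfile", function(x, zRange = NULL, ...) {
  keep <- is.finite(x@W)
  if (!is.null(zRange))
    keep <- keep & x@z >= zRange[1L] & x@z <= zRange[2L]
  if (sum(keep) < 2L) stop("fewer than two profile points in range")
  z <- x@z[keep]; W <- x@W[keep]
  ord <- order(z)
  z <- z[ord]; W <- W[ord]
  imax <- which(W >= max(W) - 1e-12)[1L]   # ties -> smaller z
  list(deltaG = W[imax] - W[1L], z = z[imax])
})

#' Write a PMF profile as TSV (z, W, sd)
#'
#' @param profile a \linkS4class{PMFProfile}.
#' @param path output TSV.
#' @export
writePMF <- function(profile, path) {
  write.table(pmfTable(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
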