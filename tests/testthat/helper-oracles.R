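## Independent oracles used to check package results. These deliberately
## use different algorithms / code paths than the implementation:
## eigen-decomposition for Markov stationary distributions, hand-rolled
## breadth-first search on explicit distance matrices, direct Boltzmann
## quadrature on the ground-truth potential, exhaustive in-plane grid
## search for pore radii, and a binless MBAR estimator (convex-objective
## minimisation) as the cross-implementation free-energy check.

RGAS <- 0.0083145

## stationary distribution of a row-stochastic matrix via eigen
stationaryDist <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

## standard error of an occupancy fraction estimated from an
## autocorrelated two-state chain: the usual binomial SE inflated by the
## integrated autocorrelation of a chain with second eigenvalue lambda
markovSE <- function(p, n, lambda) {
  sqrt(p * (1 - p) / n * (1 + lambda) / (1 - lambda))
}

## breadth-first search connectivity on an explicit distance matrix
bfsConnected <- function(D, from, to, dLink) {
  n <- nrow(D)
  seen <- rep(FALSE, n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    if (v %in% to) return(TRUE)
    nb <- which(D[v, ] <= dLink + 1e-9 & !seen)
    nb <- setdiff(nb, v)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  any(seen[to])
}

## brute-force water count in an axis-aligned cylindrical region of a toy
## pore: direct coordinate test against the generating spec's bounds
bruteForceRegionCount <- function(traj, spec, regionName, frame,
                                  subunit = 1L) {
  co <- frameCoords(traj, frame)
  top <- topology(traj)
  ch <- LETTERS[subunit]
  wat <- top$resid == "HOH" & top$chain == ch
  b <- spec@regionBounds[[regionName]]
  cx <- (subunit - 1L) *
    (2 * (spec@poreRadius + 1.7 + 6) + 8)  # generator's subunit offset
  r <- sqrt((co[wat, 1L] - cx)^2 + co[wat, 2L]^2)
  sum(co[wat, 3L] >= b[1L] & co[wat, 3L] <= b[2L] &
      r <= spec@poreRadius + 1e-9)
}

## exact binned free-energy profile by Boltzmann quadrature of the
## ground-truth potential on a refined grid (trapezoidal integration of
## exp(-U/kT) within each bin)
exactBinnedPMF <- function(pmfSpec, edges) {
  kT <- RGAS * pmfSpec@temperature
  Uf <- approxfun(pmfSpec@z, pmfSpec@U, rule = 2)  # clamp past the grid
  W <- vapply(seq_len(length(edges) - 1L), function(b) {
    zz <- seq(edges[b], edges[b + 1L], length.out = 51L)
    y <- exp(-Uf(zz) / kT)
    -kT * log(sum((y[-1L] + y[-length(y)]) / 2 * diff(zz)))
  }, numeric(1L))
  W - min(W, na.rm = TRUE)
}

## barrier of a binned profile, referenced to the first bin of the range
## (mirrors the package convention, computed independently)
binnedBarrier <- function(z, W, zRange) {
  keep <- z >= zRange[1L] & z <= zRange[2L] & is.finite(W)
  zz <- z[keep]; ww <- W[keep]
  ord <- order(zz)
  zz <- zz[ord]; ww <- ww[ord]
  max(ww) - ww[1L]
}

## exhaustive in-plane grid search for the maximal inscribed sphere at one
## z station (0.05 A grid)
gridSearchRadius <- function(coords, radii, z, xlim, ylim, grid = 0.05,
                             maxRadius = 10) {
  xs <- seq(xlim[1L], xlim[2L], by = grid)
  ys <- seq(ylim[1L], ylim[2L], by = grid)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  best <- -Inf; bestP <- c(NA, NA)
  for (i in seq_len(nrow(g))) {
    d <- sqrt((g[i, 1L] - coords[, 1L])^2 + (g[i, 2L] - coords[, 2L])^2 +
              (z - coords[, 3L])^2) - radii
    f <- min(min(d), maxRadius)
    if (f > best) { best <- f; bestP <- g[i, ] }
  }
  list(radius = best, center = bestP)
}

## ---------------------------------------------------------------------
## Binless MBAR estimator (independent cross-check of the package's
## binned WHAM). Window free energies minimise the convex MBAR objective
##   F(f) = (1/N) sum_n logsumexp_k(log N_k + f_k - u_k(z_n))
##          - sum_k (N_k / N) f_k
## (gradient = MBAR self-consistency); unbiased sample weights are
## w_n = exp(-logsumexp_n), binned on the supplied edges.
## f0: optional starting values for the window free energies (units kT).
## The objective is convex, so the starting point only affects the
## iteration count, never the optimum.
mbarPMF <- function(windows, edges, f0 = NULL) {
  kT <- RGAS * windows[[1L]]@temperature
  z <- unlist(lapply(windows, windowSamples))
  Nk <- vapply(windows, function(w) length(w@samples), numeric(1L))
  N <- sum(Nk)
  K <- length(windows)
  ## reduced bias u_k(z_n), K x N
  U <- matrix(0, K, N)
  for (k in seq_len(K)) {
    w <- windows[[k]]
    U[k, ] <- 0.5 * w@k * 0.01 * (z - w@center)^2 / kT
  }
  lognk <- log(Nk)
  objgrad <- function(fr) {
    f <- c(0, fr)                       # fix f_1 = 0 (gauge)
    A <- (f + lognk) - U                # K x N
    m <- A[1L, ]
    for (k in 2:K) m <- pmax(m, A[k, ])
    E <- exp(A - rep(m, each = K))
    S <- colSums(E)
    val <- mean(m + log(S)) - sum(Nk * f) / N
    P <- E / rep(S, each = K)
    g <- rowSums(P) / N - Nk / N
    attr(val, "gradient") <- g[-1L]
    val
  }
  start <- if (is.null(f0)) numeric(K - 1L) else (f0 - f0[1L])[-1L]
  opt <- nlm(objgrad, start, gradtol = 1e-8, iterlim = 500L)
  f <- c(0, opt$estimate)
  A <- (f + lognk) - U
  m <- A[1L, ]
  for (k in 2:K) m <- pmax(m, A[k, ])
  logDenom <- m + log(colSums(exp(A - rep(m, each = K))))
  w <- exp(-(logDenom - min(logDenom)))
  bin <- findInterval(z, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), length(edges) - 1L)
  sums <- rowsum(w, bin)
  W <- rep(NA_real_, length(edges) - 1L)
  W[as.integer(rownames(sums))] <- -kT * log(sums)
  W - min(W, na.rm = TRUE)
}
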