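## Solid-supported membrane electrophysiology (SSME) analysis. A substrate
## pulse on proteoliposome-coated sensors triggers a transient current;
## its one-phase exponential decay rate, and how that rate responds to the
## liposomal lipid-to-protein ratio (LPR), distinguishes full transport
## cycles (faster decay at lower LPR, i.e. more protein per liposome)
## from mere substrate binding (LPR-independent decay).

#' Fit a one-phase exponential decay to a transient current
#'
#' Locates the peak apex as the signed extremum matching the trace's
#' dominant polarity, takes the trailing-median baseline, and fits
#' \code{y = y0 + A1 * exp(-x / t1)} (x measured from the apex) between
#' the apex and the point where the smoothed trace settles to within
#' twice the noise of the baseline, using Levenberg-Marquardt
#' least-squares.
#'
#' @param trace a \linkS4class{CurrentTrace} with at least 10 samples
#'   after the apex.
#' @param baselineFraction trailing fraction of samples defining the
#'   baseline and noise floor (default 0.05).
#' @return a \linkS4class{DecayFit}; \code{flat} is TRUE when the fitted
#'   amplitude is below the noise floor (no resolvable transient).
#' @export
fitDecay <- function(trace, baselineFraction = 0.05) {
  stopifnot(is(trace, "CurrentTrace"))
  validObject(trace)
  t <- trace@time
  y <- trace@current
  n <- length(t)
  polarity <- sign(y[which.max(abs(y))])
  if (polarity == 0) polarity <- 1
  apex <- which.max(polarity * y)
  if (n - apex + 1L < 10L)
    stop("window error: fewer than 10 samples after the apex")
  nb <- max(3L, ceiling(baselineFraction * n))
  tailIdx <- (n - nb + 1L):n
  baseline <- median(y[tailIdx])
  noise <- sd(y[tailIdx])
  ## end of the fit window: first time the smoothed trace stays within
  ## 2 x noise of the baseline for good (noiseless traces use the full
  ## tail)
  endIdx <- n
  if (is.finite(noise) && noise > 1e-12) {
    k <- min(max(3L, 2L * (n %/% 100L) + 1L), n - (n + 1L) %% 2L)
    sm <- runmed(y, k)
    inside <- abs(sm - baseline) <= 2 * noise
    stays <- rev(cumprod(rev(inside))) > 0
    hit <- which(stays & seq_len(n) > apex)
    if (length(hit)) endIdx <- max(hit[1L], apex + 9L)
  }
  idx <- apex:endIdx
  x <- t[idx] - t[apex]
  yy <- y[idx]
  a0 <- yy[1L] - baseline
  ## crude t1 start: time to decay to 1/e of the initial amplitude
  drop1 <- which(polarity * (yy - baseline) <= polarity * a0 / exp(1))
  t10 <- if (length(drop1)) max(x[drop1[1L]], diff(range(x)) / 50)
         else diff(range(x)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ y0 + A1 * exp(-x / t1),
                      start = list(y0 = baseline, A1 = a0, t1 = t10),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit error: Levenberg-Marquardt did not converge (",
           conditionMessage(e), ")"))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3L, 3L))
  flat <- abs(cf[["A1"]]) <= 2 * max(noise, 0)
  new("DecayFit", y0 = cf[["y0"]], A1 = cf[["A1"]], t1 = cf[["t1"]],
      rate = 1 / cf[["t1"]], window = c(t[apex], t[endIdx]), cov = vc,
      flat = flat,
      details = list(sigma = summary(fit)$sigma,
                     df = stats::df.residual(fit), nPoints = length(idx),
                     baseline = baseline, noise = noise))
}

#' 95 percent confidence interval for the fitted time constant
#'
#' Wald interval from the fit covariance, on the t distribution with the
#' fit's residual degrees of freedom.
#'
#' @param fit a \linkS4class{DecayFit}.
#' @return c(lower, upper) in seconds.
#' @export
decayCI <- function(fit) {
  stopifnot(is(fit, "DecayFit"))
  se <- sqrt(fit@cov[3L, 3L])
  q <- qt(0.975, fit@details$df)
  c(fit@t1 - q * se, fit@t1 + q * se)
}

#' Classify transport vs binding from LPR-dependent decay rates
#'
#' A full transport cycle empties the liposome faster when more
#' transporters are present, so its current decays faster at LPR 5 than
#' at LPR 10; a binding-only (pre-steady-state) current is
#' LPR-independent. The call is made on the ratio
#' \code{r = rate(LPR 5) / rate(LPR 10)}: transport when
#' \code{r >= ratioThreshold}, binding below it, and no_current when
#' either condition recorded no transient (NC).
#'
#' @param rates data.frame with columns \code{variant}, \code{substrate},
#'   \code{lpr} and either per-fit \code{rate} rows (aggregated to mean
#'   and sd here) or summary columns \code{rate_mean}, \code{rate_sd}.
#'   NA rates mark NC conditions.
#' @param ratioThreshold decision threshold on r (default 1.2).
#' @return data.frame with one row per (variant, substrate): mean rates
#'   and sds at both LPRs, the ratio, and \code{call} in
#'   \{"transport", "binding", "no_current"\}.
#' @export
classifyTransport <- function(rates, ratioThreshold = 1.2) {
  .assertScalarPositive(ratioThreshold, "ratioThreshold")
  need <- c("variant", "substrate", "lpr")
  if (!all(need %in% names(rates)))
    stop("rates must have columns variant, substrate, lpr")
  if ("rate" %in% names(rates)) {
    agg <- aggregate(rate ~ variant + substrate + lpr, data = rates,
                     FUN = function(v) c(mean(v), sd(v)), na.action = NULL)
    rates <- data.frame(agg[, need], rate_mean = agg$rate[, 1L],
                        rate_sd = agg$rate[, 2L])
  }
  if (!all(c("rate_mean", "rate_sd") %in% names(rates)))
    stop("rates must have rate columns ('rate' or 'rate_mean'/'rate_sd')")
  keys <- unique(rates[, c("variant", "substrate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(keys[i, , drop = FALSE], rates)
    pick <- function(lpr) {
      r <- sub[sub$lpr == lpr, , drop = FALSE]
      if (!nrow(r)) stop(sprintf(
        "missing LPR %g group for %s/%s", lpr, keys$variant[i],
        keys$substrate[i]))
      r[1L, ]
    }
    r10 <- pick(10); r5 <- pick(5)
    nc <- is.na(r10$rate_mean) || is.na(r5$rate_mean)
    ratio <- if (nc) NA_real_ else r5$rate_mean / r10$rate_mean
    call <- if (nc) "no_current"
            else if (ratio >= ratioThreshold) "transport" else "binding"
    data.frame(variant = keys$variant[i], substrate = keys$substrate[i],
               rate_lpr10 = r10$rate_mean, sd_lpr10 = r10$rate_sd,
               rate_lpr5 = r5$rate_mean, sd_lpr5 = r5$rate_sd,
               ratio = ratio, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the packaged SSME decay-rate summary table
#'
#' Mean and sd of one-phase decay rates (1/s) of transient currents after
#' a 200 mM ammonium or potassium pulse, for AmtB variants and NeRh50
#' reconstituted at LPR 10 and LPR 5. NA rates mark conditions with no
#' recorded transient (NC).
#'
#' @param path TSV; defaults to the packaged table.
#' @return data.frame(variant, substrate, lpr, rate_mean, rate_sd).
#' @export
loadDecayRateTable <- function(path = system.file(
                                 "extdata", "amtb_ssme_decay_rates.tsv",
                                 package = "ammtools")) {
  if (!file.exists(path)) stop("rate table not found: ", path)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, na.strings = c("NA", "NC"))
}

#' Build a rate table from decay fits
#'
#' @param fits list of \linkS4class{DecayFit}.
#' @param meta data.frame with one row per fit: variant, substrate, lpr.
#' @return data.frame(variant, substrate, lpr, rate) suitable for
#'   \code{\link{classifyTransport}}.
#' @export
decayRateTable <- function(fits, meta) {
  stopifnot(length(fits) == nrow(meta))
  data.frame(meta[, c("variant", "substrate", "lpr")],
             rate = vapply(fits, decayRate, numeric(1L)))
}

#' Normalize an amplitude-vs-concentration series
#'
#' Divides every amplitude by the amplitude recorded at the largest tested
#' concentration (the convention for comparing saturation curves across
#' variants: the 200 mM pulse is normalised to 1.0).
#'
#' @param series data.frame(concentration, amplitude).
#' @return the series with amplitude rescaled.
#' @export
normalizeAmplitudes <- function(series) {
  if (!nrow(series)) stop("empty series")
  ref <- series$amplitude[which.max(series$concentration)]
  if (!is.finite(ref) || ref == 0)
    stop("amplitude at the largest concentration is zero")
  series$amplitude <- series$amplitude / ref
  series
}

#' Fit Michaelis-Menten kinetics to an amplitude series
#'
#' Fits \code{I = Imax * c / (Km + c)} by Levenberg-Marquardt. When the
#' fitted Km exceeds the largest tested concentration, or its confidence
#' interval is unbounded above, no saturation was reached in the tested
#' range: \code{saturating} is FALSE and Km is reported as not measurable
#' (NA).
#'
#' @param series data.frame(concentration, amplitude), >= 4 concentrations.
#' @return a \linkS4class{KineticsFit}.
#' @export
fitMM <- function(series) {
  if (length(unique(series$concentration)) < 4L)
    stop("at least 4 concentrations required")
  cmax <- max(series$concentration)
  conc <- series$concentration
  amp <- series$amplitude
  ## Levenberg-Marquardt on the residual function directly; several Km
  ## starting guesses since saturated (Km -> 0) and non-saturating
  ## (Km -> Inf) limits sit on opposite ends of a shallow valley
  best <- NULL
  for (km0 in c(median(conc), min(conc) / 100, 10 * cmax)) {
    r <- tryCatch(
      minpack.lm::nls.lm(
        par = c(imax = max(amp) * 1.2, km = km0),
        fn = function(p) amp - p[[1L]] * conc / (p[[2L]] + conc),
        lower = c(1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 500L)),
      error = function(e) NULL)
    if (!is.null(r) && r$info %in% 1:3 &&
        (is.null(best) || r$deviance < best$deviance)) best <- r
  }
  if (is.null(best))
    stop("fit error: Michaelis-Menten regression did not converge")
  cf <- coef(best)
  dof <- max(length(amp) - 2L, 1L)
  sigma2 <- best$deviance / dof
  se <- if (sigma2 < 1e-20) c(imax = 0, km = 0)  # interpolating fit
        else tryCatch(sqrt(pmax(diag(sigma2 * solve(best$hessian)), 0)),
                      error = function(e) c(imax = Inf, km = Inf))
  kmUpper <- cf[["km"]] + qt(0.975, dof) * se[["km"]]
  saturating <- is.finite(kmUpper) && cf[["km"]] <= cmax &&
    kmUpper <= 4 * cmax
  new("KineticsFit",
      km = if (saturating) cf[["km"]] else NA_real_,
      imax = cf[["imax"]], saturating = saturating,
      concRange = range(conc),
      se = c(imax = unname(se[["imax"]]), km = unname(se[["km"]])))
}

#' Solvent (heavy-water) effect on peak amplitudes
#'
#' Proton transfer through a water wire is strongly slowed in D2O (each
#' deuteron hop is ~30 percent slower per molecule), so a transporter
#' whose cycle requires water-wire proton transfer loses its current in
#' heavy water, while direct ion translocation does not. Compares peak
#' amplitudes between solvents: ratio of means (D2O / H2O) with a
#' two-sided bootstrap percentile interval and a qualitative tag.
#'
#' @param h2o,d2o lists of \linkS4class{CurrentTrace} (or numeric vectors
#'   of peak amplitudes) for the two solvents.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param level interval level (default 0.95).
#' @return list(ratio, ci, tag) with tag in \{"abolished" (ratio < 0.1),
#'   "unchanged" (interval contains 1), "reduced"\}.
#' @export
solventEffect <- function(h2o, d2o, nBoot = 2000, seed = 1, level = 0.95) {
  peak <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(tr) max(abs(tr@current)), numeric(1L))
  }
  a <- peak(h2o); b <- peak(d2o)
  if (!length(a) || !length(b)) stop("both solvent groups must be non-empty")
  ratio <- mean(b) / mean(a)
  ci <- withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(i)
      mean(sample(b, replace = TRUE)) / mean(sample(a, replace = TRUE)),
      numeric(1L))
    quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  })
  tag <- if (ratio < 0.1) "abolished"
         else if (ci[1L] <= 1 && ci[2L] >= 1) "unchanged"
         else "reduced"
  list(ratio = ratio, ci = ci, tag = tag)
}
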