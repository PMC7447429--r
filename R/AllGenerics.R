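#' Water-wire occupancy of a trajectory region
#'
#' @param x object holding per-frame counts (a \linkS4class{Trajectory}).
#' @param ... method arguments.
#' @return a \linkS4class{WireOccupancyResult}.
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

#' Free-energy barrier of a profile or site list
#'
#' @param x a \linkS4class{PMFProfile} or \linkS4class{ProtonProfile}.
#' @param ... method arguments (\code{zRange}, \code{reference}).
#' @return list with elements \code{deltaG} (kJ/mol), \code{z} (Angstrom)
#'   and, for site lists, \code{label}.
#' @export
setGeneric("barrier", function(x, ...) standardGeneric("barrier"))

#' Number of frames in a trajectory
#' @param x a \linkS4class{Trajectory}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom topology of a trajectory
#' @param x a \linkS4class{Trajectory}.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinates of one frame
#' @param x a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @return numeric matrix (atoms x 3), Angstrom.
#' @export
setGeneric("frameCoords", function(x, frame = 1L)
  standardGeneric("frameCoords"))

#' Write a trajectory to disk
#'
#' @param x a \linkS4class{Trajectory}.
#' @param path output file; format from extension (.pdb multi-model,
#'   .gro multi-frame).
#' @param ... method arguments.
#' @export
setGeneric("writeTrajectory", function(x, path, ...)
  standardGeneric("writeTrajectory"))

## ---- accessors ----

#' @describeIn nFrames frame count
#' @export
setMethod("nFrames", "Trajectory", function(x) nrow(x@xyz))

#' @describeIn topology atom table
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @describeIn frameCoords one frame as an (atoms x 3) matrix
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= nrow(x@xyz))
  matrix(x@xyz[frame, ], ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
})

#' Occupancy fractions of a WireOccupancyResult
#'
#' @param x a \linkS4class{WireOccupancyResult}.
#' @param which "subunit" (named vector), "mean", or "max".
#' @return numeric.
#' @export
occupancyFraction <- function(x, which = c("mean", "max", "subunit")) {
  stopifnot(is(x, "WireOccupancyResult"))
  switch(match.arg(which), mean = x@phiMean, max = x@phiMax, subunit = x@phi)
}

#' Per-frame water counts of a WireOccupancyResult
#' @param x a \linkS4class{WireOccupancyResult}.
#' @return integer matrix, frames x subunits.
#' @export
wireCounts <- function(x) {
  stopifnot(is(x, "WireOccupancyResult"))
  x@counts
}

#' Grid, values and bootstrap error of a PMF profile
#' @param x a \linkS4class{PMFProfile}.
#' @return data.frame with columns z, W, sd, empty.
#' @export
pmfTable <- function(x) {
  stopifnot(is(x, "PMFProfile"))
  data.frame(z = x@z, W = x@W, sd = x@sd, empty = x@emptyBins)
}

#' Site table of a ProtonProfile
#' @param x a \linkS4class{ProtonProfile}.
#' @export
protonSites <- function(x) {
  stopifnot(is(x, "ProtonProfile"))
  x@sites
}

#' Decay rate (1/t1) of a DecayFit
#' @param x a \linkS4class{DecayFit}.
#' @export
decayRate <- function(x) {
  stopifnot(is(x, "DecayFit"))
  x@rate
}

#' Fitted decay parameters as a named vector
#' @param x a \linkS4class{DecayFit}.
#' @export
decayParams <- function(x) {
  stopifnot(is(x, "DecayFit"))
  c(y0 = x@y0, A1 = x@A1, t1 = x@t1)
}

#' Window samples of an UmbrellaWindow
#' @param x an \linkS4class{UmbrellaWindow}.
#' @export
windowSamples <- function(x) {
  stopifnot(is(x, "UmbrellaWindow"))
  x@samples
}

#' Station table of a PoreProfile
#' @param x a \linkS4class{PoreProfile}.
#' @export
poreStations <- function(x) {
  stopifnot(is(x, "PoreProfile"))
  x@stations
}

## ---- show methods ----

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %d atoms", nrow(object@xyz),
              nrow(object@topology)))
  ch <- unique(object@topology$chain)
  cat(sprintf(", chains: %s\n", paste(ch, collapse = " ")))
  if (!is.null(object@metadata$tautomer))
    cat(" tautomer state:", object@metadata$tautomer, "\n")
  cat(sprintf(" time: %.1f .. %.1f ps\n", min(object@time), max(object@time)))
})

setMethod("show", "WireOccupancyResult", function(object) {
  cat(sprintf("WireOccupancyResult: region %s, tautomer %s, tau = %g\n",
              object@region, object@tautomer, object@threshold))
  cat(sprintf(" %d frames x %d subunit(s); phi mean = %.3f, max = %.3f\n",
              nrow(object@counts), ncol(object@counts), object@phiMean,
              object@phiMax))
})

setMethod("show", "PoreProfile", function(object) {
  st <- object@stations
  cat(sprintf("PoreProfile: %d stations, z in [%.2f, %.2f] A, step %.2f A\n",
              nrow(st), min(st$z), max(st$z), object@step))
  cat(sprintf(" radius: min %.2f A at z = %.2f, max %.2f A\n",
              min(st$radius), st$z[which.min(st$radius)], max(st$radius)))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf(
    "UmbrellaWindow: z0 = %.2f A, k = %g kJ/mol/nm^2, %d samples, T = %g K\n",
    object@center, object@k, length(object@samples), object@temperature))
})

setMethod("show", "PMFProfile", function(object) {
  ok <- is.finite(object@W)
  cat(sprintf("PMFProfile: %d bins, z in [%.2f, %.2f] A (%s)\n",
              length(object@z), min(object@z), max(object@z),
              object@reference))
  if (any(ok))
    cat(sprintf(" W: 0 .. %.2f kJ/mol; %d empty bin(s)\n",
                max(object@W[ok]), sum(object@emptyBins)))
})

setMethod("show", "ProtonProfile", function(object) {
  cat(sprintf("ProtonProfile: %d sites (%s)\n", nrow(object@sites),
              object@valueType))
  print(object@sites, row.names = FALSE)
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples, %.3g .. %.3g s\n",
              length(object@time), min(object@time), max(object@time)))
  md <- object@metadata
  lab <- c(md$variant, md$substrate,
           if (!is.null(md$lpr)) paste0("LPR ", md$lpr))
  if (length(lab)) cat(" ", paste(lab, collapse = " / "), "\n")
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit: y0 = %.3g nA, A1 = %.3g nA, t1 = %.4g s (rate %.4g 1/s)%s\n",
    object@y0, object@A1, object@t1, object@rate,
    if (object@flat) " [flat]" else ""))
})

setMethod("show", "KineticsFit", function(object) {
  if (object@saturating)
    cat(sprintf("KineticsFit: Km = %.3g mM, Imax = %.3g (saturating)\n",
                object@km, object@imax))
  else
    cat(sprintf(
      "KineticsFit: Km not measurable in [%g, %g] mM (non-saturating)\n",
      object@concRange[1], object@concRange[2]))
})
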