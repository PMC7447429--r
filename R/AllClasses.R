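## Central S4 containers. Validity methods enforce the structural
## invariants; constructors live next to the code that fills them.

#' Trajectory: time-ordered atomic coordinates with one shared topology
#'
#' Coordinates are stored bio3d-style: one row per frame, columns
#' \code{(x1, y1, z1, x2, ...)}, in Angstrom. The topology is a data.frame
#' with bio3d column names (\code{eleno}, \code{elety}, \code{resid} =
#' residue name, \code{resno}, \code{chain}, \code{elesy} = element).
#' \code{box} holds per-frame orthorhombic box lengths (Angstrom); a row of
#' zeros means "no periodic cell".
#'
#' @slot topology data.frame of atom records shared by every frame.
#' @slot xyz numeric matrix, frames x (3 * atoms), Angstrom.
#' @slot time numeric vector of frame times (ps).
#' @slot box numeric matrix, frames x 3, Angstrom.
#' @slot metadata list of free-form annotations (e.g. tautomer label,
#'   generator ground truth).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(topology = "data.frame", xyz = "matrix", time = "numeric",
                 box = "matrix", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character()
    nat <- nrow(object@topology)
    if (ncol(object@xyz) != 3L * nat)
      msg <- c(msg, sprintf("xyz has %d columns; topology implies %d",
                            ncol(object@xyz), 3L * nat))
    if (!all(is.finite(object@xyz)))
      msg <- c(msg, "coordinates must be finite")
    if (length(object@time) != nrow(object@xyz))
      msg <- c(msg, "time must have one entry per frame")
    if (nrow(object@box) != nrow(object@xyz) || ncol(object@box) != 3L)
      msg <- c(msg, "box must be an (nframes x 3) matrix")
    if (nrow(object@xyz) < 1L) msg <- c(msg, "at least one frame required")
    if (length(msg)) msg else TRUE
  })

#' WireRegion: geometric definition of a water-wire compartment
#'
#' A region is the finite cylinder between the centroids of two anchor atom
#' selections (e.g. the D160 carboxylate above and the H168 sidechain below
#' for the periplasmic wire), padded by \code{zPad} along the axis, with
#' radius \code{radialCutoff} around the anchor-to-anchor axis. Anchor
#' selectors are named lists matched against topology columns
#' (\code{resno}, \code{resid}, \code{elety}, \code{chain}).
#'
#' @slot name region label, e.g. "PWW" or "CWW".
#' @slot anchorTop,anchorBottom atom selectors (named lists).
#' @slot radialCutoff radial cutoff from the region axis (Angstrom).
#' @slot zPad axial padding beyond the anchor planes (Angstrom).
#' @slot subunit chain id the region is tied to; NA means "every chain in
#'   which both anchors resolve".
#' @exportClass WireRegion
setClass("WireRegion",
  representation(name = "character", anchorTop = "list",
                 anchorBottom = "list", radialCutoff = "numeric",
                 zPad = "numeric", subunit = "character"),
  prototype(radialCutoff = 6.0, zPad = 1.0, subunit = NA_character_),
  validity = function(object) {
    msg <- character()
    if (!length(object@anchorTop) || !length(object@anchorBottom))
      msg <- c(msg, "both anchor selectors must be non-empty")
    if (object@radialCutoff <= 0) msg <- c(msg, "radialCutoff must be > 0")
    if (object@zPad < 0) msg <- c(msg, "zPad must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' WireOccupancyResult: per-frame water counts and occupancy fractions
#'
#' @slot counts integer matrix, frames x subunits, water counts.
#' @slot region region name the counts refer to.
#' @slot tautomer tautomer label of the underlying simulation ("DE"/"ED").
#' @slot threshold water-count cutoff tau used for the occupancy.
#' @slot phi per-subunit occupancy fractions (named).
#' @slot phiMean mean occupancy over subunits.
#' @slot phiMax maximum occupancy over subunits (the "up to" statistic).
#' @slot time frame times (ps).
#' @exportClass WireOccupancyResult
setClass("WireOccupancyResult",
  representation(counts = "matrix", region = "character",
                 tautomer = "character", threshold = "numeric",
                 phi = "numeric", phiMean = "numeric", phiMax = "numeric",
                 time = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@phi < 0 | object@phi > 1))
      msg <- c(msg, "occupancy fractions must lie in [0, 1]")
    if (object@threshold < 0) msg <- c(msg, "threshold must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PoreProfile: maximal-inscribed-sphere radius along a channel axis
#'
#' @slot stations data.frame with columns z, x, y, radius, capped
#'   (z along the pore axis, x/y the optimised in-plane centre, all
#'   Angstrom; capped flags stations where the in-plane maximisation hit
#'   the configured maximum radius).
#' @slot axis unit vector of the pore axis in the input frame.
#' @slot step station spacing (Angstrom).
#' @exportClass PoreProfile
setClass("PoreProfile",
  representation(stations = "data.frame", axis = "numeric", step = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("z", "x", "y", "radius", "capped")
    if (!all(need %in% names(object@stations)))
      msg <- c(msg, "stations must have columns z, x, y, radius, capped")
    else {
      dz <- diff(object@stations$z)
      if (length(dz) && !(all(dz > 0) || all(dz < 0)))
        msg <- c(msg, "station z must be strictly monotone")
      if (any(object@stations$radius < 0))
        msg <- c(msg, "radius must be >= 0 at every station")
    }
    if (length(msg)) msg else TRUE
  })

#' UmbrellaWindow: biased samples of a 1-D coordinate
#'
#' @slot center restraint centre z0 (Angstrom).
#' @slot k harmonic force constant along z, kJ/mol/nm^2 (MD pull-code
#'   convention; converted internally).
#' @slot flatBottom list describing an optional in-plane flat-bottom
#'   restraint (radius, k); carried as metadata only, since a restraint
#'   constant in z contributes no z-dependent bias.
#' @slot samples sampled z values (Angstrom).
#' @slot temperature K.
#' @exportClass UmbrellaWindow
setClass("UmbrellaWindow",
  representation(center = "numeric", k = "numeric", flatBottom = "list",
                 samples = "numeric", temperature = "numeric"),
  prototype(flatBottom = list(), temperature = 310),
  validity = function(object) {
    msg <- character()
    if (object@k <= 0) msg <- c(msg, "force constant k must be > 0")
    if (!length(object@samples) || !all(is.finite(object@samples)))
      msg <- c(msg, "samples must be non-empty and finite")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    if (length(msg)) msg else TRUE
  })

#' PMFProfile: reconstructed 1-D free-energy profile
#'
#' @slot z bin centres (Angstrom).
#' @slot W free energy (kJ/mol), anchored so min(W) = 0 under the
#'   "anchor-min" convention; NA at bins with zero counts.
#' @slot sd pointwise standard deviation from the Bayesian bootstrap
#'   (kJ/mol); zeros before a bootstrap has been run.
#' @slot reference anchoring convention tag ("anchor-min" or a site label).
#' @slot emptyBins logical flags for zero-count bins.
#' @slot details list: window free energies f (kJ/mol), iterations,
#'   residual, temperature, bin width.
#' @exportClass PMFProfile
setClass("PMFProfile",
  representation(z = "numeric", W = "numeric", sd = "numeric",
                 reference = "character", emptyBins = "logical",
                 details = "list"),
  prototype(reference = "anchor-min", details = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@W) != length(object@z))
      msg <- c(msg, "W and z must have equal length")
    if (length(object@sd) != length(object@z))
      msg <- c(msg, "sd and z must have equal length")
    if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    ok <- is.finite(object@W)
    if (identical(object@reference, "anchor-min") && any(ok) &&
        abs(min(object@W[ok]) - 0) > 1e-6)
      msg <- c(msg, "under the anchor-min convention min(W) must be 0")
    if (length(msg)) msg else TRUE
  })

#' ProtonProfile: labelled sites along z with free energies or pKa values
#'
#' Site table for proton translocation along the periplasmic and
#' cytoplasmic water wires. \code{z} is measured relative to the H168
#' sidechain; \code{value} is either a free energy (kJ/mol) or a pKa,
#' according to \code{valueType}.
#'
#' @slot sites data.frame with columns label, wire, z, value.
#' @slot valueType "dG" (kJ/mol) or "pKa".
#' @slot reference label of the zero-reference site (NA if min-anchored or
#'   not yet referenced).
#' @exportClass ProtonProfile
setClass("ProtonProfile",
  representation(sites = "data.frame", valueType = "character",
                 reference = "character"),
  prototype(reference = NA_character_),
  validity = function(object) {
    msg <- character()
    need <- c("label", "z", "value")
    if (!all(need %in% names(object@sites)))
      msg <- c(msg, "sites must have columns label, z, value")
    else {
      if (anyDuplicated(object@sites$label))
        msg <- c(msg, "site labels must be unique")
      if (!all(is.finite(object@sites$z)))
        msg <- c(msg, "site z coordinates must be finite")
    }
    if (!object@valueType %in% c("dG", "pKa"))
      msg <- c(msg, "valueType must be 'dG' or 'pKa'")
    if (length(msg)) msg else TRUE
  })

#' CurrentTrace: an SSME transient-current time series
#'
#' @slot time seconds, strictly increasing.
#' @slot current nA, same length as time.
#' @slot metadata list (variant, substrate, concentration, LPR, pH, solvent,
#'   sensor id, generator ground truth, ...).
#' @exportClass CurrentTrace
setClass("CurrentTrace",
  representation(time = "numeric", current = "numeric", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@current))
      msg <- c(msg, "time and current must have equal length")
    if (length(object@time) > 1L && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' DecayFit: one-phase exponential decay fit of a transient current
#'
#' Model: y(x) = y0 + A1 * exp(-x / t1), x measured from the peak apex.
#'
#' @slot y0 offset (nA).
#' @slot A1 amplitude (nA).
#' @slot t1 time constant (s).
#' @slot rate decay rate 1/t1 (1/s).
#' @slot window fit window c(tApex, tBaseline) in trace time (s).
#' @slot cov 3x3 covariance matrix of (y0, A1, t1).
#' @slot flat TRUE when |A1| is below the noise floor (no resolvable decay).
#' @slot details list (sigma, df, nPoints, baseline, noise).
#' @exportClass DecayFit
setClass("DecayFit",
  representation(y0 = "numeric", A1 = "numeric", t1 = "numeric",
                 rate = "numeric", window = "numeric", cov = "matrix",
                 flat = "logical", details = "list"),
  prototype(flat = FALSE, details = list()),
  validity = function(object) {
    msg <- character()
    if (object@t1 <= 0) msg <- c(msg, "t1 must be > 0")
    if (abs(object@rate * object@t1 - 1) > 1e-12)
      msg <- c(msg, "rate must equal 1/t1")
    if (length(msg)) msg else TRUE
  })

#' KineticsFit: Michaelis-Menten fit of amplitude vs concentration
#'
#' @slot km Michaelis constant (mM); NA when not measurable.
#' @slot imax fitted maximal (normalised) amplitude.
#' @slot saturating FALSE when the fitted Km exceeds the tested range or its
#'   confidence interval is unbounded above (Km then "not measurable").
#' @slot concRange range of tested concentrations (mM).
#' @slot se named standard errors of (imax, km).
#' @exportClass KineticsFit
setClass("KineticsFit",
  representation(km = "numeric", imax = "numeric", saturating = "logical",
                 concRange = "numeric", se = "numeric"),
  validity = function(object) {
    if (isTRUE(object@saturating) && (is.na(object@km) || object@km <= 0))
      "km must be a positive number when saturating" else TRUE
  })

#' RunConfig: validated pipeline configuration
#'
#' @slot config named list of settings (see \code{\link{defaultRunConfig}}).
#' @exportClass RunConfig
setClass("RunConfig", representation(config = "list"))
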