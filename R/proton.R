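## Proton-translocation free-energy profiles. The microscopic pKa
## computation is upstream of this package; here, per-site pKa or free
## energy values along the two water wires (z relative to the H168
## sidechain) are turned into translocation profiles and barrier calls.

#' Construct a ProtonProfile from a site table
#'
#' @param sites data.frame with columns \code{label}, \code{z} (Angstrom,
#'   relative to the H168 sidechain), \code{value}, and optionally
#'   \code{wire} ("periplasmic"/"cytoplasmic").
#' @param valueType "dG" (kJ/mol) or "pKa".
#' @param reference label of the zero-reference site, if any.
#' @return a \linkS4class{ProtonProfile}.
#' @export
ProtonProfile <- function(sites, valueType = c("dG", "pKa"),
                          reference = NA_character_) {
  valueType <- match.arg(valueType)
  if (!"wire" %in% names(sites)) sites$wire <- NA_character_
  new("ProtonProfile",
      sites = sites[, c("label", "wire", "z", "value")],
      valueType = valueType, reference = reference)
}

#' Load the packaged per-site proton-translocation free energies
#'
#' Free energies (kJ/mol) for protonating individual water sites along the
#' periplasmic and cytoplasmic water wires of E. coli AmtB, referenced to
#' the periplasmic bulk site wat1, with z measured relative to the H168
#' sidechain.
#'
#' @param path TSV file; defaults to the packaged table.
#' @return a \linkS4class{ProtonProfile} (valueType "dG", reference
#'   "wat1").
#' @export
loadProtonSites <- function(path = system.file("extdata",
                                               "amtb_proton_sites.tsv",
                                               package = "ammtools")) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[names(df) == "free_energy_kj_mol"] <- "value"
  ProtonProfile(df, valueType = "dG", reference = "wat1")
}

#' Thermodynamic settings for free-energy conversions
#'
#' @param temperature K (default 310, the simulation temperature).
#' @param R gas constant, kJ/(mol K).
#' @return list(temperature, R).
#' @export
thermoSettings <- function(temperature = 310, R = .RGAS) {
  .assertScalarPositive(temperature, "temperature")
  list(temperature = temperature, R = R)
}

#' Convert per-site pKa values to proton-translocation free energies
#'
#' Moving the proton from the reference site to site i costs
#' \code{dG_i = ln(10) * R * T * (pKa_ref - pKa_i)}: a site with a lower
#' pKa holds the proton less favourably, so translocation to it is
#' uphill. The reference site gets exactly zero.
#'
#' @param profile a \linkS4class{ProtonProfile} with pKa values.
#' @param reference label of the reference site (must be present).
#' @param thermo \code{\link{thermoSettings}}.
#' @return a \linkS4class{ProtonProfile} with dG values (kJ/mol).
#' @export
pkaToDg <- function(profile, reference, thermo = thermoSettings()) {
  stopifnot(is(profile, "ProtonProfile"))
  if (profile@valueType != "pKa")
    stop("profile does not hold pKa values")
  sites <- profile@sites
  ri <- match(reference, sites$label)
  if (is.na(ri)) stop("reference site not found: ", reference)
  lnRT <- log(10) * thermo$R * thermo$temperature
  sites$value <- lnRT * (sites$value[ri] - sites$value)
  sites$value[ri] <- 0
  ProtonProfile(sites, valueType = "dG", reference = reference)
}

#' @describeIn barrier barrier over a site list: max(value) minus the
#'   reference value. The reference defaults to the first site of the
#'   (optionally range-restricted) list; pass \code{reference} to use a
#'   named site from the full list instead (e.g. the bulk site when
#'   scanning one wire). Ties are broken toward smaller z.
#' @param reference site label to reference against (ProtonProfile
#'   method).
#' @export
setMethod("barrier", "ProtonProfile",
  function(x, zRange = NULL, reference = NULL, ...) {
    if (x@valueType != "dG")
      stop("convert pKa values with pkaToDg() before calling barrier()")
    sites <- x@sites
    sel <- sites
    if (!is.null(zRange))
      sel <- sites[sites$z >= zRange[1L] & sites$z <= zRange[2L], ,
                   drop = FALSE]
    if (nrow(sel) < 1L) stop("no sites in range")
    refVal <- if (is.null(reference)) {
      if (nrow(sel) < 2L) stop("fewer than two sites in range")
      sel$value[1L]
    } else {
      ri <- match(reference, sites$label)
      if (is.na(ri)) stop("reference site not found: ", reference)
      sites$value[ri]
    }
    cand <- which(sel$value >= max(sel$value) - 1e-12)
    imax <- cand[which.min(sel$z[cand])]   # ties -> smaller z
    list(deltaG = sel$value[imax] - refVal, z = sel$z[imax],
         label = sel$label[imax])
  })

#' Global and per-wire barrier summary of a proton profile
#'
#' Reports the barrier over all sites and over each wire separately, all
#' referenced to the profile's reference site (or the first site).
#'
#' @param profile a \linkS4class{ProtonProfile} with dG values.
#' @return data.frame(scope, deltaG, z, label).
#' @export
wireBarriers <- function(profile) {
  stopifnot(is(profile, "ProtonProfile"))
  sites <- profile@sites
  ref <- if (!is.na(profile@reference)) profile@reference
         else sites$label[1L]
  refVal <- sites$value[match(ref, sites$label)]
  wires <- unique(sites$wire[!is.na(sites$wire)])
  scopes <- c(list(global = sites),
              setNames(lapply(wires, function(w)
                sites[sites$wire %in% w, , drop = FALSE]), wires))
  rows <- lapply(names(scopes), function(nm) {
    sel <- scopes[[nm]]
    cand <- which(sel$value >= max(sel$value) - 1e-12)
    imax <- cand[which.min(sel$z[cand])]
    data.frame(scope = nm, deltaG = sel$value[imax] - refVal,
               z = sel$z[imax], label = sel$label[imax],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a proton site table as TSV (label, wire, z, value)
#'
#' @param profile a \linkS4class{ProtonProfile}.
#' @param path output TSV.
#' @export
writeProtonSites <- function(profile, path) {
  write.table(profile@sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
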