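## Water-wire detection and occupancy statistics. A region is the finite
## cylinder between two anchor-atom centroids (e.g. the D160 carboxylate
## and the H168 sidechain for the periplasmic wire); per-frame counts of
## water oxygens inside it, chain continuity through an O-O hydrogen-bond
## graph, and occupancy fractions under the >= tau water cutoff.

#' Construct a WireRegion
#'
#' @param name region label ("PWW", "CWW", or custom).
#' @param anchorTop,anchorBottom atom selectors: named lists whose entries
#'   are matched against topology columns \code{resno}, \code{resid},
#'   \code{elety}, \code{chain}, e.g. \code{list(resid = "ASP", resno =
#'   160)}.
#' @param radialCutoff radial cutoff from the region axis (Angstrom,
#'   default 6; the boundary is closed, waters exactly on it count).
#' @param zPad axial padding beyond the anchor centroid planes (Angstrom).
#' @param subunit chain id, or NA for every chain in which both anchors
#'   resolve.
#' @return a \linkS4class{WireRegion}.
#' @export
WireRegion <- function(name, anchorTop, anchorBottom, radialCutoff = 6,
                       zPad = 1, subunit = NA_character_) {
  new("WireRegion", name = name, anchorTop = anchorTop,
      anchorBottom = anchorBottom, radialCutoff = radialCutoff,
      zPad = zPad, subunit = subunit)
}

#' Select atom indices by topology fields
#'
#' @param topology a trajectory topology data.frame.
#' @param selector named list; entries matched (set membership) against the
#'   corresponding topology columns.
#' @param chain optional chain restriction applied on top of the selector.
#' @return integer atom indices.
#' @export
atomSelect <- function(topology, selector, chain = NULL) {
  keep <- rep(TRUE, nrow(topology))
  for (key in names(selector)) {
    if (!key %in% names(topology))
      stop("unknown selector field: ", key)
    keep <- keep & topology[[key]] %in% selector[[key]]
  }
  if (!is.null(chain) && !is.na(chain)) keep <- keep & topology$chain %in% chain
  which(keep)
}

.waterOxygenIdx <- function(topology) {
  which(topology$resid %in% .WATER_RESNAMES &
        trimws(topology$elety) %in% .WATER_O_NAMES)
}

## chains in which both anchors of `region` resolve
.regionChains <- function(topology, region) {
  if (!is.na(region@subunit)) {
    chains <- region@subunit
  } else {
    chains <- sort(unique(topology$chain[.waterOxygenIdx(topology)]))
    if (!length(chains)) chains <- sort(unique(topology$chain))
  }
  ok <- vapply(chains, function(ch)
    length(atomSelect(topology, region@anchorTop, ch)) > 0L &&
    length(atomSelect(topology, region@anchorBottom, ch)) > 0L,
    logical(1L))
  if (!any(ok))
    stop(sprintf(
      "region '%s': anchors do not resolve in any chain", region@name))
  chains[ok]
}

## minimum-image displacement of points towards a reference, orthorhombic
.pbcWrap <- function(d, box) {
  if (all(box <= 0)) return(d)
  for (k in 1:3) if (box[k] > 0)
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## geometry worker: water positions (mapped to the image nearest the
## region centroid) inside the padded anchor-to-anchor cylinder.
## Returns indices into `watIdx`.
.watersInRegion <- function(coords, box, topIdx, botIdx, watIdx, region) {
  a <- colMeans(coords[botIdx, , drop = FALSE])
  b <- colMeans(coords[topIdx, , drop = FALSE])
  axis <- b - a
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop(sprintf(
    "region '%s': anchor centroids coincide", region@name))
  u <- axis / len
  centroid <- (a + b) / 2
  w <- coords[watIdx, , drop = FALSE]
  if (!length(watIdx)) return(integer())
  ## map each water to the periodic image nearest the region centroid
  d <- .pbcWrap(sweep(w, 2L, centroid), box)
  w <- sweep(d, 2L, centroid, `+`)
  rel <- sweep(w, 2L, a)
  s <- drop(rel %*% u)
  perp2 <- rowSums(rel^2) - s^2
  which(s >= -region@zPad & s <= len + region@zPad &
        perp2 <= region@radialCutoff^2 + 1e-9)
}

#' Count water oxygens inside a wire region for one frame
#'
#' Waters are identified by residue name (HOH/SOL/TIP3/WAT) and oxygen atom
#' name; each is mapped to the periodic image nearest the region centroid
#' before testing. The region is the cylinder of radius
#' \code{radialCutoff} around the axis joining the anchor centroids,
#' extended by \code{zPad} beyond the anchor planes; boundaries are closed
#' (a water exactly on the cutoff counts).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param region a \linkS4class{WireRegion}.
#' @param frame frame index (default 1).
#' @return named integer vector of counts, one per resolved subunit.
#' @export
countRegionWaters <- function(traj, region, frame = 1L) {
  stopifnot(is(traj, "Trajectory"), is(region, "WireRegion"))
  top <- traj@topology
  chains <- .regionChains(top, region)
  coords <- frameCoords(traj, frame)
  box <- traj@box[frame, ]
  out <- vapply(chains, function(ch) {
    ti <- atomSelect(top, region@anchorTop, ch)
    bi <- atomSelect(top, region@anchorBottom, ch)
    wi <- intersect(.waterOxygenIdx(top), which(top$chain == ch))
    length(.watersInRegion(coords, box, ti, bi, wi, region))
  }, integer(1L))
  setNames(out, chains)
}

#' Is the water wire continuous across a region?
#'
#' Builds an undirected graph whose nodes are the region's water oxygens
#' plus the two anchor atom sets, with edges between nodes at most
#' \code{dLink} apart (the O-O hydrogen-bond heuristic; no angular
#' criterion is applied), and asks whether the top anchors connect to the
#' bottom anchors.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param region a \linkS4class{WireRegion}.
#' @param frame frame index.
#' @param dLink linking distance (Angstrom, default 3.5), > 0.
#' @param subunit chain id; defaults to the region's subunit or the first
#'   resolved chain.
#' @return logical.
#' @export
wireIsContinuous <- function(traj, region, frame = 1L, dLink = 3.5,
                             subunit = NULL) {
  .assertScalarPositive(dLink, "dLink")
  top <- traj@topology
  ch <- subunit %||% (if (!is.na(region@subunit)) region@subunit
                      else .regionChains(top, region)[1L])
  coords <- frameCoords(traj, frame)
  box <- traj@box[frame, ]
  ti <- atomSelect(top, region@anchorTop, ch)
  bi <- atomSelect(top, region@anchorBottom, ch)
  wi <- intersect(.waterOxygenIdx(top), which(top$chain == ch))
  keep <- .watersInRegion(coords, box, ti, bi, wi, region)
  wsel <- wi[keep]
  ## node order: top anchors, bottom anchors, waters
  idx <- c(ti, bi, wsel)
  centroid <- colMeans(coords[c(ti, bi), , drop = FALSE])
  pts <- sweep(.pbcWrap(sweep(coords[idx, , drop = FALSE], 2L, centroid),
                        box), 2L, centroid, `+`)
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  adj <- dm <= dLink + 1e-9
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  topNodes <- seq_along(ti)
  botNodes <- length(ti) + seq_along(bi)
  any(outer(comp[topNodes], comp[botNodes], `==`))
}

## occupancy fraction phi(tau) from a counts matrix (frames x subunits)
.occupancyFromCounts <- function(counts, tau) {
  phi <- colMeans(counts >= tau)
  list(phi = phi, mean = mean(phi), max = max(phi))
}

#' @describeIn occupancy water-wire occupancy of a trajectory region:
#'   per-subunit fraction of frames with at least \code{tau} waters, plus
#'   the mean and maximum over subunits.
#' @param region a \linkS4class{WireRegion}.
#' @param tau water-count cutoff (default 3, the per-subunit cutoff used
#'   to call a water chain "complete").
#' @param frames frame indices to analyse (default: all; use a stride here
#'   to subsample).
#' @param tautomer tautomer label; defaults to the trajectory metadata.
#' @export
setMethod("occupancy", "Trajectory",
  function(x, region, tau = 3, frames = NULL, tautomer = NULL, ...) {
    if (tau < 0) stop("tau must be >= 0")
    if (nrow(x@xyz) < 1L) stop("empty trajectory")
    frames <- frames %||% seq_len(nrow(x@xyz))
    if (!length(frames)) stop("no frames selected")
    top <- x@topology
    chains <- .regionChains(top, region)
    counts <- matrix(0L, length(frames), length(chains),
                     dimnames = list(NULL, chains))
    wat <- .waterOxygenIdx(top)
    sel <- lapply(chains, function(ch) list(
      ti = atomSelect(top, region@anchorTop, ch),
      bi = atomSelect(top, region@anchorBottom, ch),
      wi = intersect(wat, which(top$chain == ch))))
    for (fi in seq_along(frames)) {
      coords <- frameCoords(x, frames[fi])
      box <- x@box[frames[fi], ]
      for (ci in seq_along(chains)) {
        s <- sel[[ci]]
        counts[fi, ci] <- length(
          .watersInRegion(coords, box, s$ti, s$bi, s$wi, region))
      }
    }
    occ <- .occupancyFromCounts(counts, tau)
    new("WireOccupancyResult", counts = counts, region = region@name,
        tautomer = tautomer %||% (x@metadata$tautomer %||% NA_character_),
        threshold = tau, phi = occ$phi, phiMean = occ$mean,
        phiMax = occ$max, time = x@time[frames])
  })

#' Re-threshold an occupancy result
#'
#' Recomputes the occupancy fractions from the stored counts at a new
#' cutoff without touching the trajectory.
#'
#' @param result a \linkS4class{WireOccupancyResult}.
#' @param tau new cutoff.
#' @return a \linkS4class{WireOccupancyResult}.
#' @export
rethreshold <- function(result, tau) {
  stopifnot(is(result, "WireOccupancyResult"), tau >= 0)
  occ <- .occupancyFromCounts(result@counts, tau)
  initialize(result, threshold = tau, phi = occ$phi, phiMean = occ$mean,
             phiMax = occ$max)
}

#' Compare occupancy between tautomer states and regions
#'
#' Tabulates mean occupancy, maximum-over-subunit occupancy and water-count
#' variance per (region, tautomer) cell, and the DE - ED difference per
#' region where both states are present.
#'
#' @param results list of \linkS4class{WireOccupancyResult} (each tagged
#'   with region and tautomer).
#' @return data.frame with one row per (region, tautomer) cell and columns
#'   \code{n}, \code{phiMean}, \code{phiMax}, \code{countVariance}; the
#'   per-region DE - ED contrast is attached as attribute
#'   \code{"contrast"}.
#' @export
compareStates <- function(results) {
  if (!length(results)) stop("empty result list")
  stopifnot(all(vapply(results, is, logical(1L), "WireOccupancyResult")))
  key <- vapply(results, function(r)
    paste(r@region, r@tautomer, sep = "\r"), character(1L))
  groups <- split(results, key)
  rows <- lapply(groups, function(g) {
    data.frame(
      region = g[[1L]]@region, tautomer = g[[1L]]@tautomer, n = length(g),
      phiMean = mean(vapply(g, function(r) r@phiMean, numeric(1L))),
      phiMax = max(vapply(g, function(r) r@phiMax, numeric(1L))),
      countVariance = mean(vapply(g, function(r)
        mean(apply(r@counts, 2L, var)), numeric(1L))),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(tab$region, tab$tautomer), , drop = FALSE]
  contrasts <- lapply(split(tab, tab$region), function(sub) {
    if (all(c("DE", "ED") %in% sub$tautomer))
      data.frame(region = sub$region[1L],
                 phiMeanDiff = sub$phiMean[sub$tautomer == "DE"] -
                               sub$phiMean[sub$tautomer == "ED"])
  })
  contrasts <- do.call(rbind, Filter(Negate(is.null), contrasts))
  if (!is.null(contrasts)) rownames(contrasts) <- NULL
  attr(tab, "contrast") <- contrasts
  tab
}

#' Write per-frame counts and the occupancy summary to disk
#'
#' Per-frame counts go to a TSV (frame, time, subunit, region, count);
#' the occupancy summary to TSV and JSON.
#'
#' @param result a \linkS4class{WireOccupancyResult}.
#' @param stem output path stem; writes \code{<stem>_counts.tsv},
#'   \code{<stem>_summary.tsv} and \code{<stem>_summary.json}.
#' @return invisibly, the summary as a list.
#' @export
writeOccupancy <- function(result, stem) {
  counts <- result@counts
  long <- data.frame(
    frame = rep(seq_len(nrow(counts)), ncol(counts)),
    time = rep(result@time, ncol(counts)),
    subunit = rep(colnames(counts), each = nrow(counts)),
    region = result@region,
    count = as.vector(counts))
  write.table(long, paste0(stem, "_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- list(region = result@region, tautomer = result@tautomer,
               tau = result@threshold,
               phi = as.list(setNames(result@phi, colnames(counts))),
               phiMean = result@phiMean, phiMax = result@phiMax)
  write.table(
    data.frame(region = summ$region, tautomer = summ$tautomer,
               tau = summ$tau, phiMean = summ$phiMean, phiMax = summ$phiMax),
    paste0(stem, "_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(summ, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
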