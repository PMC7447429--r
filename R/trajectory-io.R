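## Structure / trajectory reading and writing. PDB (incl. multi-model) and
## DCD go through bio3d; GRO (single- and multi-frame) is parsed here since
## no installed R package reads it. All coordinates are normalised to
## Angstrom internally (GRO files are in nm).

#' Read a structure (+ optional trajectory) into a Trajectory
#'
#' Formats are detected from file extensions: \code{.pdb} (single- or
#' multi-model), \code{.gro} (single- or multi-frame, nm converted to
#' Angstrom), \code{.dcd}. When \code{trajectoryPath} is given, the
#' structure file supplies the topology and the trajectory file the
#' frames; their atom counts must agree.
#'
#' @param structurePath PDB or GRO file.
#' @param trajectoryPath optional multi-model PDB, multi-frame GRO, or DCD.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(structurePath, trajectoryPath = NULL) {
  if (!file.exists(structurePath))
    stop("structure file not found: ", structurePath)
  top <- .readStructure(structurePath)
  if (is.null(trajectoryPath))
    return(new("Trajectory", topology = top$topology, xyz = top$xyz,
               time = seq_len(nrow(top$xyz)) - 1, box = top$box))
  if (!file.exists(trajectoryPath))
    stop("trajectory file not found: ", trajectoryPath)
  ext <- tolower(tools::file_ext(trajectoryPath))
  frames <- switch(ext,
    pdb = , gro = .readStructure(trajectoryPath),
    dcd = {
      xyz <- tryCatch(bio3d::read.dcd(trajectoryPath, verbose = FALSE),
                      error = function(e)
                        stop("unreadable DCD file: ", conditionMessage(e)))
      list(xyz = unclass(xyz),
           box = matrix(0, nrow(xyz), 3L))
    },
    stop("unsupported trajectory format: .", ext))
  nat <- nrow(top$topology)
  if (ncol(frames$xyz) != 3L * nat)
    stop(sprintf(
      "atom-count mismatch: topology has %d atoms but frames have %d",
      nat, ncol(frames$xyz) %/% 3L))
  new("Trajectory", topology = top$topology, xyz = frames$xyz,
      time = seq_len(nrow(frames$xyz)) - 1, box = frames$box)
}

.readStructure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = {
      pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                      error = function(e)
                        stop("unreadable PDB file: ", conditionMessage(e)))
      at <- pdb$atom
      topo <- data.frame(eleno = at$eleno, elety = at$elety,
                         resid = at$resid, resno = at$resno,
                         chain = ifelse(is.na(at$chain), "A", at$chain),
                         elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                                        substr(trimws(at$elety), 1L, 1L),
                                        at$elesy),
                         stringsAsFactors = FALSE)
      xyz <- unclass(pdb$xyz)
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
      list(topology = topo, xyz = xyz, box = matrix(0, nrow(xyz), 3L))
    },
    gro = .readGro(path),
    stop("unsupported structure format: .", ext))
}

## GRO: fixed-width, coordinates in nm; concatenated blocks form a
## plain-text frame series
.readGro <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); boxes <- list(); topo <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO file: bad atom count at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      stop("malformed GRO file: truncated frame")
    block <- lines[i + 1L + seq_len(nat)]
    resno <- as.integer(substr(block, 1L, 5L))
    resnm <- trimws(substr(block, 6L, 10L))
    atnm <- trimws(substr(block, 11L, 15L))
    xyz <- cbind(as.numeric(substr(block, 21L, 28L)),
                 as.numeric(substr(block, 29L, 36L)),
                 as.numeric(substr(block, 37L, 44L))) * 10  # nm -> A
    if (is.null(topo)) {
      topo <- data.frame(eleno = seq_len(nat), elety = atnm, resid = resnm,
                         resno = resno, chain = "A",
                         elesy = substr(atnm, 1L, 1L),
                         stringsAsFactors = FALSE)
    } else if (nat != nrow(topo)) {
      stop(sprintf(
        "atom-count mismatch between GRO frames: %d then %d",
        nrow(topo), nat))
    }
    bx <- as.numeric(strsplit(trimws(lines[i + nat + 2L]), "\\s+")[[1L]])
    frames[[length(frames) + 1L]] <- as.numeric(t(xyz))
    boxes[[length(boxes) + 1L]] <- bx[1:3] * 10
    i <- i + nat + 3L
  }
  if (!length(frames)) stop("malformed GRO file: no frames found")
  list(topology = topo, xyz = do.call(rbind, frames),
       box = do.call(rbind, boxes))
}

#' @describeIn writeTrajectory write as multi-model PDB or multi-frame GRO
#'   (format chosen from the file extension)
#' @export
setMethod("writeTrajectory", "Trajectory", function(x, path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = .writePdb(x, path),
    gro = .writeGro(x, path),
    stop("unsupported output format: .", ext))
  invisible(path)
})

.writePdb <- function(x, path) {
  top <- x@topology
  bio3d::write.pdb(file = path, xyz = x@xyz, eleno = top$eleno,
                   elety = top$elety, resid = top$resid, resno = top$resno,
                   chain = top$chain)
}

.writeGro <- function(x, path) {
  top <- x@topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(x@xyz))) {
    co <- matrix(x@xyz[f, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
    writeLines(sprintf("frame t=%.3f", x@time[f]), con)
    writeLines(sprintf("%5d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resno %% 100000L, substr(top$resid, 1L, 5L),
                       substr(top$elety, 1L, 5L), top$eleno %% 100000L,
                       co[, 1L], co[, 2L], co[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", x@box[f, 1L] / 10,
                       x@box[f, 2L] / 10, x@box[f, 3L] / 10), con)
  }
}

## ---------------------------------------------------------------------
## umbrella-window I/O: two-column delimited text (time, z) mirroring MD
## pull-coordinate output, plus a YAML metadata sidecar per window

#' Write umbrella windows as pull-style text files with YAML sidecars
#'
#' Each window becomes \code{window_###.dat} (two columns: sample index as
#' pseudo-time, z in Angstrom) and \code{window_###.yaml} (center, force
#' constant, temperature, flat-bottom metadata).
#'
#' @param windows list of \linkS4class{UmbrellaWindow}.
#' @param dir output directory (created if needed).
#' @return invisibly, the data file paths.
#' @export
writeUmbrellaWindows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    stem <- file.path(dir, sprintf("window_%03d", i))
    df <- data.frame(time = seq_along(w@samples) - 1, z = w@samples)
    write.table(format(df, digits = 10), paste0(stem, ".dat"),
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    yaml::write_yaml(list(center = w@center, k = w@k,
                          temperature = w@temperature,
                          flat_bottom = w@flatBottom),
                     paste0(stem, ".yaml"))
    paths[i] <- paste0(stem, ".dat")
  }
  invisible(paths)
}

#' Read umbrella windows written by \code{\link{writeUmbrellaWindows}}
#'
#' @param dir directory holding \code{window_*.dat} + \code{window_*.yaml}.
#' @return list of \linkS4class{UmbrellaWindow}.
#' @export
readUmbrellaWindows <- function(dir) {
  dats <- sort(list.files(dir, pattern = "^window_\\d+\\.dat$",
                          full.names = TRUE))
  if (!length(dats)) stop("no window_*.dat files found in ", dir)
  lapply(dats, function(p) {
    meta <- yaml::read_yaml(sub("\\.dat$", ".yaml", p))
    z <- read.table(p, header = FALSE)[[2L]]
    new("UmbrellaWindow", center = meta$center, k = meta$k,
        flatBottom = meta$flat_bottom %||% list(), samples = z,
        temperature = meta$temperature %||% 310)
  })
}

## ---------------------------------------------------------------------
## current-trace I/O: CSV with a '#'-prefixed header block carrying
## metadata (including generator ground truth, if any)

#' Write a current trace as CSV with a metadata header block
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param path output CSV.
#' @export
writeCurrentTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  md <- trace@metadata
  flat <- unlist(md)
  if (length(flat))
    writeLines(sprintf("# %s: %s", names(flat), as.character(flat)), con)
  writeLines("time_s,current_nA", con)
  writeLines(sprintf("%.9g,%.9g", trace@time, trace@current), con)
  invisible(path)
}

#' Read a current trace written by \code{\link{writeCurrentTrace}}
#'
#' @param path CSV with optional '#' metadata header lines.
#' @return a \linkS4class{CurrentTrace}.
#' @export
readCurrentTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  md <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    md[[key]] <- if (is.na(num)) val else num
  }
  df <- read.table(text = lines[!hdr], header = TRUE, sep = ",")
  new("CurrentTrace", time = df[[1L]], current = df[[2L]], metadata = md)
}
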