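## Pipeline driver: validated configuration, stage execution in dependency
## order, and a JSON + Markdown report whose every number is read back
## from a stage output file (the report computes nothing itself).

.CONFIG_KEYS <- list(
  top = c("output_dir", "seed", "stages", "hydration", "pore", "wham",
          "proton", "ssme", "classify"),
  hydration = c("tau", "d_link", "n_frames", "occupancy_de", "occupancy_ed",
                "occupancy_pww_ed"),
  pore = c("step", "spacing", "cylinder_radius", "cylinder_length"),
  wham = c("barrier", "well_halfwidth", "window_spacing", "kz", "n_samples",
           "burn_in", "n_boot", "bin_width", "temperature"),
  proton = c("sites_path"),
  ssme = c("y0", "A1", "t1", "noise_sd", "mm_km", "mm_imax",
           "concentrations"),
  classify = c("rates_path", "ratio_threshold"))

.STAGES <- c("simulate", "hydration", "pore", "wham", "proton", "ssme",
             "classify", "report")

#' Default pipeline configuration
#'
#' Settings mirror the study conditions of the analysis chain: occupancy
#' cutoff tau = 3 waters per subunit, O-O linking distance 3.5 A, window
#' spacing 0.5 A with a 1000 kJ/mol/nm^2 z restraint, T = 310 K, decay
#' traces at 1 kHz, Michaelis-Menten series over 12.5-200 mM, and an LPR
#' rate-ratio threshold of 1.2.
#'
#' @param outputDir run output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return a \linkS4class{RunConfig}.
#' @export
defaultRunConfig <- function(outputDir = tempfile("ammtools_run_"),
                             seed = 1) {
  cfg <- list(
    output_dir = outputDir,
    seed = seed,
    stages = .STAGES,
    hydration = list(tau = 3, d_link = 3.5, n_frames = 2000,
                     occupancy_de = 0.79, occupancy_ed = 0.12,
                     occupancy_pww_ed = 0.23),
    pore = list(step = 0.5, spacing = 0.5, cylinder_radius = 2,
                cylinder_length = 20),
    wham = list(barrier = 10, well_halfwidth = 5, window_spacing = 0.5,
                kz = 1000, n_samples = 2000, burn_in = 500, n_boot = 25,
                bin_width = 0.2, temperature = 310),
    proton = list(sites_path = NULL),
    ssme = list(y0 = 0, A1 = 3, t1 = 0.05, noise_sd = 0.05,
                mm_km = 50, mm_imax = 1,
                concentrations = c(12.5, 25, 50, 100, 200)),
    classify = list(rates_path = NULL, ratio_threshold = 1.2))
  validateRunConfig(cfg)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys, checks that all thresholds are positive, and
#' confirms the configuration round-trips losslessly through YAML.
#'
#' @param config named list (or \linkS4class{RunConfig}, or path to a YAML
#'   file).
#' @return a validated \linkS4class{RunConfig}.
#' @export
validateRunConfig <- function(config) {
  if (is(config, "RunConfig")) config <- config@config
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .CONFIG_KEYS$top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (sect in intersect(names(.CONFIG_KEYS), names(config))) {
    bad <- setdiff(names(config[[sect]]), .CONFIG_KEYS[[sect]])
    if (length(bad))
      stop(sprintf("unknown config keys in '%s': %s", sect,
                   paste(bad, collapse = ", ")))
  }
  pos <- c(hydration.tau = config$hydration$tau,
           hydration.d_link = config$hydration$d_link,
           pore.step = config$pore$step,
           pore.spacing = config$pore$spacing,
           wham.kz = config$wham$kz,
           classify.ratio_threshold = config$classify$ratio_threshold)
  for (nm in names(pos))
    if (!is.null(pos[[nm]]) && pos[[nm]] <= 0)
      stop("config threshold must be positive: ", nm)
  bad <- setdiff(config$stages, .STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  ## YAML round-trip must be lossless
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  back <- yaml::read_yaml(tmp)
  if (!isTRUE(all.equal(back, config, tolerance = 1e-9)))
    stop("config does not round-trip through YAML losslessly")
  new("RunConfig", config = config)
}

.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 131L + match(stage, .STAGES) * 7919L) %% 2147483629L
}

.writeStageSummary <- function(dir, stage, summary) {
  jsonlite::write_json(summary, file.path(dir, stage, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order (simulate, hydration,
#' pore, wham, proton, ssme, classify, report), writing every stage's
#' outputs under \code{output_dir/<stage>/} and, at the end, a combined
#' \code{report.json} + \code{report.md} stamped with the configuration
#' hash and seed. All report numbers are read back from stage output
#' files. A stage failure aborts the run naming the stage; partial
#' outputs are kept next to a \code{FAILED} marker.
#'
#' @param config a \linkS4class{RunConfig}, a named list, or the path to
#'   a YAML configuration (see \code{\link{defaultRunConfig}}).
#' @param quiet suppress stage progress messages on stderr.
#' @return invisibly, the report as a list.
#' @export
runPipeline <- function(config = defaultRunConfig(), quiet = FALSE) {
  rc <- validateRunConfig(config)
  cfg <- rc@config
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "output_dir")], cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  say <- function(stage, msg) if (!quiet)
    message(sprintf("[%s] %s", stage, msg))
  state <- new.env(parent = emptyenv())
  stages <- intersect(.STAGES, cfg$stages)  # dependency order
  for (stage in setdiff(stages, "report"))
    dir.create(file.path(out, stage), showWarnings = FALSE)
  for (stage in stages) {
    say(stage, "running")
    ok <- tryCatch({
      switch(stage,
        simulate = .stageSimulate(cfg, out, state),
        hydration = .stageHydration(cfg, out, state),
        pore = .stagePore(cfg, out, state),
        wham = .stageWham(cfg, out, state),
        proton = .stageProton(cfg, out, state),
        ssme = .stageSsme(cfg, out, state),
        classify = .stageClassify(cfg, out, state),
        report = .stageReport(cfg, out, cfgHash, state))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      writeLines(c(stage, conditionMessage(ok)), file.path(out, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(ok)))
    }
  }
  invisible(state$report)
}

.stageSimulate <- function(cfg, out, state) {
  h <- cfg$hydration
  seed <- .stageSeed(cfg$seed, "simulate")
  mk <- function(tautomer, pCww, pPww, sd) {
    genToyPoreTrajectory(ToyPoreSpec(
      occupancyChain = list(PWW = twoStateChain(c(0, 3), pPww),
                            CWW = twoStateChain(c(2, 4), pCww)),
      tautomerLabel = tautomer, nFrames = h$n_frames, seed = sd))
  }
  state$trajDE <- mk("DE", h$occupancy_de, 0.10, seed)
  state$trajED <- mk("ED", h$occupancy_ed, h$occupancy_pww_ed, seed + 1L)
  ## a short demonstration excerpt on disk; full trajectories stay in
  ## memory (they are regenerable from the seed)
  excerpt <- state$trajDE
  excerpt@xyz <- excerpt@xyz[1:5, , drop = FALSE]
  excerpt@time <- excerpt@time[1:5]
  excerpt@box <- excerpt@box[1:5, , drop = FALSE]
  writeTrajectory(excerpt, file.path(out, "simulate", "toy_pore_DE.pdb"))
  w <- cfg$wham
  spec <- doubleWellSpec(height = w$barrier, a = w$well_halfwidth,
                         temperature = w$temperature)
  centers <- seq(-2 * w$well_halfwidth, 2 * w$well_halfwidth,
                 by = w$window_spacing)
  state$pmfSpec <- spec
  state$windows <- genUmbrellaSamples(spec, centers, kz = w$kz,
                                      nSamples = w$n_samples,
                                      burnIn = w$burn_in, seed = seed + 2L)
  writeUmbrellaWindows(state$windows, file.path(out, "simulate", "windows"))
  s <- cfg$ssme
  state$trace <- genCurrentTrace(TraceSpec(y0 = s$y0, A1 = s$A1, t1 = s$t1,
                                           noiseSd = s$noise_sd,
                                           seed = seed + 3L))
  writeCurrentTrace(state$trace, file.path(out, "simulate", "trace.csv"))
  state$mmSat <- genMMSeries(s$mm_imax, s$mm_km, s$concentrations,
                             seed = seed + 4L)
  state$mmLin <- genMMSeries(s$mm_imax, Inf, s$concentrations,
                             seed = seed + 5L)
  write.csv(state$mmSat, file.path(out, "simulate", "mm_saturating.csv"),
            row.names = FALSE)
  write.csv(state$mmLin, file.path(out, "simulate", "mm_linear.csv"),
            row.names = FALSE)
  .writeStageSummary(out, "simulate", list(
    n_frames = h$n_frames,
    ground_truth = list(occupancy_de = h$occupancy_de,
                        occupancy_ed = h$occupancy_ed,
                        occupancy_pww_ed = h$occupancy_pww_ed,
                        wham_barrier = w$barrier, t1 = s$t1,
                        mm_km = s$mm_km)))
}

.stageHydration <- function(cfg, out, state) {
  if (is.null(state$trajDE)) .stageSimulate(cfg, out, state)
  h <- cfg$hydration
  results <- list()
  for (tr in list(state$trajDE, state$trajED)) {
    regions <- toyPoreRegions(tr@metadata$spec)
    for (rg in regions) {
      r <- occupancy(tr, rg, tau = h$tau)
      results[[length(results) + 1L]] <- r
      writeOccupancy(r, file.path(out, "hydration",
                                  paste0(rg@name, "_", r@tautomer)))
    }
  }
  tab <- compareStates(results)
  write.table(tab, file.path(out, "hydration", "state_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$hydration <- results
  cww <- function(tau) vapply(results, function(r)
    if (r@region == "CWW" && r@tautomer == tau) r@phiMean else NA_real_,
    numeric(1L))
  .writeStageSummary(out, "hydration", list(
    tau = h$tau,
    occupancy_cww_de = max(cww("DE"), na.rm = TRUE),
    occupancy_cww_ed = max(cww("ED"), na.rm = TRUE),
    occupancy_pww_ed_max = max(vapply(results, function(r)
      if (r@region == "PWW" && r@tautomer == "ED") r@phiMax else NA_real_,
      numeric(1L)), na.rm = TRUE)))
}

.stagePore <- function(cfg, out, state) {
  p <- cfg$pore
  struct <- cylinderStructure(radius = p$cylinder_radius,
                              length = p$cylinder_length)
  prof <- findPoreProfile(struct, zRange = c(1, p$cylinder_length - 1),
                          step = p$step,
                          seed = .stageSeed(cfg$seed, "pore"))
  seeds <- writePoreProfile(prof, file.path(out, "pore", "cylinder"),
                            spacing = p$spacing)
  state$poreProfile <- prof
  .writeStageSummary(out, "pore", list(
    n_stations = nrow(poreStations(prof)),
    radius_mean = mean(poreStations(prof)$radius),
    radius_true = p$cylinder_radius,
    n_seed_points = nrow(seeds)))
}

.stageWham <- function(cfg, out, state) {
  if (is.null(state$windows)) .stageSimulate(cfg, out, state)
  w <- cfg$wham
  prof <- bayesianBootstrap(state$windows, nBoot = w$n_boot,
                            seed = .stageSeed(cfg$seed, "wham"),
                            binWidth = w$bin_width)
  writePMF(prof, file.path(out, "wham", "pmf.tsv"))
  b <- barrier(prof, zRange = c(-w$well_halfwidth, 0))
  state$pmf <- prof
  .writeStageSummary(out, "wham", list(
    barrier_kj_mol = b$deltaG, barrier_z = b$z,
    barrier_true_kj_mol = w$barrier,
    median_sd_kj_mol = median(prof@sd[is.finite(prof@W)])))
}

.stageProton <- function(cfg, out, state) {
  sites <- if (is.null(cfg$proton$sites_path)) loadProtonSites()
           else loadProtonSites(cfg$proton$sites_path)
  tab <- wireBarriers(sites)
  write.table(tab, file.path(out, "proton", "barriers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeProtonSites(sites, file.path(out, "proton", "sites.tsv"))
  g <- tab[tab$scope == "global", ]
  .writeStageSummary(out, "proton", list(
    barrier_kj_mol = g$deltaG, barrier_site = g$label, barrier_z = g$z,
    barriers = lapply(split(tab, tab$scope), function(r)
      list(deltaG = r$deltaG, site = r$label))))
}

.stageSsme <- function(cfg, out, state) {
  if (is.null(state$trace)) .stageSimulate(cfg, out, state)
  fit <- fitDecay(state$trace)
  mmS <- fitMM(normalizeAmplitudes(state$mmSat))
  mmL <- fitMM(normalizeAmplitudes(state$mmLin))
  .writeStageSummary(out, "ssme", list(
    decay_rate_per_s = decayRate(fit), t1_s = fit@t1,
    t1_true_s = cfg$ssme$t1,
    mm_km_mM = mmS@km, mm_km_true_mM = cfg$ssme$mm_km,
    mm_saturating = mmS@saturating,
    mm_linear_saturating = mmL@saturating))
}

.stageClassify <- function(cfg, out, state) {
  rates <- if (is.null(cfg$classify$rates_path)) loadDecayRateTable()
           else loadDecayRateTable(cfg$classify$rates_path)
  calls <- classifyTransport(rates, cfg$classify$ratio_threshold)
  write.table(calls, file.path(out, "classify", "transport_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(calls, file.path(out, "classify",
                                        "transport_calls.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeStageSummary(out, "classify", list(
    n_transport = sum(calls$call == "transport"),
    n_binding = sum(calls$call == "binding"),
    n_no_current = sum(calls$call == "no_current")))
}

.stageReport <- function(cfg, out, cfgHash, state) {
  stages <- setdiff(intersect(.STAGES, cfg$stages), "report")
  summaries <- list()
  for (stage in stages) {
    p <- file.path(out, stage, "summary.json")
    if (file.exists(p)) summaries[[stage]] <- jsonlite::read_json(p)
  }
  report <- list(config_hash = cfgHash, seed = cfg$seed,
                 package_version = as.character(packageVersion("ammtools")),
                 stages = summaries)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# ammtools run report", "",
          sprintf("- config hash: %s", cfgHash),
          sprintf("- seed: %d", as.integer(cfg$seed)), "")
  for (stage in names(summaries)) {
    md <- c(md, sprintf("## %s", stage), "")
    s <- summaries[[stage]]
    flat <- unlist(s)
    md <- c(md, sprintf("- %s: %s", names(flat), as.character(flat)), "")
  }
  writeLines(md, file.path(out, "report.md"))
  state$report <- report
  invisible(report)
}
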