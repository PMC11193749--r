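## Orchestration: configuration, the simulate/analyze/report entry points,
## and run-report serialisation.

#' Analysis configuration
#'
#' All tunables of the analysis stages in one validated object. Unknown keys
#' are rejected; every default is echoed into the run report so no hidden
#' defaults exist.
#'
#' @param orientation which template end is at the position origin
#'   (`"ss_top"` or `"ds_top"`).
#' @param k_sigma binarization threshold multiplier, in [3, 5].
#' @param box_width junction box width (pixels, odd).
#' @param search_range offset search half-range (pixels/lines).
#' @param background_offset_px pixel offset of the background box from the
#'   junction line.
#' @param min_run minimum fluorescent run length (lines).
#' @param min_cluster minimum correlation cluster length (lines).
#' @param sg_window Savitzky-Golay window (samples, odd).
#' @param step_sensitivity step-fit penalty multiplier.
#' @param flank_window flanking-state margin (s).
#' @param tau_bleach photobleaching time used in the lifetime correction (s).
#' @param tolerance_px junction-region half-width for binding-position
#'   classification (pixels).
#' @param max_jump,max_gap,min_track_length tracker settings
#'   (see [track_particles()]).
#' @param fit_lags MSD lags used in the diffusion fit.
#' @param thresholds a [pause_thresholds()] object.
#' @param params an [elasticity_params()] object.
#' @param ... rejected; guards against misspelled keys.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(orientation = "ss_top",
                            k_sigma = 4,
                            box_width = 5,
                            search_range = 5,
                            background_offset_px = 15,
                            min_run = 3,
                            min_cluster = 3,
                            sg_window = 15,
                            step_sensitivity = 4,
                            flank_window = 0.5,
                            tau_bleach = 13,
                            tolerance_px = 3,
                            max_jump = 2,
                            max_gap = 2,
                            min_track_length = 8,
                            fit_lags = 4,
                            thresholds = pause_thresholds(),
                            params = elasticity_params(),
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("analysis_config: unknown keys: ", paste(names(extra), collapse = ", "))
  if (!orientation %in% c("ss_top", "ds_top"))
    stop("analysis_config: orientation must be ss_top or ds_top")
  if (k_sigma < 3 || k_sigma > 5) stop("analysis_config: k_sigma must be in [3, 5]")
  if (box_width %% 2 != 1 || box_width < 1) stop("analysis_config: box_width must be odd")
  if (sg_window %% 2 != 1 || sg_window < 5) stop("analysis_config: sg_window must be odd, >= 5")
  for (k in c("search_range", "min_run", "min_cluster", "flank_window",
              "tau_bleach", "tolerance_px", "max_jump", "max_gap",
              "min_track_length", "fit_lags", "step_sensitivity"))
    if (!is.numeric(get(k)) || get(k) <= 0)
      stop(sprintf("analysis_config: %s must be positive", k))
  structure(list(orientation = orientation, k_sigma = k_sigma,
                 box_width = box_width, search_range = search_range,
                 background_offset_px = background_offset_px,
                 min_run = min_run, min_cluster = min_cluster,
                 sg_window = sg_window, step_sensitivity = step_sensitivity,
                 flank_window = flank_window, tau_bleach = tau_bleach,
                 tolerance_px = tolerance_px, max_jump = max_jump,
                 max_gap = max_gap, min_track_length = min_track_length,
                 fit_lags = fit_lags, thresholds = thresholds,
                 params = params),
            class = "analysis_config")
}

# small stable polynomial hash of a deparsed object, for provenance stamping
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("polfx"))
}

#' Simulate a dataset and write it to disk
#'
#' Writes `force_trace.csv`, `kymograph.tsv` (+ `.meta.json`) and
#' `truth.json` into `out_dir`. Byte-identical on re-run for a fixed seed.
#'
#' @param config a [simulation_config()] (or path to a JSON file of its
#'   fields).
#' @param out_dir output directory (created if missing).
#' @param params an [elasticity_params()] object.
#' @return invisibly, the named vector of file paths.
#' @export
run_simulate <- function(config = simulation_config(), out_dir,
                         params = elasticity_params()) {
  if (is.character(config)) {
    fields <- jsonlite::read_json(config, simplifyVector = TRUE)
    bad <- setdiff(names(fields), names(formals(simulation_config)))
    if (length(bad))
      stop("run_simulate: unknown config keys: ", paste(bad, collapse = ", "))
    config <- do.call(simulation_config, fields)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(config, params)
  paths <- c(force = file.path(out_dir, "force_trace.csv"),
             kymo = file.path(out_dir, "kymograph.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_force_csv(sim$trace, paths[["force"]])
  write_kymograph(sim$kymo, paths[["kymo"]])
  write_truth_json(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Run the full analysis pipeline on an interchange dataset
#'
#' Stage order: junction reconstruction from the force trace -> kymograph
#' registration -> junction-box intensity extraction and binarization ->
#' burst segmentation with flanking states and memory counts -> activity x
#' fluorescence correlation and cluster statistics -> binding lifetimes with
#' photobleaching correction -> particle tracking, binding-position
#' discrimination and MSD diffusion fits. Per-stage event counts are logged
#' into the report so aggregate n's are auditable.
#'
#' @param data_dir directory holding `force_trace.csv` and `kymograph.tsv`
#'   (as written by [run_simulate()] or a converter).
#' @param config an [analysis_config()].
#' @param out_dir optional output directory; when given, the report JSON,
#'   CSV tables and a log are written there.
#' @return an object of class `run_report` (a nested list; see the `summary`
#'   element for aggregates).
#' @export
run_analyze <- function(data_dir, config = analysis_config(), out_dir = NULL) {
  fpath <- file.path(data_dir, "force_trace.csv")
  kpath <- file.path(data_dir, "kymograph.tsv")
  if (!file.exists(fpath)) stop("run_analyze: missing input ", fpath)
  if (!file.exists(kpath)) stop("run_analyze: missing input ", kpath)
  trace <- read_force_csv(fpath)
  kymo <- read_kymograph(kpath)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  ## 1. junction reconstruction
  traj <- reconstruct_junction(trace, config$params, config$orientation)
  say("reconstruct: %d samples, %d clamped, %d flagged",
      nrow(traj), attr(traj, "n_clamped"), attr(traj, "n_flagged"))

  ## 2. registration
  no_signal <- sum(kymo$photons) == 0
  offsets <- if (no_signal) list(x_offset = 0L, y_offset = 0L, objective_value = 0)
  else refine_offsets(kymo, traj, config$search_range, config$box_width)
  say("register: offsets dx=%d dy=%d, objective=%g",
      offsets$x_offset, offsets$y_offset, offsets$objective_value)

  ## 3. junction intensity, background box, binarization
  intens <- extract_junction_intensity(kymo, traj, offsets, config$box_width)
  bg_off <- list(x_offset = offsets$x_offset,
                 y_offset = offsets$y_offset + config$background_offset_px)
  bg_box <- extract_junction_intensity(kymo, traj, bg_off, config$box_width)
  ok_lines <- !is.na(intens$intensity) & !is.na(bg_box$intensity)
  bfl <- binarize(ifelse(ok_lines, intens$intensity, NA),
                  time = intens$time, k_sigma = config$k_sigma,
                  sigma_source = "background_region",
                  background_series = bg_box$intensity[ok_lines])
  bfl <- min_run_filter(bfl, config$min_run)
  say("binarize: threshold=%.2f counts, %d/%d lines fluorescent",
      attr(bfl, "threshold_used"), sum(bfl$state == 1), nrow(bfl))

  ## 4. activity fit, pauses, segments, memory
  afit <- activity_step_fit(traj, trace,
                            sensitivity = config$step_sensitivity,
                            thresholds = config$thresholds)
  pauses <- detect_pauses(afit, thresholds = config$thresholds)
  segs <- extract_segments(bfl, afit, thresholds = config$thresholds,
                           min_run = config$min_run)
  segs <- flanking_states(segs, afit, config$flank_window)
  mem <- memory_configuration_counts(segs)
  say("segments: %d total (%d single-type), %d pauses, %d memory-countable",
      nrow(segs), sum(segs$segment_type == "single"), nrow(pauses), mem$n_total)

  ## 5. correlation statistics
  bact <- activity_to_binary(afit, bfl$time, config$thresholds)
  series <- build_correlation_series(bfl, bact)
  clusters <- cluster_events(series, config$min_cluster)
  fl_frac <- if (clusters$total > 0) fluorescent_event_fraction(clusters) else NA_real_
  nf_pause <- nonfluorescent_pause_fraction(clusters)
  say("correlation: clusters 11=%d 10=%d 01=%d 00=%d",
      clusters$n11, clusters$n10, clusters$n01, clusters$n00)

  ## 6. lifetimes (trace-boundary-truncated segments excluded)
  t_hi <- max(bfl$time) + stats::median(diff(bfl$time))
  full <- segs$t_start > min(bfl$time) & segs$t_end < t_hi - 1e-9
  lifetime <- if (sum(full) >= 10)
    fit_lifetime(segs$duration[full], config$tau_bleach) else NULL
  say("lifetime: %d usable events, %d truncated at trace ends",
      sum(full), sum(!full))

  ## 7. tracking, binding positions, diffusion
  tracks <- track_particles(kymo, k_sigma = config$k_sigma,
                            max_jump = config$max_jump, max_gap = config$max_gap,
                            min_length = config$min_track_length)
  jp <- junction_to_pixels(traj, kymo)
  track_tab <- NULL; diffusion <- list()
  if (length(tracks)) {
    cls <- vapply(tracks, classify_binding_position, character(1),
                  junction_pixels = jp, tolerance = config$tolerance_px,
                  orientation = config$orientation)
    D <- vapply(tracks, function(tr) {
      if (nrow(tr) < 8) return(NA_real_)
      ms <- msd(tr, kymo$line_time)
      if (nrow(ms) < 3) return(NA_real_)
      fit_diffusion(ms, config$fit_lags)$D
    }, numeric(1))
    track_tab <- data.frame(track = seq_along(tracks),
                            n_lines = vapply(tracks, nrow, integer(1)),
                            class = cls, D_um2_s = D)
    for (cl in unique(cls))
      diffusion[[cl]] <- list(mean_D = mean(D[cls == cl], na.rm = TRUE),
                              n = sum(cls == cl))
  }
  say("tracking: %d trajectories", length(tracks))

  report <- structure(list(
    software_version = .pkg_version(),
    config = config,
    config_hash = .config_hash(config),
    offsets = offsets,
    segments = as.data.frame(segs),
    pauses = pauses,
    clusters = unclass(clusters),
    memory = list(counts = as.list(mem$counts),
                  fractions = as.list(mem$fractions),
                  n_total = mem$n_total),
    tracks = track_tab,
    summary = list(
      n_segments = nrow(segs),
      single_type_fraction = if (nrow(segs)) mean(segs$segment_type == "single") else NA_real_,
      n_pauses = nrow(pauses),
      fluorescent_event_fraction = fl_frac,
      nonfluorescent_pause_fraction = nf_pause,
      lifetime = if (!is.null(lifetime)) unclass(lifetime) else NULL,
      diffusion = diffusion),
    log = log,
    intensity = data.frame(time = intens$time, intensity = intens$intensity,
                           fluor_state = bfl$state),
    junction = as.data.frame(traj)),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    utils::write.csv(report$segments, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(report$pauses, file.path(out_dir, "pauses.csv"),
                     row.names = FALSE)
    if (!is.null(track_tab))
      utils::write.csv(track_tab, file.path(out_dir, "tracks.csv"),
                       row.names = FALSE)
    writeLines(log, file.path(out_dir, "analysis.log"))
  }
  report
}

#' Write / read a run report as JSON
#' @param report a [run_analyze()] result.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$config <- lapply(unclass(out$config), function(x)
    if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}

#' Render a human-readable summary and figure panels from a run report
#'
#' Writes `summary.txt` plus PNG panels (junction-intensity overlay with the
#' binarized state, correlation class strip, memory-configuration bar chart,
#' segment-duration survival, per-track diffusion constants). Panels degrade
#' to placeholders when a stage produced no events.
#'
#' @param report a [run_analyze()] result, or path to a `report.json`.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
run_report <- function(report, out_dir) {
  if (is.character(report)) {
    if (!file.exists(report)) stop("run_report: no such report: ", report)
    report <- read_report_json(report)
  }
  if (is.null(report$summary)) stop("run_report: malformed report (no summary)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  lines <- c(
    sprintf("polfx %s run report (config %s)", report$software_version, report$config_hash),
    sprintf("segments: %s (single-type fraction %.3f)", s$n_segments,
            as.numeric(s$single_type_fraction)),
    sprintf("pauses: %s", s$n_pauses),
    sprintf("fluorescent event fraction: %.3f", as.numeric(s$fluorescent_event_fraction)),
    sprintf("non-fluorescent pause fraction: %.3f", as.numeric(s$nonfluorescent_pause_fraction)),
    if (!is.null(s$lifetime))
      sprintf("bound lifetime: %.3f +/- %.3f s (bleach-corrected, n=%s)",
              s$lifetime$tau_corrected, s$lifetime$fit_error, s$lifetime$n_events)
    else "bound lifetime: too few events",
    "", "stage log:", report$log)
  paths <- file.path(out_dir, c("summary.txt", "intensity.png", "memory.png",
                                "survival.png", "diffusion.png"))
  writeLines(lines, paths[1])

  placeholder <- function(msg) {
    plot.new(); title(main = msg)
  }
  grDevices::png(paths[2], 900, 400)
  it <- report$intensity
  if (!is.null(it) && nrow(it) > 0 && any(is.finite(it$intensity))) {
    graphics::plot(it$time, it$intensity, type = "l", col = "grey40",
                   xlab = "time (s)", ylab = "junction box photons/line",
                   main = "junction fluorescence and binarized state")
    graphics::lines(it$time, it$fluor_state * max(it$intensity, na.rm = TRUE),
                    col = "red")
  } else placeholder("no intensity data")
  grDevices::dev.off()

  grDevices::png(paths[3], 600, 400)
  mc <- unlist(report$memory$counts)
  if (length(mc) && sum(mc) > 0) {
    graphics::barplot(mc / sum(mc), ylab = "fraction",
                      main = "memory configurations (pre-during-post)",
                      las = 2)
  } else placeholder("no memory-countable segments")
  grDevices::dev.off()

  grDevices::png(paths[4], 600, 400)
  segs <- report$segments
  if (!is.null(segs) && NROW(segs) > 0) {
    d <- sort(segs$duration)
    surv <- (length(d) - seq_along(d) + 1) / length(d)
    graphics::plot(d, surv, log = "y", type = "s", xlab = "duration (s)",
                   ylab = "survival", main = "burst-duration survival")
  } else placeholder("no segments")
  grDevices::dev.off()

  grDevices::png(paths[5], 600, 400)
  tt <- report$tracks
  if (!is.null(tt) && NROW(tt) > 0 && any(is.finite(tt$D_um2_s))) {
    graphics::boxplot(D_um2_s ~ class, data = tt, ylab = "D (um^2/s)",
                      main = "diffusion by binding region")
  } else placeholder("no tracked particles")
  grDevices::dev.off()

  invisible(paths)
}
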