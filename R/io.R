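## Plain-text interchange formats. The instrument's proprietary raw format is
## out of scope; converters can target these instead. (HDF5/TIFF variants are
## an extension point; this build uses text formats only.)

#' Write / read a force-extension trace as CSV
#'
#' Header `time_s,force_pN,eed_um` (RFC-4180).
#'
#' @param trace a [force_extension_trace()].
#' @param path file path.
#' @return `read_force_csv` returns a [force_extension_trace()].
#' @export
write_force_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "force_pN", "eed_um")
  if (!all(need %in% names(d)))
    stop("read_force_csv: expected header time_s,force_pN,eed_um")
  force_extension_trace(d$time_s, d$force_pN, d$eed_um)
}

#' Write / read a kymograph as a TSV photon matrix plus JSON metadata
#'
#' `<path>` holds the integer photon matrix (lines x pixels, tab-separated);
#' `<path>.meta.json` holds `line_time_s`, `pixel_size_um`, `origin_um`,
#' `bead_band_pixels`.
#'
#' @param kymo a [kymograph()].
#' @param path file path for the matrix.
#' @return `read_kymograph` returns a [kymograph()].
#' @export
write_kymograph <- function(kymo, path) {
  utils::write.table(kymo$photons, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(line_time_s = kymo$line_time, pixel_size_um = kymo$pixel_size,
               origin_um = kymo$origin_position,
               bead_band_pixels = kymo$bead_band_pixels)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  ph <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(ph) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  kymograph(ph, meta$line_time_s, meta$pixel_size_um, meta$origin_um,
            meta$bead_band_pixels)
}

#' Write / read simulation truth as JSON
#'
#' Serialises the event tables, latent grid and binder trajectories; the
#' elasticity parameters and configuration are echoed for provenance.
#'
#' @param truth a [simulate_kinetics()] result.
#' @param path file path.
#' @return `read_truth_json` returns the truth list (class `sim_truth`).
#' @export
write_truth_json <- function(truth, path) {
  out <- list(events = truth$events, sub_intervals = truth$sub_intervals,
              grid = truth$grid, truth_pauses = truth$truth_pauses,
              binders = truth$binders, line_times = truth$line_times,
              config = unclass(truth$config), params = unclass(truth$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config <- do.call(simulation_config,
                      x$config[names(x$config) %in% names(formals(simulation_config))])
  x$params <- do.call(elasticity_params, x$params)
  if (is.data.frame(x$binders)) {
    # jsonlite simplifies the list of binder records into a data frame
    x$binders <- lapply(seq_len(nrow(x$binders)), function(i) {
      b <- as.list(x$binders[i, , drop = FALSE])
      b$trajectory <- x$binders$trajectory[[i]]
      b
    })
  }
  structure(x, class = "sim_truth")
}
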