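## Registration of the reconstructed junction trajectory onto the
## fluorescence kymograph, junction-box intensity extraction, and
## discrimination of binding positions (ssDNA / dsDNA / junction).

# nearest-sample resampling of a trajectory column onto kymograph line times
.resample_nearest <- function(time, value, target) {
  idx <- vapply(target, function(t) which.min(abs(time - t)), integer(1))
  value[idx]
}

# columns that belong to the bead bands of a kymograph
.bead_cols <- function(kymo) {
  bb <- kymo$bead_band_pixels
  if (bb <= 0) return(integer(0))
  np <- ncol(kymo$photons)
  c(seq_len(bb), np - bb + seq_len(bb))
}

#' Map a junction trajectory onto kymograph pixel coordinates
#'
#' The trajectory is resampled to the kymograph line times by nearest sample;
#' positions convert to (1-based) pixel indices via
#' `floor((position - origin) / pixel_size) + 1`. Lines whose pixel falls
#' outside the frame are flagged.
#'
#' @param traj a [reconstruct_junction()] result (or data frame with
#'   `time_s`, `junction_um`).
#' @param kymo a [kymograph()].
#' @return data frame `line`, `time`, `pixel`, `in_frame`.
#' @export
junction_to_pixels <- function(traj, kymo) {
  tl <- kymo_times(kymo)
  if (max(traj$time_s) < min(tl) || min(traj$time_s) > max(tl))
    stop("junction_to_pixels: trajectory and kymograph do not overlap in time")
  pos <- .resample_nearest(traj$time_s, traj$junction_um, tl)
  pix <- floor((pos - kymo$origin_position) / kymo$pixel_size) + 1L
  in_frame <- !is.na(pix) & pix >= 1L & pix <= ncol(kymo$photons)
  data.frame(line = seq_along(tl), time = tl, pixel = pix, in_frame = in_frame)
}

# total photons inside a box of width box_width centred at `centre[i]` on
# kymograph line `lines[i]`, excluding bead-band pixels; NA centres skipped
.box_total <- function(kymo, lines, centre, box_width) {
  half <- (box_width - 1) %/% 2
  np <- ncol(kymo$photons)
  bead <- .bead_cols(kymo)
  tot <- 0
  for (i in seq_along(lines)) {
    if (is.na(centre[i])) next
    px <- (centre[i] - half):(centre[i] + half)
    px <- px[px >= 1 & px <= np & !(px %in% bead)]
    if (length(px)) tot <- tot + sum(kymo$photons[lines[i], px])
  }
  tot
}

#' Refine kymograph/trajectory alignment by exhaustive offset search
#'
#' Grid search over integer line offsets `dx` and pixel offsets `dy` in
#' `[-search_range, +search_range]^2`, maximising the total photon count
#' inside a `box_width`-pixel box around the shifted junction line. Ties are
#' broken deterministically: smallest `|dx| + |dy|`, then smallest `dy`, then
#' smallest `dx`. Bead-band pixels are excluded from the objective.
#'
#' To keep candidate offsets comparable, the objective is evaluated only on
#' lines whose box lies fully inside the non-bead interior for *every*
#' candidate offset (so all candidates sum the same number of pixels); if no
#' such line exists the full-frame truncated sums are used. Because the
#' objective is statistically flat in `dx` for a slowly moving junction,
#' candidates within `tie_sd` Poisson standard deviations of the maximum are
#' treated as tied; noiseless constructed shifts are still recovered exactly.
#'
#' @param kymo a [kymograph()].
#' @param traj a [reconstruct_junction()] result.
#' @param search_range half-width of the search grid (pixels/lines).
#' @param box_width box width (pixels, odd).
#' @param tie_sd near-tie width in Poisson SDs of the maximum objective
#'   (0 for exact argmax only).
#' @return an object of class `registration_offsets`: `x_offset` (lines),
#'   `y_offset` (pixels), `objective_value` (total photons).
#' @export
refine_offsets <- function(kymo, traj, search_range = 5, box_width = 5,
                           tie_sd = 1) {
  if (sum(kymo$photons) == 0) stop("refine_offsets: no signal to register")
  jp <- junction_to_pixels(traj, kymo)
  n_lines <- nrow(kymo$photons)
  half <- (box_width - 1) %/% 2
  bb <- kymo$bead_band_pixels
  np <- ncol(kymo$photons)
  # lines usable by every candidate offset
  interior <- !is.na(jp$pixel) &
    jp$pixel - search_range - half >= bb + 1 &
    jp$pixel + search_range + half <= np - bb &
    jp$line - search_range >= 1 & jp$line + search_range <= n_lines
  use <- if (any(interior)) which(interior) else seq_len(nrow(jp))
  grid <- expand.grid(dx = -search_range:search_range,
                      dy = -search_range:search_range)
  obj <- vapply(seq_len(nrow(grid)), function(g) {
    dx <- grid$dx[g]; dy <- grid$dy[g]
    lines <- jp$line[use] + dx
    keep <- lines >= 1 & lines <= n_lines
    .box_total(kymo, lines[keep], jp$pixel[use][keep] + dy, box_width)
  }, numeric(1))
  tol <- tie_sd * sqrt(max(obj))
  tied <- which(obj >= max(obj) - tol)
  ord <- order(abs(grid$dx[tied]) + abs(grid$dy[tied]),
               grid$dy[tied], grid$dx[tied])
  best <- tied[ord[1]]
  structure(list(x_offset = grid$dx[best], y_offset = grid$dy[best],
                 objective_value = obj[best]),
            class = "registration_offsets")
}

#' Extract the junction-line fluorescence intensity series
#'
#' Per kymograph line, sums the photons inside a `box_width`-pixel box
#' centred on the offset-corrected junction pixel. Bead-band pixels are
#' excluded; boxes truncated at the frame edge or bead bands are flagged and
#' their totals rescaled to full-box equivalents (`box_width / n_included`)
#' so the intensity statistics stay comparable across lines; a box fully
#' outside the frame yields NA for that line.
#'
#' @param kymo a [kymograph()].
#' @param traj a [reconstruct_junction()] result.
#' @param offsets a [refine_offsets()] result (or `list(x_offset=0, y_offset=0)`).
#' @param box_width box width (pixels, odd).
#' @return data frame `line`, `time`, `intensity`, `truncated`.
#' @export
extract_junction_intensity <- function(kymo, traj, offsets = list(x_offset = 0, y_offset = 0),
                                       box_width = 5) {
  jp <- junction_to_pixels(traj, kymo)
  half <- (box_width - 1) %/% 2
  np <- ncol(kymo$photons)
  n_lines <- nrow(kymo$photons)
  bead <- .bead_cols(kymo)
  intensity <- rep(NA_real_, nrow(jp))
  truncated <- rep(FALSE, nrow(jp))
  for (i in seq_len(nrow(jp))) {
    line <- jp$line[i] + offsets$x_offset
    if (is.na(jp$pixel[i]) || line < 1 || line > n_lines) next
    centre <- jp$pixel[i] + offsets$y_offset
    px <- (centre - half):(centre + half)
    inside <- px[px >= 1 & px <= np & !(px %in% bead)]
    if (!length(inside)) next
    intensity[i] <- sum(kymo$photons[line, inside]) * box_width / length(inside)
    truncated[i] <- length(inside) < box_width
  }
  data.frame(line = jp$line, time = jp$time, intensity = intensity,
             truncated = truncated)
}

#' Classify where a particle trajectory binds: junction, ssDNA or dsDNA
#'
#' The kymograph is virtually divided into three regions around the junction
#' line: within `tolerance` pixels of the junction, the ssDNA side, and the
#' dsDNA side. With orientation `"ss_top"` the ssDNA region is the low-pixel
#' (origin) side. Each trajectory line is labelled and the majority label
#' over the trajectory's lifetime is returned.
#'
#' @param particle_traj data frame with columns `line` and `pixel` (or
#'   `position_um`, converted using the kymograph calibration).
#' @param junction_pixels a [junction_to_pixels()] result.
#' @param tolerance junction half-width (pixels).
#' @param orientation `"ss_top"` or `"ds_top"`.
#' @param kymo optional [kymograph()], needed when `particle_traj` has
#'   positions in um instead of pixels.
#' @return one of `"junction"`, `"ssDNA"`, `"dsDNA"`.
#' @export
classify_binding_position <- function(particle_traj, junction_pixels,
                                      tolerance = 3,
                                      orientation = c("ss_top", "ds_top"),
                                      kymo = NULL) {
  orientation <- match.arg(orientation)
  if (!"pixel" %in% names(particle_traj)) {
    if (is.null(kymo)) stop("classify_binding_position: need kymo to convert positions")
    particle_traj$pixel <-
      floor((particle_traj$position_um - kymo$origin_position) / kymo$pixel_size) + 1L
  }
  jpix <- junction_pixels$pixel[match(particle_traj$line, junction_pixels$line)]
  if (all(is.na(jpix))) stop("classify_binding_position: trajectory outside frame")
  d <- particle_traj$pixel - jpix
  lab <- ifelse(abs(d) <= tolerance, "junction",
                ifelse(d < 0,
                       if (orientation == "ss_top") "ssDNA" else "dsDNA",
                       if (orientation == "ss_top") "dsDNA" else "ssDNA"))
  lab <- lab[!is.na(lab)]
  names(which.max(table(lab)))
}
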