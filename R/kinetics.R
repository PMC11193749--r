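## Bound-lifetime fitting with photobleaching correction, kymograph particle
## tracking, and MSD-based diffusion estimation.

#' Mono-exponential lifetime fit with photobleaching correction
#'
#' The observed bound durations are the minimum of the true dwell and the
#' fluorophore bleaching time, so under exponential kinetics
#' `1/tau_observed = 1/tau_off + 1/tau_bleach`. `tau_observed` is the
#' maximum-likelihood exponential mean of the survival curve (the sample
#' mean); the bleaching contribution is then removed via
#' `tau_corrected = 1 / (1/tau_observed - 1/tau_bleach)`.
#'
#' @param durations bound durations (s), at least 10 events.
#' @param tau_bleach mean photobleaching time (s); `Inf` for no correction.
#' @return object of class `lifetime_fit`: `tau_observed`, `tau_corrected`,
#'   `tau_bleach_used`, `fit_error` (SE of `tau_corrected`), `n_events`,
#'   `degenerate` flag.
#' @export
fit_lifetime <- function(durations, tau_bleach = Inf) {
  durations <- durations[is.finite(durations) & durations > 0]
  n <- length(durations)
  if (n < 10) stop("fit_lifetime: need at least 10 events")
  if (!(tau_bleach > 0)) stop("fit_lifetime: tau_bleach must be positive")
  tau_obs <- mean(durations)                 # exponential MLE
  se_obs <- tau_obs / sqrt(n)
  degenerate <- stats::sd(durations) < 1e-12 * tau_obs
  if (is.finite(tau_bleach) && tau_obs >= tau_bleach)
    stop("fit_lifetime: lifetime not identifiable (tau_observed >= tau_bleach)")
  tau_corr <- if (is.finite(tau_bleach))
    1 / (1 / tau_obs - 1 / tau_bleach) else tau_obs
  # delta method: d tau_corr / d tau_obs = (tau_corr / tau_obs)^2
  se_corr <- se_obs * (tau_corr / tau_obs)^2
  structure(list(tau_observed = tau_obs, tau_corrected = tau_corr,
                 tau_bleach_used = tau_bleach, fit_error = se_corr,
                 n_events = n, degenerate = degenerate),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("lifetime fit: tau_obs = %.3g s, tau_corrected = %.3g +/- %.2g s (n = %d%s)\n",
              x$tau_observed, x$tau_corrected, x$fit_error, x$n_events,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Track fluorescent particles in a kymograph
#'
#' Detect-then-link tracker: per line, local maxima above
#' `background + k_sigma * sigma` (bead bands excluded) are localised by
#' centroid over a +/-2 pixel window; detections are linked to the nearest
#' active track within `max_jump` pixels per elapsed line, with gap closing
#' up to `max_gap` missed lines.
#'
#' @param kymo a [kymograph()].
#' @param k_sigma detection threshold multiplier.
#' @param min_photons absolute detection threshold (counts); overrides
#'   `k_sigma` when given.
#' @param max_jump maximum link distance per line step (pixels).
#' @param max_gap maximum number of missed lines inside a track.
#' @param min_length minimum track length (detections) to keep.
#' @param min_sep non-maximum-suppression radius (pixels): weaker peaks
#'   within this distance of a stronger one are discarded, so Poisson bumps
#'   on a bright emitter's PSF shoulders do not spawn spurious tracks.
#' @return list of trajectories, each a data frame `line`, `time`,
#'   `position_um`, `pixel`, `photons`.
#' @export
track_particles <- function(kymo, k_sigma = 4, min_photons = NULL,
                            max_jump = 2, max_gap = 2, min_length = 3,
                            min_sep = 4) {
  ph <- kymo$photons
  np <- ncol(ph); nl <- nrow(ph)
  bead <- .bead_cols(kymo)
  interior <- setdiff(seq_len(np), bead)
  bgvals <- as.numeric(ph[, interior])
  bg <- stats::median(bgvals)
  sigma <- 1.4826 * stats::median(abs(bgvals - bg))
  thr <- if (!is.null(min_photons)) min_photons else bg + k_sigma * max(sigma, 1e-9)
  tl <- kymo_times(kymo)

  tracks <- list()          # finished
  active <- list()          # each: list(rows = data.frame, last_line, last_pix)
  for (li in seq_len(nl)) {
    row <- ph[li, ]
    cand <- interior[row[interior] > thr]
    # local maxima among candidates
    peaks <- cand[vapply(cand, function(j) {
      lo <- max(1, j - 1); hi <- min(np, j + 1)
      row[j] >= max(row[lo:hi])
    }, logical(1))]
    # non-maximum suppression: strongest first, drop peaks within min_sep
    if (length(peaks) > 1) {
      peaks <- peaks[order(-row[peaks])]
      kept <- integer(0)
      for (j in peaks)
        if (!length(kept) || all(abs(kept - j) > min_sep)) kept <- c(kept, j)
      peaks <- sort(kept)
    }
    dets <- lapply(peaks, function(j) {
      px <- max(1, j - 2):min(np, j + 2)
      w <- pmax(row[px] - bg, 0)
      cpix <- if (sum(w) > 0) sum(px * w) / sum(w) else j
      list(pixel = cpix,
           position_um = kymo$origin_position + (cpix - 0.5) * kymo$pixel_size,
           photons = sum(row[px]))
    })
    used <- logical(length(dets))
    # link to active tracks (greedy nearest)
    if (length(active)) {
      for (a in seq_along(active)) {
        tr <- active[[a]]
        gap <- li - tr$last_line
        if (gap > max_gap + 1L || !length(dets)) next
        d <- vapply(dets, function(z) abs(z$pixel - tr$last_pix), numeric(1))
        d[used] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] <= max_jump * gap) {
          z <- dets[[j]]
          active[[a]]$rows <- rbind(tr$rows, data.frame(
            line = li, time = tl[li], position_um = z$position_um,
            pixel = z$pixel, photons = z$photons))
          active[[a]]$last_line <- li
          active[[a]]$last_pix <- z$pixel
          used[j] <- TRUE
        }
      }
      # retire stale tracks
      stale <- vapply(active, function(tr) li - tr$last_line > max_gap, logical(1))
      tracks <- c(tracks, lapply(active[stale], `[[`, "rows"))
      active <- active[!stale]
    }
    # new tracks from unused detections
    for (j in which(!used)) {
      z <- dets[[j]]
      active[[length(active) + 1L]] <- list(
        rows = data.frame(line = li, time = tl[li],
                          position_um = z$position_um, pixel = z$pixel,
                          photons = z$photons),
        last_line = li, last_pix = z$pixel)
    }
  }
  tracks <- c(tracks, lapply(active, `[[`, "rows"))
  tracks[vapply(tracks, nrow, integer(1)) >= min_length]
}

#' Time-averaged mean squared displacement of a trajectory
#'
#' `MSD(k dt) = mean over i of (x[i+k] - x[i])^2`, over all overlapping pairs,
#' for lags up to `max_lag_fraction` of the trajectory length. Requires at
#' least 8 lines.
#'
#' @param trajectory data frame with `position_um` and `line` (equally
#'   spaced; gap-closed lines are treated by line index).
#' @param dt line time (s).
#' @param max_lag_fraction maximum lag as a fraction of trajectory length.
#' @return data frame `lag_s`, `msd` (um^2), `n_pairs`.
#' @export
msd <- function(trajectory, dt, max_lag_fraction = 0.25) {
  x <- trajectory$position_um
  lines <- trajectory$line
  n <- length(x)
  if (n < 8) stop("msd: trajectory shorter than 8 lines")
  # place on the full line grid to respect gaps
  full <- rep(NA_real_, max(lines) - min(lines) + 1L)
  full[lines - min(lines) + 1L] <- x
  m <- length(full)
  max_lag <- max(1L, floor(m * max_lag_fraction))
  out <- lapply(seq_len(max_lag), function(k) {
    d <- full[(1 + k):m] - full[seq_len(m - k)]
    d <- d[!is.na(d)]
    data.frame(lag_s = k * dt, msd = mean(d^2), n_pairs = length(d))
  })
  out <- do.call(rbind, out)
  out[out$n_pairs > 0, , drop = FALSE]
}

#' Diffusion constant from an MSD curve
#'
#' Weighted least-squares fit of `MSD = 2 D lag + b` (1-D convention, motion
#' along the DNA axis) over the first `fit_lags` lag points, weighting each
#' point by its pair count. The intercept `b` absorbs localisation noise;
#' a negative slope is truncated to `D = 0` with a flag.
#'
#' @param msd_series a [msd()] result (>= 3 lag points).
#' @param fit_lags number of initial lags used in the fit.
#' @return object of class `diffusion_estimate`: `D` (um^2/s), `intercept`,
#'   `fit_lags`, `n_points`, `truncated`.
#' @export
fit_diffusion <- function(msd_series, fit_lags = 4) {
  m <- msd_series[seq_len(min(fit_lags, nrow(msd_series))), , drop = FALSE]
  if (nrow(m) < 3) stop("fit_diffusion: need at least 3 lag points")
  w <- if ("n_pairs" %in% names(m)) m$n_pairs else rep(1, nrow(m))
  fit <- stats::lm(msd ~ lag_s, data = m, weights = w)
  slope <- stats::coef(fit)[["lag_s"]]
  D <- slope / 2
  truncated <- D < 0
  structure(list(D = max(D, 0), intercept = stats::coef(fit)[["(Intercept)"]],
                 fit_lags = nrow(m), n_points = nrow(msd_series),
                 truncated = truncated),
            class = "diffusion_estimate")
}
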