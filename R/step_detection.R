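## Savitzky-Golay filtering, robust noise estimation, change-point step
## fitting and binarization, shared by the fluorescence-intensity and
## base-pair branches of the pipeline.

# SG projection matrix for one window: rows give fitted values at each
# in-window position (deriv = 0) or fitted first derivatives (deriv = 1).
.sg_hat <- function(window, polyorder, deriv = 0L) {
  h <- (window - 1L) %/% 2L
  x <- -h:h
  A <- outer(x, 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))        # (p+1) x w coefficient map
  if (deriv == 0L) A %*% C
  else {
    dA <- outer(x, 0:polyorder, function(xx, k) ifelse(k == 0, 0, k * xx^(k - 1)))
    dA %*% C
  }
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing with the standard convolution in
#' the interior and polynomial extension (the boundary fits evaluated at the
#' boundary samples) at the ends. Polynomials up to `polyorder` are
#' reproduced exactly, so constants and linear ramps pass through unchanged.
#'
#' @param series numeric vector, longer than `window`.
#' @param window odd window length (samples).
#' @param polyorder polynomial order, < `window`.
#' @return smoothed numeric vector of the same length.
#' @export
sg_smooth <- function(series, window = 15, polyorder = 2) {
  n <- length(series)
  if (window %% 2 != 1) stop("sg_smooth: window must be odd")
  if (n <= window) stop("sg_smooth: series must be longer than the window")
  H <- .sg_hat(window, polyorder, 0L)
  h <- (window - 1L) %/% 2L
  centre <- H[h + 1L, ]
  out <- as.numeric(stats::filter(series, rev(centre), sides = 2))
  out[seq_len(h)] <- as.numeric(H[seq_len(h), ] %*% series[seq_len(window)])
  out[(n - h + 1L):n] <- as.numeric(H[(h + 2L):window, ] %*% series[(n - window + 1L):n])
  out
}

#' Savitzky-Golay first derivative
#'
#' Same local fits as [sg_smooth()], returning the fitted slope per sample,
#' scaled by the sample interval.
#'
#' @inheritParams sg_smooth
#' @param dt sample interval (s); the result is in signal units per second.
#' @return derivative series of the same length.
#' @export
sg_derivative <- function(series, dt = 1, window = 15, polyorder = 2) {
  n <- length(series)
  if (window %% 2 != 1) stop("sg_derivative: window must be odd")
  if (n <= window) stop("sg_derivative: series must be longer than the window")
  H <- .sg_hat(window, polyorder, 1L)
  h <- (window - 1L) %/% 2L
  centre <- H[h + 1L, ]
  out <- as.numeric(stats::filter(series, rev(centre), sides = 2))
  out[seq_len(h)] <- as.numeric(H[seq_len(h), ] %*% series[seq_len(window)])
  out[(n - h + 1L):n] <- as.numeric(H[(h + 2L):window, ] %*% series[(n - window + 1L):n])
  out / dt
}

#' Robust noise SD from the MAD of first differences
#'
#' `1.4826 * median(|d - median(d)|) / sqrt(2)` where `d` are the sequential
#' differences of the series. The 1.4826 factor calibrates the MAD to a
#' Gaussian SD; the `sqrt(2)` corrects for the variance doubling of first
#' differences, so the estimator targets the per-sample noise SD and is
#' insensitive to slow trends and steps.
#'
#' @param series numeric vector, length >= 2.
#' @return noise SD estimate (0 for a constant series).
#' @export
mad_sigma <- function(series) {
  if (length(series) < 2) stop("mad_sigma: need at least 2 samples")
  d <- diff(series)
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

#' Change-point step fitting by penalized greedy binary splitting
#'
#' Fits a piecewise-constant model: repeatedly split the plateau whose best
#' single split maximally reduces the residual sum of squares, and stop when
#' the best improvement falls below `sensitivity * sigma^2 * log(n)` with
#' `sigma` the [mad_sigma()] noise estimate. Deterministic for fixed input.
#'
#' For smoothed inputs (e.g. a Savitzky-Golay derivative) adjacent samples
#' are correlated; supply `corr_len` (the smoothing window) so the noise is
#' estimated from lag-`corr_len` differences and the penalty is scaled by the
#' effective sample correlation length.
#'
#' @param series numeric vector, length >= 4.
#' @param sensitivity penalty multiplier; larger values yield fewer steps.
#' @param sigma noise SD; estimated from the series by default.
#' @param corr_len correlation length of the noise (samples); 1 for raw data.
#' @return an object of class `step_fit`: `change_points` (indices of the
#'   first sample of each new plateau), `levels` (plateau means),
#'   `plateaus` (data frame `start`, `end`, `level`), `residual_sd`.
#' @export
fit_steps <- function(series, sensitivity = 3, sigma = NULL, corr_len = 1) {
  n <- length(series)
  if (n < 4) stop("fit_steps: need at least 4 samples")
  if (is.null(sigma)) {
    sigma <- if (corr_len <= 1) mad_sigma(series) else {
      lag <- min(as.integer(corr_len), n - 1L)
      d <- series[(1 + lag):n] - series[seq_len(n - lag)]
      1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
    }
  }
  threshold <- max(sensitivity * sigma^2 * corr_len * log(n),
                   1e-10 * max(stats::var(series), .Machine$double.eps))
  cs <- cumsum(series); cs2 <- cumsum(series^2)
  seg_rss <- function(a, b) { # RSS of samples a..b around their mean
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    s2 - s^2 / (b - a + 1)
  }
  best_split <- function(a, b) {
    if (b - a < 1) return(c(NA, -Inf))
    ks <- a:(b - 1)                        # last index of the left part
    sl <- cs[ks] - if (a > 1) cs[a - 1] else 0
    sl2 <- cs2[ks] - if (a > 1) cs2[a - 1] else 0
    nl <- ks - a + 1
    rss_l <- sl2 - sl^2 / nl
    st <- cs[b] - cs[ks]; st2 <- cs2[b] - cs2[ks]
    nr <- b - ks
    rss_r <- st2 - st^2 / nr
    gain <- seg_rss(a, b) - (rss_l + rss_r)
    k <- which.max(gain)                   # first max: deterministic
    c(ks[k], gain[k])
  }
  bounds <- list(c(1L, n))
  splits <- lapply(bounds, function(ab) best_split(ab[1], ab[2]))
  repeat {
    gains <- vapply(splits, `[`, numeric(1), 2L)
    j <- which.max(gains)
    if (!is.finite(gains[j]) || gains[j] <= threshold) break
    ab <- bounds[[j]]; k <- as.integer(splits[[j]][1])
    left <- c(ab[1], k); right <- c(k + 1L, ab[2])
    bounds[[j]] <- left
    bounds[[length(bounds) + 1L]] <- right
    splits[[j]] <- best_split(left[1], left[2])
    splits[[length(splits) + 1L]] <- best_split(right[1], right[2])
  }
  starts <- vapply(bounds, `[`, integer(1), 1L)
  ord <- order(starts)
  bounds <- bounds[ord]
  plateaus <- data.frame(start = vapply(bounds, `[`, integer(1), 1L),
                         end = vapply(bounds, `[`, integer(1), 2L))
  plateaus$level <- mapply(function(a, b) (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1),
                           plateaus$start, plateaus$end)
  fitted <- rep(plateaus$level, plateaus$end - plateaus$start + 1L)
  structure(list(change_points = plateaus$start[-1],
                 levels = plateaus$level,
                 plateaus = plateaus,
                 residual_sd = stats::sd(series - fitted)),
            class = "step_fit")
}

#' Per-sample fitted levels of a step fit
#' @param fit a [fit_steps()] result.
#' @return numeric vector of plateau levels, one per sample.
#' @export
step_levels <- function(fit) {
  rep(fit$levels, fit$plateaus$end - fit$plateaus$start + 1L)
}

#' Piecewise-linear change-point fit
#'
#' Greedy binary splitting with an independent linear fit per segment:
#' repeatedly split the segment whose best split maximally reduces the
#' residual sum of squares, stopping when the improvement falls below
#' `sensitivity * sigma^2 * log(n)` (`sigma` = [mad_sigma()] of the series,
#' i.e. the iid sample noise). This is the engine for base-pair traces, whose
#' natural model is piecewise-constant *rate*: each segment's slope is the
#' local catalytic rate. Deterministic for fixed input.
#'
#' @param series numeric vector (e.g. base pairs per sample).
#' @param dt sample interval (s); slopes are returned per second.
#' @param sensitivity penalty multiplier (calibrated on null data so that a
#'   fitted extra segment on pure linear-plus-noise input is rare).
#' @param min_seg minimum segment length (samples).
#' @return object of class `linear_segments`: data frame `segments` with
#'   `start`, `end`, `slope` (units/s), `intercept` (value at segment start),
#'   plus `residual_sd`.
#' @export
fit_linear_segments <- function(series, dt = 1, sensitivity = 4, min_seg = 6) {
  n <- length(series)
  if (n < 2 * min_seg) stop("fit_linear_segments: series too short")
  y <- series - mean(series)
  x <- seq_len(n) - (n + 1) / 2
  cy <- cumsum(y); cy2 <- cumsum(y^2); cxy <- cumsum(x * y)
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  ssum <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  seg_stats <- function(a, b) {
    m <- b - a + 1
    sx <- ssum(cx, a, b); sy <- ssum(cy, a, b)
    sxx <- ssum(cx2, a, b); sxy <- ssum(cxy, a, b); syy <- ssum(cy2, a, b)
    vx <- sxx - sx^2 / m
    beta <- if (vx > 0) (sxy - sx * sy / m) / vx else 0
    rss <- syy - sy^2 / m - beta^2 * vx
    c(rss = max(rss, 0), beta = beta, mean_y = sy / m, mean_x = sx / m)
  }
  rss_vec <- function(a, b) { # vectorised over equal-length index vectors
    m <- b - a + 1
    p <- ifelse(a > 1, a - 1, 0)
    at0 <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1)], 0)
    sx <- cx[b] - at0(cx, p); sy <- cy[b] - at0(cy, p)
    sxx <- cx2[b] - at0(cx2, p); sxy <- cxy[b] - at0(cxy, p)
    syy <- cy2[b] - at0(cy2, p)
    vx <- sxx - sx^2 / m
    beta <- ifelse(vx > 0, (sxy - sx * sy / m) / vx, 0)
    pmax(syy - sy^2 / m - beta^2 * vx, 0)
  }
  best_split <- function(a, b) {
    if (b - a + 1 < 2 * min_seg) return(c(NA, -Inf))
    parent <- rss_vec(a, b)
    ks <- (a + min_seg - 1):(b - min_seg)
    gains <- parent - rss_vec(rep(a, length(ks)), ks) -
      rss_vec(ks + 1, rep(b, length(ks)))
    i <- which.max(gains)
    c(ks[i], gains[i])
  }
  sigma <- mad_sigma(series)
  threshold <- max(sensitivity * sigma^2 * log(n),
                   1e-10 * max(stats::var(series), .Machine$double.eps))
  bounds <- list(c(1L, n))
  splits <- list(best_split(1L, n))
  repeat {
    gains <- vapply(splits, `[`, numeric(1), 2L)
    j <- which.max(gains)
    if (!is.finite(gains[j]) || gains[j] <= threshold) break
    ab <- bounds[[j]]; k <- as.integer(splits[[j]][1])
    left <- c(ab[1], k); right <- c(k + 1L, ab[2])
    bounds[[j]] <- left
    bounds[[length(bounds) + 1L]] <- right
    splits[[j]] <- best_split(left[1], left[2])
    splits[[length(splits) + 1L]] <- best_split(right[1], right[2])
  }
  starts <- vapply(bounds, `[`, integer(1), 1L)
  bounds <- bounds[order(starts)]
  segs <- data.frame(start = vapply(bounds, `[`, integer(1), 1L),
                     end = vapply(bounds, `[`, integer(1), 2L))
  # boundary refinement: greedy split points are conditioned on the parent
  # segment; re-optimise each internal boundary between its neighbours
  if (nrow(segs) > 1) {
    for (sweep in 1:3) {
      moved <- FALSE
      for (j in seq_len(nrow(segs) - 1L)) {
        a <- segs$start[j]; b <- segs$end[j + 1L]
        if (b - a + 1 < 2 * min_seg) next
        ks <- (a + min_seg - 1):(b - min_seg)
        rss <- rss_vec(rep(a, length(ks)), ks) + rss_vec(ks + 1, rep(b, length(ks)))
        k <- ks[which.min(rss)]
        if (k != segs$end[j]) {
          segs$end[j] <- k; segs$start[j + 1L] <- k + 1L
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  st <- t(vapply(seq_len(nrow(segs)),
                 function(i) seg_stats(segs$start[i], segs$end[i]),
                 numeric(4)))
  segs$slope <- st[, "beta"] / dt
  # value of the fitted line at the segment's first sample, in original units
  segs$intercept <- mean(series) + st[, "mean_y"] +
    st[, "beta"] * (segs$start - (n + 1) / 2 - st[, "mean_x"])
  fitted <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    idx <- segs$start[i]:segs$end[i]
    mean(series) + st[i, "mean_y"] + st[i, "beta"] * (idx - (n + 1) / 2 - st[i, "mean_x"])
  }))
  structure(list(segments = segs, residual_sd = stats::sd(series - fitted)),
            class = "linear_segments")
}

#' Threshold binarization of a signal
#'
#' `state = 1` where the background-subtracted series exceeds
#' `k_sigma * sigma`. The background level is the median of a declared
#' background region (emulating an off-junction reference box) or of the full
#' series; sigma comes from the same region via [mad_sigma()] unless supplied.
#'
#' @param series numeric vector.
#' @param time optional time stamps (defaults to 0-based sample index).
#' @param k_sigma threshold multiplier, in [3, 5].
#' @param sigma_source `"mad"` (full series) or `"background_region"`.
#' @param background_region integer indices of background samples within
#'   `series`, or use `background_series`.
#' @param background_series photon counts from an off-junction reference box
#'   of the same size (takes precedence over `background_region`).
#' @return a `binary_trace` data frame with columns `time`, `state`;
#'   attributes `threshold_used`, `k_sigma`, `background`.
#' @export
binarize <- function(series, time = seq_along(series) - 1,
                     k_sigma = 4,
                     sigma_source = c("mad", "background_region"),
                     background_region = NULL, background_series = NULL) {
  sigma_source <- match.arg(sigma_source)
  if (k_sigma < 3 || k_sigma > 5) stop("binarize: k_sigma must lie in [3, 5]")
  ref <- if (sigma_source == "background_region") {
    if (!is.null(background_series)) background_series
    else if (!is.null(background_region)) series[background_region]
    else stop("binarize: background_region or background_series required")
  } else series
  bg <- stats::median(ref, na.rm = TRUE)
  sigma <- mad_sigma(ref[!is.na(ref)])
  thr <- bg + k_sigma * sigma
  state <- as.integer(!is.na(series) & series > thr)
  structure(data.frame(time = time, state = state),
            class = c("binary_trace", "data.frame"),
            threshold_used = thr, k_sigma = k_sigma, background = bg)
}

#' Remove short runs of 1 from a binary trace
#'
#' Runs of 1 shorter than `min_len` samples are set to 0; runs of 0 are never
#' modified, so the filter is idempotent. Mirrors the "more than ~3 adjacent
#' fluorescent pixels (~1 s)" event filter.
#'
#' @param binary a [binarize()] result (or data frame with `time`, `state`).
#' @param min_len minimum surviving run length (samples).
#' @return filtered `binary_trace`.
#' @export
min_run_filter <- function(binary, min_len = 3) {
  state <- binary$state
  r <- rle(state)
  r$values[r$values == 1L & r$lengths < min_len] <- 0L
  out <- binary
  out$state <- inverse.rle(r)
  out
}
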