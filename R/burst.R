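## Activity classification, pause detection, burst-segment extraction and
## the eight-configuration memory-effect statistic.

#' Force-regime pause thresholds
#'
#' Catalytic rates a factor ~10 below the functional activity are scored as
#' pauses: below 10 bp/s in the exonucleolysis regime (>= 40 pN) and below
#' 20 bp/s in the polymerisation regime (<= 20 pN). Forces in the undeclared
#' 20-40 pN band are left unclassified.
#'
#' @param high_force_cutoff pause cutoff (bp/s) for the exo regime.
#' @param low_force_cutoff pause cutoff (bp/s) for the pol regime.
#' @param exo_force_min lower force bound of the exo regime (pN).
#' @param pol_force_max upper force bound of the pol regime (pN).
#' @return an object of class `pause_thresholds`.
#' @export
pause_thresholds <- function(high_force_cutoff = 10, low_force_cutoff = 20,
                             exo_force_min = 40, pol_force_max = 20) {
  if (high_force_cutoff <= 0 || low_force_cutoff <= 0)
    stop("pause cutoffs must be positive")
  structure(list(high_force_cutoff = high_force_cutoff,
                 low_force_cutoff = low_force_cutoff,
                 exo_force_min = exo_force_min,
                 pol_force_max = pol_force_max),
            class = "pause_thresholds")
}

# regime pause cutoff per force; NA in the undeclared middle band
.regime_cutoff <- function(force, thresholds) {
  ifelse(force >= thresholds$exo_force_min, thresholds$high_force_cutoff,
         ifelse(force <= thresholds$pol_force_max, thresholds$low_force_cutoff,
                NA_real_))
}

#' Classify a catalytic rate as exo, pol or pause
#'
#' Rates below the regime cutoff in magnitude are pauses; otherwise the sign
#' decides: negative (base-pair removal) is exonucleolysis, positive is
#' polymerisation. Forces in the 20-40 pN band return `"unclassified"`.
#'
#' @param rate catalytic rate (bp/s); vectorised.
#' @param force template tension (pN); scalar or same length.
#' @param thresholds a [pause_thresholds()] object.
#' @return character vector in `{"exo", "pol", "pause", "unclassified"}`.
#' @export
classify_rate <- function(rate, force, thresholds = pause_thresholds()) {
  cutoff <- .regime_cutoff(force, thresholds)
  out <- ifelse(is.na(cutoff), "unclassified",
                ifelse(abs(rate) < cutoff, "pause",
                       ifelse(rate < 0, "exo", "pol")))
  as.character(out)
}

#' Simplify an activity label to enzymatic (E) or paused (P)
#' @param label character vector of activity labels.
#' @return `"E"` for exo/pol, `"P"` for pause, NA otherwise.
#' @export
simplify_label <- function(label) {
  ifelse(label %in% c("exo", "pol"), "E",
         ifelse(label == "pause", "P", NA_character_))
}

#' Piecewise-constant rate fit of a base-pair trace
#'
#' Segments the base-pair trace with a penalized piecewise-linear
#' change-point fit ([fit_linear_segments()]); each linear segment's slope is
#' the local catalytic rate, so the result is a piecewise-constant rate
#' ("plateau") model, classified per segment with [classify_rate()]. Fitting
#' lines on the raw trace (rather than step-fitting a smoothed derivative)
#' keeps the noise independent and the change-point penalty well calibrated;
#' the Savitzky-Golay utilities remain available for display and for
#' fluorescence traces.
#'
#' @param bp_trace data frame with columns `time_s` and `basepairs_ds`
#'   (e.g. a [reconstruct_junction()] result).
#' @param force force values aligned with `bp_trace` (vector or a
#'   [force_extension_trace()] resampled by nearest time).
#' @param sensitivity change-point penalty multiplier.
#' @param min_seg minimum segment length (samples).
#' @param thresholds a [pause_thresholds()] object.
#' @return object of class `activity_fit`: `time` (s), `dt`, `rate` (bp/s per
#'   sample), `plateaus` data frame (`start`, `end`, `t_start`, `t_end`,
#'   `rate_bps`, `force_pN`, `label`).
#' @export
activity_step_fit <- function(bp_trace, force, sensitivity = 4, min_seg = 6,
                              thresholds = pause_thresholds()) {
  time <- bp_trace$time_s
  bp <- bp_trace$basepairs_ds
  ok <- is.finite(bp)
  time <- time[ok]; bp <- bp[ok]
  if (inherits(force, "data.frame"))
    force <- .resample_nearest(force$time_s, force$force_pN, time)
  else force <- force[ok]
  dt <- stats::median(diff(time))
  fit <- fit_linear_segments(bp, dt, sensitivity = sensitivity, min_seg = min_seg)
  pl <- fit$segments
  pl$t_start <- time[pl$start]
  pl$t_end <- time[pl$end] + dt
  pl$rate_bps <- pl$slope
  pl$force_pN <- vapply(seq_len(nrow(pl)),
                        function(i) stats::median(force[pl$start[i]:pl$end[i]]),
                        numeric(1))
  pl$label <- classify_rate(pl$rate_bps, pl$force_pN, thresholds)
  rate <- rep(pl$rate_bps, pl$end - pl$start + 1L)
  structure(list(time = time, dt = dt, rate = rate, series = bp,
                 plateaus = pl[, c("start", "end", "t_start", "t_end",
                                   "rate_bps", "force_pN", "label")]),
            class = "activity_fit")
}

#' Detect pauses in a base-pair trace
#'
#' Pauses are step-fit rate plateaus whose absolute rate is below the
#' force-regime cutoff and whose duration is at least `min_duration`
#' (default: ten times the single-base traversal time at the cutoff, i.e.
#' `10 / cutoff` seconds). Adjacent sub-cutoff plateaus are merged, and each
#' candidate then grows outward, absorbing neighbouring plateaus as long as
#' the joint linear refit of the base-pair trace over the extended interval
#' stays below the cutoff; this protects slow stretches that the change-point
#' fit fragmented into short noisy pieces.
#'
#' @param bp_trace,force,sensitivity see [activity_step_fit()]; a
#'   precomputed `activity_fit` can be supplied instead of `bp_trace`.
#' @param thresholds a [pause_thresholds()] object.
#' @param min_duration minimum pause duration (s); `NULL` for the default.
#' @return data frame `t_start`, `t_end`, `duration`, `rate_bps`.
#' @export
detect_pauses <- function(bp_trace, force = NULL,
                          thresholds = pause_thresholds(),
                          min_duration = NULL, sensitivity = 4) {
  afit <- if (inherits(bp_trace, "activity_fit")) bp_trace
  else activity_step_fit(bp_trace, force, sensitivity,
                         thresholds = thresholds)
  pl <- afit$plateaus
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), rate_bps = numeric(0))
  cutoff <- .regime_cutoff(pl$force_pN, thresholds)
  is_pause <- !is.na(cutoff) & abs(pl$rate_bps) < cutoff
  if (!any(is_pause)) return(empty)
  # joint rate of plateaus a..b by linear refit of the base-pair samples
  joint_rate <- function(a, b) {
    idx <- pl$start[a]:pl$end[b]
    t <- afit$time[idx]; y <- afit$series[idx]
    sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  }
  # seeds: maximal runs of sub-cutoff plateaus
  r <- rle(is_pause)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(a = starts[r$values], b = ends[r$values])
  # grow each seed while the joint refit stays below the seed's cutoff
  grown <- lapply(seq_len(nrow(runs)), function(g) {
    a <- unname(runs[g, "a"]); b <- unname(runs[g, "b"])
    co <- stats::median(cutoff[a:b], na.rm = TRUE)
    repeat {
      ext <- FALSE
      if (a > 1 && !is.na(cutoff[a - 1]) && abs(joint_rate(a - 1, b)) < co) {
        a <- a - 1; ext <- TRUE
      }
      if (b < nrow(pl) && !is.na(cutoff[b + 1]) && abs(joint_rate(a, b + 1)) < co) {
        b <- b + 1; ext <- TRUE
      }
      if (!ext) break
    }
    c(a = a, b = b, cutoff = co)
  })
  grown <- do.call(rbind, grown)
  # merge overlapping grown intervals
  grown <- grown[order(grown[, "a"]), , drop = FALSE]
  merged <- list(grown[1, ])
  for (i in seq_len(nrow(grown))[-1]) {
    last <- merged[[length(merged)]]
    if (grown[i, "a"] <= last["b"] + 1) {
      last["b"] <- max(last["b"], grown[i, "b"])
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- grown[i, ]
  }
  out <- do.call(rbind, lapply(merged, function(m) {
    a <- m[["a"]]; b <- m[["b"]]
    dur <- pl$t_end[b] - pl$t_start[a]
    md <- if (is.null(min_duration)) 10 / m[["cutoff"]] else min_duration
    if (dur < md) return(NULL)
    data.frame(t_start = pl$t_start[a], t_end = pl$t_end[b],
               duration = dur, rate_bps = joint_rate(a, b))
  }))
  if (is.null(out)) empty else out
}

#' Extract burst segments from a binarized fluorescence trace
#'
#' One segment per maximal run of 1 in the (min-run-filtered) binarized
#' junction fluorescence. Within each segment the step-fitted rate plateaus
#' define activity sub-intervals; a segment is `single`-type iff all
#' sub-interval labels agree, else `transitional`.
#'
#' @param binary_fluor a [binarize()]/[min_run_filter()] result whose `time`
#'   column is in seconds (kymograph line times).
#' @param bp_trace,force_trace,thresholds,sensitivity see
#'   [activity_step_fit()]; a precomputed `activity_fit` may be supplied as
#'   `bp_trace` (then `force_trace` is ignored).
#' @param min_run minimum run length (samples) enforced with
#'   [min_run_filter()].
#' @param min_sub_duration sub-intervals shorter than this (s) are ignored
#'   when determining the segment type (guards against boundary jitter
#'   between the fluorescence and activity time bases); if all sub-intervals
#'   are shorter, the longest one decides. The default matches the
#'   pipeline-wide event resolution of ~3 kymograph lines (the same
#'   convention as `min_run` and the cluster filter).
#' @return a `burst_segments` data frame: `t_start`, `t_end`, `duration`,
#'   `segment_type`, `n_sub`, `labels`, `mean_rate`, `during_state`, plus the
#'   activity fit in the `"activity_fit"` attribute. Sub-interval tables are
#'   in the `"sub_intervals"` attribute.
#' @export
extract_segments <- function(binary_fluor, bp_trace, force_trace = NULL,
                             thresholds = pause_thresholds(),
                             sensitivity = 4, min_run = 3,
                             min_sub_duration = 0.3) {
  afit <- if (inherits(bp_trace, "activity_fit")) bp_trace
  else activity_step_fit(bp_trace, force_trace, sensitivity,
                         thresholds = thresholds)
  bf <- min_run_filter(binary_fluor, min_run)
  dt_line <- stats::median(diff(bf$time))
  r <- rle(bf$state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values == 1L)
  pl <- afit$plateaus
  seg_rows <- list(); sub_tabs <- list()
  for (g in runs) {
    t0 <- bf$time[starts[g]]
    t1 <- bf$time[ends[g]] + dt_line
    ov <- pl[pl$t_end > t0 & pl$t_start < t1, , drop = FALSE]
    if (nrow(ov) == 0) next
    ov$t_start <- pmax(ov$t_start, t0)
    ov$t_end <- pmin(ov$t_end, t1)
    ov <- ov[ov$t_end - ov$t_start > 1e-9, , drop = FALSE]
    if (nrow(ov) == 0) next
    w <- ov$t_end - ov$t_start
    substantial <- w >= min_sub_duration
    if (!any(substantial)) substantial <- w == max(w)
    labels <- unique(ov$label[substantial])
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      t_start = t0, t_end = t1, duration = t1 - t0,
      segment_type = if (length(labels) == 1L) "single" else "transitional",
      n_sub = sum(substantial), labels = paste(ov$label[substantial], collapse = ","),
      mean_rate = sum(ov$rate_bps * w) / sum(w),
      during_state = if (length(labels) == 1L) simplify_label(labels) else NA_character_,
      stringsAsFactors = FALSE)
    sub_tabs[[length(sub_tabs) + 1L]] <-
      ov[, c("t_start", "t_end", "rate_bps", "force_pN", "label")]
  }
  segs <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(t_start = numeric(0), t_end = numeric(0), duration = numeric(0),
               segment_type = character(0), n_sub = integer(0),
               labels = character(0), mean_rate = numeric(0),
               during_state = character(0))
  structure(segs, class = c("burst_segments", "data.frame"),
            activity_fit = afit, sub_intervals = sub_tabs)
}

#' Flanking activity states of burst segments
#'
#' For each segment, classifies the step-fit plateau immediately before
#' `t_start` and immediately after `t_end` (evaluated `flank_window` capped),
#' simplified to E/P. Segments without a full `flank_window` margin inside
#' the trace get NA flanks and are excluded from memory counts.
#'
#' @param segments a [extract_segments()] result.
#' @param afit the `activity_fit` (defaults to the one stored in `segments`).
#' @param flank_window required margin inside the trace (s).
#' @return `segments` with `pre_state` and `post_state` columns added.
#' @export
flanking_states <- function(segments, afit = attr(segments, "activity_fit"),
                            flank_window = 0.5) {
  pl <- afit$plateaus
  t_lo <- min(pl$t_start); t_hi <- max(pl$t_end)
  state_at <- function(t) {
    i <- which(pl$t_start <= t & pl$t_end > t)
    if (!length(i)) return(NA_character_)
    simplify_label(pl$label[i[1]])
  }
  pre <- post <- rep(NA_character_, nrow(segments))
  for (i in seq_len(nrow(segments))) {
    if (segments$t_start[i] - t_lo >= flank_window)
      pre[i] <- state_at(segments$t_start[i] - 1e-6)
    if (t_hi - segments$t_end[i] >= flank_window)
      post[i] <- state_at(segments$t_end[i] + 1e-6)
  }
  segments$pre_state <- pre
  segments$post_state <- post
  segments
}

#' Eight-configuration memory-effect counts
#'
#' Counts the (pre, during, post) state triplets over {E, P}^3 for
#' single-type segments with available flanks. Fractions carry
#' square-root-of-count error bars.
#'
#' @param segments a [flanking_states()] result, or a data frame with
#'   `pre_state`, `during_state`, `post_state` (and optionally
#'   `segment_type`).
#' @return object of class `memory_counts`: named `counts` over the 8
#'   triplets (`"EEE"` = E before, E during, E after, etc.), `fractions`,
#'   `frac_se`, `n_total`, `n_excluded`.
#' @export
memory_configuration_counts <- function(segments) {
  keep <- rep(TRUE, nrow(segments))
  if ("segment_type" %in% names(segments))
    keep <- keep & segments$segment_type == "single"
  keep <- keep &
    segments$pre_state %in% c("E", "P") &
    segments$during_state %in% c("E", "P") &
    segments$post_state %in% c("E", "P")
  s <- segments[keep, , drop = FALSE]
  lv <- c("EEE", "EEP", "EPE", "EPP", "PEE", "PEP", "PPE", "PPP")
  trip <- paste0(s$pre_state, s$during_state, s$post_state)
  counts <- table(factor(trip, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  n <- sum(counts)
  fr <- if (n > 0) counts / n else counts * 0
  structure(list(counts = counts, fractions = fr,
                 frac_se = if (n > 0) sqrt(counts) / n else counts * 0,
                 n_total = n, n_excluded = nrow(segments) - nrow(s)),
            class = "memory_counts")
}

#' Chi-squared test of triplet independence
#'
#' Tests whether the (pre, during, post) triplet distribution factorises into
#' the product of its marginals (no memory). Expected counts come from the
#' observed marginal E/P frequencies at each position; the statistic is
#' compared to chi-squared with 8 - 1 - 3 = 4 degrees of freedom.
#'
#' @param mc a [memory_configuration_counts()] result.
#' @return list `statistic`, `df`, `p_value`, `expected`.
#' @export
memory_independence_test <- function(mc) {
  counts <- mc$counts
  n <- sum(counts)
  if (n == 0) stop("memory_independence_test: no counts")
  keys <- names(counts)
  pos <- function(k) substring(keys, k, k)
  pE <- vapply(1:3, function(k) sum(counts[pos(k) == "E"]) / n, numeric(1))
  expected <- n * vapply(seq_along(keys), function(i) {
    prod(vapply(1:3, function(k)
      if (substring(keys[i], k, k) == "E") pE[k] else 1 - pE[k], numeric(1)))
  }, numeric(1))
  names(expected) <- keys
  use <- expected > 0
  stat <- sum((counts[use] - expected[use])^2 / expected[use])
  df <- 4
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}
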