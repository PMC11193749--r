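## Binarized activity x fluorescence correlation series, event clustering,
## and the derived fluorescent-event and non-fluorescent-pause fractions.

#' Binarize polymerase activity on a target time base
#'
#' Activity is 1 where the absolute step-fitted plateau rate exceeds the
#' force-regime pause cutoff; samples in the undeclared 20-40 pN band are NA.
#'
#' @param afit an [activity_step_fit()] result.
#' @param times target time stamps (s), e.g. kymograph line times.
#' @param thresholds a [pause_thresholds()] object.
#' @return a `binary_trace` data frame (`time`, `state`).
#' @export
activity_to_binary <- function(afit, times, thresholds = pause_thresholds()) {
  pl <- afit$plateaus
  state <- rep(NA_integer_, length(times))
  for (i in seq_len(nrow(pl))) {
    idx <- times >= pl$t_start[i] & times < pl$t_end[i]
    cutoff <- .regime_cutoff(pl$force_pN[i], thresholds)
    state[idx] <- if (is.na(cutoff)) NA_integer_
    else as.integer(abs(pl$rate_bps[i]) >= cutoff)
  }
  structure(data.frame(time = times, state = state),
            class = c("binary_trace", "data.frame"))
}

#' Pair binarized fluorescence and activity into a correlation series
#'
#' Per sample, the class is `[fluorescence, activity]`: `"11"` fluorescent
#' active, `"10"` fluorescent pausing, `"01"` non-fluorescent active, `"00"`
#' non-fluorescent pausing. Both traces must share the same time base.
#'
#' @param binary_fluor,binary_activity `binary_trace` data frames on the
#'   same time base.
#' @return a `correlation_series` data frame: `time`, `fluor`, `active`,
#'   `class` (NA where either input is NA).
#' @export
build_correlation_series <- function(binary_fluor, binary_activity) {
  if (nrow(binary_fluor) != nrow(binary_activity) ||
      max(abs(binary_fluor$time - binary_activity$time)) > 1e-9)
    stop("build_correlation_series: traces are not on the same time base")
  cls <- ifelse(is.na(binary_fluor$state) | is.na(binary_activity$state),
                NA_character_,
                paste0(binary_fluor$state, binary_activity$state))
  structure(data.frame(time = binary_fluor$time,
                       fluor = binary_fluor$state,
                       active = binary_activity$state,
                       class = cls, stringsAsFactors = FALSE),
            class = c("correlation_series", "data.frame"))
}

#' Count molecular-event clusters per correlation class
#'
#' A cluster is a maximal run of identical class values; runs shorter than
#' `min_len` samples are discarded (the ~3-pixel / ~1 s event filter).
#'
#' @param series a [build_correlation_series()] result.
#' @param min_len minimum cluster length (samples).
#' @return object of class `event_cluster_counts`: `n11`, `n10`, `n01`,
#'   `n00`, `total`.
#' @export
cluster_events <- function(series, min_len = 3) {
  cls <- series$class
  r <- rle(cls)
  keep <- !is.na(r$values) & r$lengths >= min_len
  v <- r$values[keep]
  counts <- vapply(c("11", "10", "01", "00"), function(k) sum(v == k), integer(1))
  structure(list(n11 = counts[["11"]], n10 = counts[["10"]],
                 n01 = counts[["01"]], n00 = counts[["00"]],
                 total = sum(counts)),
            class = "event_cluster_counts")
}

#' Fraction of events that are fluorescent
#'
#' `(n11 + n10) / (n11 + n10 + n01 + n00)`: the share of observed event
#' clusters carrying a fluorescent (labeled, unbleached) polymerase.
#'
#' @param counts an [cluster_events()] result or list with `n11`, `n10`,
#'   `n01`, `n00`.
#' @return fraction in [0, 1].
#' @export
fluorescent_event_fraction <- function(counts) {
  tot <- counts$n11 + counts$n10 + counts$n01 + counts$n00
  if (tot == 0) stop("fluorescent_event_fraction: zero total event count")
  (counts$n11 + counts$n10) / tot
}

#' Fraction of pausing events that are non-fluorescent
#'
#' `n00 / (n00 + n10)`: among all paused states, the share without a
#' fluorescent polymerase (pauses plausibly caused by dissociation). Returns
#' NA (flagged missing) when the molecule has no pause clusters at all.
#'
#' @inheritParams fluorescent_event_fraction
#' @return fraction in [0, 1], or NA when `n00 + n10 == 0`.
#' @export
nonfluorescent_pause_fraction <- function(counts) {
  den <- counts$n00 + counts$n10
  if (den == 0) return(NA_real_)
  counts$n00 / den
}
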