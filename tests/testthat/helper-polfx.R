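# shared fixtures and independent oracles for the test suite

# length of overlap between interval [a0,a1] and intervals [b0,b1] (vectors)
interval_overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

# precision/recall of detected pause intervals against truth zero-rate
# intervals, scored at >= 50% coverage; recall over truth pauses >= min_dur
pause_scores <- function(detected, truth, min_truth_duration = 1.5) {
  prec <- if (nrow(detected) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(detected)), function(i) {
      ov <- sum(interval_overlap(detected$t_start[i], detected$t_end[i],
                                 truth$t_start, truth$t_end))
      ov >= 0.5 * detected$duration[i]
    }, logical(1)))
  big <- truth[truth$duration >= min_truth_duration, , drop = FALSE]
  rec <- if (nrow(big) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(big)), function(i) {
      ov <- sum(interval_overlap(big$t_start[i], big$t_end[i],
                                 detected$t_start, detected$t_end))
      ov >= 0.5 * big$duration[i]
    }, logical(1)))
  list(precision = prec, recall = rec, n_truth = nrow(big))
}

# independent brute-force run enumerator for correlation clusters
brute_force_clusters <- function(cls, min_len) {
  counts <- c("11" = 0L, "10" = 0L, "01" = 0L, "00" = 0L)
  i <- 1L
  n <- length(cls)
  while (i <= n) {
    j <- i
    while (j < n && identical(cls[j + 1L], cls[i]) &&
           !is.na(cls[j + 1L]) && !is.na(cls[i])) j <- j + 1L
    if (!is.na(cls[i]) && (j - i + 1L) >= min_len)
      counts[cls[i]] <- counts[cls[i]] + 1L
    i <- j + 1L
  }
  list(n11 = counts[["11"]], n10 = counts[["10"]],
       n01 = counts[["01"]], n00 = counts[["00"]])
}

# non-overlapping (pre, during, post) truth triplets from simulated kinetics,
# using each event's last activity class, simplified to E/P
truth_triplets <- function(truth, stride = 3) {
  cls <- vapply(split(truth$sub_intervals$class, truth$sub_intervals$event),
                function(x) x[length(x)], character(1))
  simp <- ifelse(cls == "pause", "P", "E")
  n <- length(simp)
  idx <- seq(2, n - 1, by = stride)
  data.frame(pre_state = simp[idx - 1], during_state = simp[idx],
             post_state = simp[idx + 1], segment_type = "single",
             stringsAsFactors = FALSE)
}

# minimal synthetic truth with a fixed constant-position junction emitter,
# for isolated kymograph-render tests
static_emitter_truth <- function(position_um = 1.0, duration = 10,
                                 config = simulation_config(),
                                 binders = list(), labeled = TRUE) {
  tg <- seq(0, duration, by = 0.005)
  grid <- data.frame(time = tg, bp = 4000, ss_fraction = 0.5,
                     junction_um = position_um, eed_um = 3,
                     force_pN = 50, rate_bps = 0,
                     occupied = TRUE, visible = labeled)
  events <- data.frame(event = 1L, t_bind = 0, t_unbind = duration,
                       labeled = labeled, t_bleach = 1e9, transitional = FALSE)
  structure(list(events = events,
                 sub_intervals = data.frame(event = 1L, t0 = 0, t1 = duration,
                                            class = "pause", rate_bps = 0),
                 grid = grid,
                 truth_pauses = data.frame(t_start = 0, t_end = duration,
                                           duration = duration),
                 binders = binders,
                 line_times = seq(0, duration - config$line_time,
                                  by = config$line_time),
                 config = config, params = elasticity_params()),
            class = "sim_truth")
}

# noiseless kymograph with a bright one-pixel emitter path (for registration)
path_kymo <- function(pixel_path, n_pix, amp = 100, line_time = 0.1,
                      pixel_size = 0.075) {
  ph <- matrix(0L, nrow = length(pixel_path), ncol = n_pix)
  for (i in seq_along(pixel_path)) ph[i, pixel_path[i]] <- amp
  kymograph(ph, line_time, pixel_size, origin_position = 0,
            bead_band_pixels = 0)
}

# trajectory whose junction_to_pixels mapping equals pixel_path exactly
path_traj <- function(pixel_path, line_time = 0.1, pixel_size = 0.075) {
  data.frame(time_s = (seq_along(pixel_path) - 1) * line_time,
             junction_um = (pixel_path - 0.5) * pixel_size)
}
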