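# activity classification, pause detection, burst segments, memory statistic

th <- pause_thresholds()

test_that("classify_rate reproduces the published regime examples", {
  expect_equal(classify_rate(-62, 50, th), "exo")   # mean exo rate at 50 pN
  expect_equal(classify_rate(5, 50, th), "pause")   # below 10 bp/s at 50 pN
  expect_equal(classify_rate(32, 20, th), "pol")    # mean pol rate at 20 pN
  expect_equal(classify_rate(15, 20, th), "pause")  # below 20 bp/s at 20 pN
  expect_equal(classify_rate(-100, 30, th), "unclassified")
})

test_that("classify_rate is antisymmetric between exo and pol", {
  rates <- c(-200, -62, -11, 11, 62, 200)
  a <- classify_rate(rates, 50, th)
  b <- classify_rate(-rates, 50, th)
  swap <- c(exo = "pol", pol = "exo", pause = "pause")
  expect_equal(b, unname(swap[a]))
  expect_equal(classify_rate(3, 50, th), classify_rate(-3, 50, th))
})

test_that("simplify_label maps to E/P", {
  expect_equal(simplify_label(c("exo", "pol", "pause", "unclassified")),
               c("E", "E", "P", NA))
})

# constructed base-pair trace: dt = 0.05 s, segments of known rate
make_bp_trace <- function(rates, durations, sd = 1, bp0 = 6000, seed = 1) {
  set.seed(seed)
  dt <- 0.05
  rate_series <- rep(rates, round(durations / dt))
  bp <- bp0 + cumsum(rate_series * dt) + rnorm(length(rate_series), 0, sd)
  data.frame(time_s = seq_along(bp) * dt, basepairs_ds = bp)
}

test_that("detect_pauses finds nothing in a monotone ramp", {
  bp <- make_bp_trace(-100, 20)
  expect_equal(nrow(detect_pauses(bp, rep(50, nrow(bp)), th)), 0L)
})

test_that("detect_pauses recovers a constructed flat plateau", {
  bp <- make_bp_trace(c(-100, 0, -100), c(6, 2, 6))
  p <- detect_pauses(bp, rep(50, nrow(bp)), th)
  expect_equal(nrow(p), 1L)
  expect_lt(abs(p$t_start - 6), 0.3)
  expect_lt(abs(p$t_end - 8), 0.3)
  expect_lt(abs(p$rate_bps), 10)
})

test_that("sub-minimum pauses are filtered by duration", {
  bp <- make_bp_trace(c(-100, 0, -100), c(6, 0.6, 6))  # 0.6 s < 1 s at 50 pN
  expect_equal(nrow(detect_pauses(bp, rep(50, nrow(bp)), th)), 0L)
  # the same plateau duration passes in the pol regime (min 0.5 s at 20 pN)
  bp2 <- make_bp_trace(c(150, 0, 150), c(6, 0.7, 6))
  expect_equal(nrow(detect_pauses(bp2, rep(20, nrow(bp2)), th)), 1L)
})

make_binary <- function(state, dt = 0.1) {
  structure(data.frame(time = (seq_along(state) - 1) * dt, state = state),
            class = c("binary_trace", "data.frame"))
}

test_that("extract_segments builds single- and transitional-type segments", {
  # constant exo under one fluorescent run -> single-type exo
  bp <- make_bp_trace(-100, 10)
  state <- rep(0L, 100); state[21:40] <- 1L
  segs <- extract_segments(make_binary(state), bp, rep(50, nrow(bp)), th)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$segment_type, "single")
  expect_equal(segs$during_state, "E")
  expect_lt(abs(segs$mean_rate + 100), 15)
  expect_equal(segs$t_start, 2.0)
  expect_equal(segs$duration, 2.0)
  # exo then flat inside one run -> transitional
  bp2 <- make_bp_trace(c(-100, 0), c(3, 7))
  state2 <- rep(0L, 100); state2[11:50] <- 1L
  segs2 <- extract_segments(make_binary(state2), bp2, rep(50, nrow(bp2)), th)
  expect_equal(segs2$segment_type, "transitional")
  expect_match(segs2$labels, "exo")
  expect_match(segs2$labels, "pause")
  # no runs -> empty
  expect_equal(nrow(extract_segments(make_binary(rep(0L, 100)), bp,
                                     rep(50, nrow(bp)), th)), 0L)
})

test_that("single plus transitional counts equal the total", {
  cfg <- simulation_config(seed = 31L, duration = 120)
  sim <- simulate_experiment(cfg)
  traj <- reconstruct_junction(sim$trace)
  off <- refine_offsets(sim$kymo, traj)
  s <- extract_junction_intensity(sim$kymo, traj, off)
  bf <- min_run_filter(binarize(s$intensity, time = s$time), 3)
  segs <- extract_segments(bf, traj, sim$trace, th)
  expect_equal(sum(segs$segment_type == "single") +
                 sum(segs$segment_type == "transitional"), nrow(segs))
})

test_that("flanking_states reads the adjacent plateaus", {
  # exo - (segment window) - exo: flanks are E
  bp <- make_bp_trace(-100, 12)
  state <- rep(0L, 120); state[41:70] <- 1L
  segs <- extract_segments(make_binary(state), bp, rep(50, nrow(bp)), th)
  segs <- flanking_states(segs)
  expect_equal(segs$pre_state, "E")
  expect_equal(segs$post_state, "E")
  # flat everywhere: flanks are P
  bp2 <- make_bp_trace(0, 12)
  segs2 <- flanking_states(extract_segments(make_binary(state), bp2,
                                            rep(50, nrow(bp2)), th))
  expect_equal(segs2$pre_state, "P")
  expect_equal(segs2$post_state, "P")
  # segment at the trace start has no pre-flank
  state3 <- rep(0L, 120); state3[1:30] <- 1L
  segs3 <- flanking_states(extract_segments(make_binary(state3), bp,
                                            rep(50, nrow(bp)), th))
  expect_true(is.na(segs3$pre_state))
})

test_that("memory counts cover the eight configurations", {
  segs <- data.frame(pre_state = c("E", "E", "P"), during_state = c("E", "E", "P"),
                     post_state = c("E", "E", "P"), segment_type = "single")
  mc <- memory_configuration_counts(segs)
  expect_equal(sum(mc$counts), 3L)
  expect_equal(unname(mc$counts[["EEE"]]), 2L)
  expect_equal(unname(mc$counts[["PPP"]]), 1L)
  expect_equal(sum(mc$fractions), 1)
  expect_equal(names(mc$counts),
               c("EEE", "EEP", "EPE", "EPP", "PEE", "PEP", "PPE", "PPP"))
  # transitional and flank-less segments are excluded
  segs2 <- rbind(segs, data.frame(pre_state = NA, during_state = "E",
                                  post_state = "E", segment_type = "single"))
  expect_equal(memory_configuration_counts(segs2)$n_excluded, 1L)
  # empty input -> all-zero counts
  expect_equal(sum(memory_configuration_counts(segs[0, ])$counts), 0L)
})

test_that("memory independence test separates memory from no memory", {
  base <- list(duration = 1200,
               force_schedule = data.frame(start_s = 0, force_pN = 50),
               p_transition = 0, p_ssdna_binder = 0, p_dsdna_binder = 0)
  tr0 <- simulate_kinetics(do.call(simulation_config,
                                   c(base, seed = 13L, memory_strength = 0)))
  it0 <- memory_independence_test(
    memory_configuration_counts(truth_triplets(tr0)))
  expect_gt(it0$p_value, 0.01)
  tr1 <- simulate_kinetics(do.call(simulation_config,
                                   c(base, seed = 13L, memory_strength = 0.9)))
  it1 <- memory_independence_test(
    memory_configuration_counts(truth_triplets(tr1)))
  expect_lt(it1$p_value, 1e-6)
})
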