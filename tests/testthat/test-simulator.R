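# stochastic exchange simulator: determinism, kinetics, rendering

test_that("fixed seed gives bit-identical truth, trace and kymograph", {
  cfg <- simulation_config(seed = 5L, duration = 30)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$grid, b$truth$grid)
  expect_identical(a$trace$eed_um, b$trace$eed_um)
  expect_identical(a$kymo$photons, b$kymo$photons)
})

test_that("changing the seed changes the kymograph", {
  a <- render_kymograph(simulate_kinetics(simulation_config(seed = 5L, duration = 20)))
  b <- render_kymograph(simulate_kinetics(simulation_config(seed = 6L, duration = 20)))
  expect_false(identical(a$photons, b$photons))
})

test_that("degenerate memory copies the first activity class forever", {
  cfg <- simulation_config(seed = 2L, duration = 200, memory_strength = 1,
                           p_transition = 0,
                           force_schedule = data.frame(start_s = 0, force_pN = 50))
  tr <- simulate_kinetics(cfg)
  expect_gt(nrow(tr$events), 50)
  expect_equal(length(unique(tr$sub_intervals$class)), 1L)
})

test_that("p_labeled = 0 produces no fluorescent truth", {
  cfg <- simulation_config(seed = 2L, duration = 60, p_labeled = 0,
                           p_ssdna_binder = 0, p_dsdna_binder = 0)
  tr <- simulate_kinetics(cfg)
  expect_false(any(tr$events$labeled))
  expect_false(any(tr$grid$visible))
})

test_that("dwell times follow the configured exponentials", {
  # ~1e4 completed bound dwells
  cfg <- simulation_config(seed = 9L, duration = 3600, k_on = 20, tau_off = 0.3,
                           p_ssdna_binder = 0, p_dsdna_binder = 0,
                           force_schedule = data.frame(start_s = 0, force_pN = 50))
  tr <- simulate_kinetics(cfg)
  ev <- tr$events
  done <- ev$t_unbind < cfg$duration
  dw <- (ev$t_unbind - ev$t_bind)[done]
  expect_gt(length(dw), 9000)
  # law of large numbers: sample mean within 3 SE of tau_off
  expect_lt(abs(mean(dw) - 0.3), 3 * 0.3 / sqrt(length(dw)))
  # Kolmogorov-Smirnov at alpha = 0.01
  expect_gt(suppressWarnings(stats::ks.test(dw, stats::pexp, 1 / 0.3))$p.value, 0.01)
  # unbound gaps are exponential(k_on)
  gaps <- ev$t_bind[-1] - ev$t_unbind[-nrow(ev)]
  expect_gt(suppressWarnings(stats::ks.test(gaps, stats::pexp, 20))$p.value, 0.01)
  # labeling fraction converges to p_labeled
  ph <- mean(ev$labeled)
  expect_lt(abs(ph - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(ev)))
  # single occupancy: events never overlap
  expect_true(all(ev$t_bind[-1] >= ev$t_unbind[-nrow(ev)] - 1e-12))
})

test_that("force trace renders the exact mixture when noiseless", {
  cfg <- simulation_config(seed = 4L, duration = 40, eed_noise_sd = 0)
  tr <- simulate_kinetics(cfg)
  trace <- render_force_trace(tr)
  traj <- reconstruct_junction(trace)
  # inverse recovers the latent ssDNA fraction exactly (nearest grid sample)
  ssf_truth <- polfx:::.grid_nearest(tr$grid$time, tr$grid$ss_fraction,
                                     trace$time_s)
  expect_lt(max(abs(traj$ss_fraction - ssf_truth)), 1e-9)
})

test_that("EED noise has the configured scale", {
  cfg <- simulation_config(seed = 4L, duration = 120, eed_noise_sd = 0.002)
  tr <- simulate_kinetics(cfg)
  noisy <- render_force_trace(tr)
  clean <- render_force_trace(tr, simulation_config(seed = 4L, duration = 120,
                                                    eed_noise_sd = 0))
  resid <- noisy$eed_um - clean$eed_um
  expect_lt(abs(stats::sd(resid) / 0.002 - 1), 0.1)
})

test_that("background-only kymograph has Poisson background statistics", {
  cfg <- simulation_config(seed = 8L, duration = 30, photons_per_line_bound = 0,
                           p_ssdna_binder = 0, p_dsdna_binder = 0,
                           background_rate = 2)
  kymo <- render_kymograph(simulate_kinetics(cfg))
  bb <- kymo$bead_band_pixels
  interior <- kymo$photons[, (bb + 1):(ncol(kymo$photons) - bb)]
  expect_lt(abs(mean(interior) - 2), 3 * sqrt(2 / length(interior)))
})

test_that("a static emitter renders at its position (centroid oracle)", {
  cfg <- simulation_config(seed = 3L, photons_per_line_bound = 2000,
                           background_rate = 0, bead_band_pixels = 0)
  truth <- static_emitter_truth(position_um = 1.0, duration = 10, config = cfg)
  kymo <- render_kymograph(truth, cfg)
  centers <- kymo$origin_position + (seq_len(ncol(kymo$photons)) - 0.5) * cfg$pixel_size
  centroids <- apply(kymo$photons, 1, function(row) sum(centers * row) / sum(row))
  expect_lt(abs(mean(centroids) - 1.0), cfg$pixel_size / 2)
})

test_that("total photons scale linearly with the per-line budget", {
  tot <- vapply(c(50, 100), function(amp) {
    cfg <- simulation_config(seed = 3L, photons_per_line_bound = amp,
                             background_rate = 0, bead_band_pixels = 0)
    truth <- static_emitter_truth(position_um = 1.0, duration = 20, config = cfg)
    sum(render_kymograph(truth, cfg)$photons)
  }, numeric(1))
  expect_lt(abs(tot[2] / tot[1] - 2), 0.05)
})

test_that("truth_line_states summarises the latent grid per line", {
  cfg <- simulation_config(seed = 5L, duration = 30)
  tr <- simulate_kinetics(cfg)
  ts <- truth_line_states(tr)
  expect_equal(nrow(ts), length(tr$line_times))
  expect_true(all(ts$visible %in% 0:1))
  expect_true(all(ts$visible_frac >= 0 & ts$visible_frac <= 1))
  # lines fully inside a labeled, unbleached binding are visible
  e <- tr$events[tr$events$labeled, ][1, ]
  mid <- which(ts$time >= e$t_bind & ts$time + cfg$line_time <=
                 min(e$t_unbind, e$t_bleach))
  if (length(mid)) expect_true(all(ts$visible[mid] == 1))
})

test_that("simulation_config validates its fields", {
  expect_error(simulation_config(p_labeled = 1.5))
  expect_error(simulation_config(tau_off = -1))
  expect_error(simulation_config(rate_exo = 100))
  expect_error(simulation_config(force_schedule = data.frame(start_s = 5,
                                                             force_pN = 50)))
})
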