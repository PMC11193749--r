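# kymograph registration, junction-box extraction, position discrimination

test_that("junction positions map to pixel indices", {
  kymo <- kymograph(matrix(0L, 10, 40), 0.1, 0.075, origin_position = 0)
  traj <- data.frame(time_s = (0:9) * 0.1,
                     junction_um = c(0, 10.5 * 0.075, rep(1, 8)))
  jp <- junction_to_pixels(traj, kymo)
  expect_equal(jp$pixel[1], 1L)      # position = origin -> first pixel
  expect_equal(jp$pixel[2], 11L)     # origin + 10.5 px -> pixel 11
  expect_true(all(jp$in_frame[1:2]))
  # out-of-frame flagged
  traj$junction_um[3] <- 100
  expect_false(junction_to_pixels(traj, kymo)$in_frame[3])
  # empty overlap errors
  expect_error(junction_to_pixels(data.frame(time_s = 50, junction_um = 1), kymo),
               "overlap")
})

test_that("refine_offsets is the identity on a pre-aligned kymograph", {
  path <- 10 + round(seq(0, 15, length.out = 60))
  kymo <- path_kymo(path, 40)
  off <- refine_offsets(kymo, path_traj(path))
  expect_equal(off$x_offset, 0L)
  expect_equal(off$y_offset, 0L)
})

test_that("refine_offsets recovers a constructed (+3, -2) shift exactly", {
  set.seed(8)
  # jumpy path so the shift is identifiable with a one-pixel box
  path <- pmin(32, pmax(8, 18 + cumsum(sample(c(-4L, 4L), 60, TRUE))))
  # emitter drawn at (line + 3, pixel - 2) relative to the trajectory
  ph <- matrix(0L, 60, 40)
  for (i in 1:57) ph[i + 3, path[i] - 2] <- 100L
  kymo <- kymograph(ph, 0.1, 0.075, 0, 0)
  off <- refine_offsets(kymo, path_traj(path), box_width = 1)
  expect_equal(off$x_offset, 3L)
  expect_equal(off$y_offset, -2L)
})

test_that("refine_offsets errors on an all-zero kymograph", {
  kymo <- kymograph(matrix(0L, 10, 20), 0.1, 0.075)
  traj <- data.frame(time_s = (0:9) * 0.1, junction_um = rep(0.5, 10))
  expect_error(refine_offsets(kymo, traj), "no signal")
})

test_that("returned offsets maximise the box objective", {
  path <- 12 + round(4 * sin(seq(0, 3, length.out = 50)))
  kymo <- path_kymo(path, 30)
  traj <- path_traj(path)
  off <- refine_offsets(kymo, traj)
  best <- sum(extract_junction_intensity(kymo, traj, off)$intensity, na.rm = TRUE)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(3, 3))) {
    alt <- sum(extract_junction_intensity(
      kymo, traj, list(x_offset = d[1], y_offset = d[2]))$intensity, na.rm = TRUE)
    expect_lte(alt, best)
  }
})

test_that("junction intensity extraction sums the box", {
  # zero image -> all-zero series
  kymo <- kymograph(matrix(0L, 20, 30), 0.1, 0.075)
  traj <- data.frame(time_s = (0:19) * 0.1, junction_um = rep(1, 20))
  s <- extract_junction_intensity(kymo, traj)
  expect_true(all(s$intensity == 0))
  # single bright pixel on the junction line appears only at that line
  ph <- matrix(0L, 20, 30); ph[7, 14] <- 55L
  kymo <- kymograph(ph, 0.1, 0.075)
  traj <- data.frame(time_s = (0:19) * 0.1, junction_um = rep(13.5 * 0.075, 20))
  s <- extract_junction_intensity(kymo, traj)
  expect_equal(s$intensity[7], 55)
  expect_true(all(s$intensity[-7] == 0))
})

test_that("extraction is translation-equivariant", {
  set.seed(21)
  ph <- matrix(rpois(50 * 40, 3), 50, 40)
  kymo <- kymograph(ph, 0.1, 0.075)
  traj <- data.frame(time_s = (0:49) * 0.1,
                     junction_um = (14.5 + round(3 * sin(1:50 / 5))) * 0.075)
  base <- extract_junction_intensity(kymo, traj)
  shift <- 4L
  ph2 <- matrix(0L, 50, 40)
  ph2[, (1 + shift):40] <- ph[, 1:(40 - shift)]
  kymo2 <- kymograph(ph2, 0.1, 0.075)
  traj2 <- traj; traj2$junction_um <- traj$junction_um + shift * 0.075
  shifted <- extract_junction_intensity(kymo2, traj2)
  expect_equal(shifted$intensity, base$intensity)
})

test_that("truncated boxes are rescaled and flagged, outside boxes are NA", {
  ph <- matrix(2L, 10, 20)
  kymo <- kymograph(ph, 0.1, 0.075)
  # junction at the first pixel: box of 5 truncated to 3 pixels
  traj <- data.frame(time_s = (0:9) * 0.1, junction_um = rep(0.01, 10))
  s <- extract_junction_intensity(kymo, traj)
  expect_true(all(s$truncated))
  expect_equal(s$intensity[1], 2 * 3 * 5 / 3)  # rescaled to full-box scale
})

test_that("binding positions are classified by region", {
  jp <- data.frame(line = 1:20, time = (0:19) * 0.1, pixel = rep(30L, 20),
                   in_frame = TRUE)
  mk <- function(px) data.frame(line = 1:20, pixel = rep(px, 20))
  expect_equal(classify_binding_position(mk(30), jp), "junction")
  expect_equal(classify_binding_position(mk(32), jp), "junction")  # within tol 3
  expect_equal(classify_binding_position(mk(50), jp), "dsDNA")     # ss_top: high side
  expect_equal(classify_binding_position(mk(10), jp), "ssDNA")
  expect_equal(classify_binding_position(mk(50), jp, orientation = "ds_top"),
               "ssDNA")
})

test_that("simulated ssDNA binders are classified as ssDNA", {
  cfg <- simulation_config(seed = 12L, duration = 120, k_on = 1e-6,
                           init_ds_fraction = 0.5, p_ssdna_binder = 0.6,
                           p_dsdna_binder = 0, p_labeled = 1, tau_bleach = 1e6,
                           photons_per_line_bound = 120)
  sim <- simulate_experiment(cfg)
  traj <- reconstruct_junction(sim$trace)
  jp <- junction_to_pixels(traj, sim$kymo)
  tracks <- track_particles(sim$kymo, min_length = 5)
  expect_gt(length(tracks), 10)
  labs <- vapply(tracks, classify_binding_position, character(1),
                 junction_pixels = jp, kymo = sim$kymo)
  # score tracks clearly away from the junction line (>= 5 px)
  away <- vapply(tracks, function(tr) {
    d <- tr$pixel - jp$pixel[match(tr$line, jp$line)]
    mean(abs(d), na.rm = TRUE) >= 5
  }, logical(1))
  expect_gte(mean(labs[away] == "ssDNA"), 0.95)
})
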