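# DNA elasticity models and junction reconstruction

p <- elasticity_params()

test_that("FJC and WLC match the frozen arbitrary-precision oracle", {
  # values computed with a 40-digit evaluation of the closed forms
  expect_equal(fjc_extension(50, p), 4.7201728420000014, tolerance = 1e-12)
  expect_equal(wlc_extension(50, p), 2.8738836148696246, tolerance = 1e-12)
  expect_equal(fjc_extension(20, p), 4.1575776694582230, tolerance = 1e-12)
  expect_equal(wlc_extension(20, p), 2.7837247583132596, tolerance = 1e-12)
  expect_equal(fjc_extension(10, p), 3.4613499032434981, tolerance = 1e-12)
  expect_equal(wlc_extension(10, p), 2.7271465618925796, tolerance = 1e-12)
})

test_that("elasticity models obey their limiting behaviour", {
  # zero-force limit of the FJC
  expect_lt(fjc_extension(1e-6, p), 1e-6)
  # inextensible saturation: huge force, huge stretch modulus -> contour length
  stiff <- elasticity_params(ss_stretch_modulus = 1e15, ds_stretch_modulus = 1e15)
  expect_equal(fjc_extension(1e8, stiff), 0.56 * 8393 / 1000, tolerance = 1e-6)
  expect_equal(wlc_extension(1e8, stiff), 0.338 * 8393 / 1000, tolerance = 1e-4)
  # monotone increasing in force over the operating range
  fs <- seq(5, 100, by = 0.5)
  expect_true(all(diff(fjc_extension(fs, p)) > 0))
  expect_true(all(diff(wlc_extension(fs, p)) > 0))
  expect_lt(wlc_extension(20, p), wlc_extension(50, p))
})

test_that("domain errors are raised", {
  expect_error(fjc_extension(0, p))
  expect_error(fjc_extension(-1, p))
  expect_error(wlc_extension(2, p), "valid")
  expect_error(ds_fraction(-0.1))
  expect_error(ds_fraction(1.2))
  expect_error(elasticity_params(ss_kuhn_length = -1))
  expect_error(force_extension_trace(c(0, 0), c(10, 10), c(1, 1)))
  expect_error(force_extension_trace(c(0, 1), c(10, 10), c(1, -1)))
})

test_that("ssDNA fraction inverts the elasticity mixture", {
  F <- 30
  expect_equal(as.numeric(ss_fraction_from_eed(wlc_extension(F, p), F, p)), 0)
  expect_equal(as.numeric(ss_fraction_from_eed(fjc_extension(F, p), F, p)), 1)
  mid <- (fjc_extension(F, p) + wlc_extension(F, p)) / 2
  expect_equal(as.numeric(ss_fraction_from_eed(mid, F, p)), 0.5)
  # clamping is counted
  over <- fjc_extension(F, p) + 0.1
  fr <- ss_fraction_from_eed(c(over, mid), F, p)
  expect_equal(as.numeric(fr), c(1, 0.5))
  expect_equal(attr(fr, "n_clamped"), 1L)
  # degenerate force where the two models cross
  f_star <- stats::uniroot(function(f) fjc_extension(f, p) - wlc_extension(f, p),
                           c(5, 7), tol = 1e-14)$root
  expect_error(ss_fraction_from_eed(2.5, f_star, p), "degenerate")
})

test_that("ds_fraction is the complement", {
  expect_equal(ds_fraction(0), 1)
  expect_equal(ds_fraction(1), 0)
  expect_equal(ds_fraction(0.25), 0.75)
})

test_that("junction positions for the two orientations sum to the EED", {
  set.seed(11)
  ssf <- runif(200)
  F <- runif(200, 10, 60)
  eed <- runif(200, 1, 3)
  top <- junction_position(ssf, F, eed, "ss_top", p)
  bot <- junction_position(ssf, F, eed, "ds_top", p)
  expect_equal(top + bot, eed, tolerance = 1e-14)
  expect_true(all(top >= 0 & top <= eed))
  expect_equal(junction_position(0, 30, 2.5, "ss_top", p), 0)
  expect_equal(junction_position(1, 30, 2.5, "ss_top", p), 2.5)
})

test_that("base-pair conversion rounds half-up", {
  expect_equal(basepairs_from_fraction(0, p), 8393)
  expect_equal(basepairs_from_fraction(1, p), 0)
  expect_equal(basepairs_from_fraction(0.5, p), 4197)  # round(4196.5) half-up
})

test_that("ss_fraction is monotone in EED at fixed force", {
  F <- 25
  eeds <- seq(wlc_extension(F, p), fjc_extension(F, p), length.out = 50)
  fr <- as.numeric(ss_fraction_from_eed(eeds, F, p))
  expect_true(all(diff(fr) > 0))
})

test_that("reconstruct_junction round-trips noiseless forward synthesis", {
  set.seed(3)
  n <- 500
  ssf <- pmin(1, pmax(0, cumsum(rnorm(n, 0, 0.01)) + 0.4))
  F <- rep(c(50, 20), each = n / 2)
  eed <- ssf * fjc_extension(F, p) + (1 - ssf) * wlc_extension(F, p)
  trace <- force_extension_trace(seq_len(n) * 0.05, F, eed)
  traj <- reconstruct_junction(trace, p, "ss_top")
  expect_lt(max(abs(traj$ss_fraction - ssf)), 1e-9)
  expect_equal(traj$basepairs_ds, floor((1 - ssf) * 8393 + 0.5))
  expect_true(all(traj$junction_um >= 0 & traj$junction_um <= eed + 1e-12))
})

test_that("reconstruct_junction flags invalid samples instead of aborting", {
  trace <- force_extension_trace(c(0.05, 0.10, 0.15), c(50, 3, 50),
                                 c(2.9, 2.9, 2.9))
  traj <- reconstruct_junction(trace, p)
  expect_equal(traj$ok, c(TRUE, FALSE, TRUE))
  expect_true(is.na(traj$ss_fraction[2]))
  expect_equal(attr(traj, "n_flagged"), 1L)
})

test_that("constant input gives a constant trajectory", {
  trace <- force_extension_trace(seq(0.05, 5, by = 0.05), rep(50, 100),
                                 rep(3.2, 100))
  traj <- reconstruct_junction(trace, p)
  expect_equal(length(unique(traj$ss_fraction)), 1L)
  expect_equal(length(unique(traj$junction_um)), 1L)
})
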