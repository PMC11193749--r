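#' Simulation configuration for the polymerase-exchange generator
#'
#' Stated-world defaults follow the experimental system the pipeline targets:
#' an 8393 bp template held at 40-50 pN for exonucleolysis (~ -100 bp/s) and
#' 10-20 pN for polymerisation (~ +200 bp/s), ~1 s bound dwells, ~60%
#' fluorescent labeling, ~13 s photobleaching, 75 nm confocal pixels and
#' 0.1-0.3 s line times. Unbound gaps are only bounded above by the scan time
#' in the source experiments; the 0.2 s mean (k_on = 5/s) is a documented
#' assumption.
#'
#' @param seed master seed; each rendered artifact (kinetics, force trace,
#'   kymograph) uses its own stream derived from it.
#' @param duration total simulated time (s).
#' @param force_schedule data frame with columns `start_s`, `force_pN`;
#'   force is piecewise constant.
#' @param k_on junction binding rate (1/s); mean unbound gap = 1/k_on.
#' @param tau_off mean bound dwell at the junction (s).
#' @param p_labeled fraction of fluorescently labeled polymerase.
#' @param tau_bleach mean single-step photobleaching time (s).
#' @param rate_exo exonucleolysis rate (bp/s, negative).
#' @param rate_pol polymerisation rate (bp/s, positive).
#' @param p_pause_given_bind probability a fresh binder is in the paused
#'   state (when not copying the previous binder).
#' @param p_transition probability a binding event switches activity class
#'   once mid-dwell (transitional-type event).
#' @param memory_strength probability the next binder adopts the previous
#'   binder's activity class (0 = independent draws).
#' @param rate_jitter_sd per-event Gaussian jitter on the catalytic rate (bp/s).
#' @param line_time confocal line-scan interval (s).
#' @param pixel_size confocal pixel size (um).
#' @param psf_sigma Gaussian point-spread-function sigma (um).
#' @param photons_per_line_bound expected photons per line from one bound,
#'   labeled, unbleached emitter.
#' @param background_rate expected background photons per pixel per line.
#' @param bead_band_pixels width of the saturating bead bands at each
#'   kymograph edge (pixels).
#' @param bead_band_intensity mean photons per pixel inside the bead bands.
#' @param init_ds_fraction initial dsDNA fraction of the template; traces
#'   start after brief digestion of the primer-overhang end, so the junction
#'   begins clear of the bead.
#' @param eed_noise_sd Gaussian measurement noise on the end-to-end
#'   distance (um).
#' @param force_sample_rate trap data rate (Hz).
#' @param p_ssdna_binder arrival rate of extra (near-static) ssDNA binders (1/s).
#' @param p_dsdna_binder arrival rate of extra diffusing dsDNA binders (1/s).
#' @param tau_ss mean dwell of ssDNA binders (s).
#' @param D_dsdna diffusion constant of dsDNA binders (um^2/s).
#' @param D_ssdna diffusion constant of ssDNA binders (um^2/s).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              duration = 120,
                              force_schedule = data.frame(
                                start_s = c(0, 60, 100),
                                force_pN = c(50, 20, 50)),
                              k_on = 5,
                              tau_off = 1.2,
                              p_labeled = 0.6,
                              tau_bleach = 13,
                              rate_exo = -100,
                              rate_pol = 200,
                              p_pause_given_bind = 0.3,
                              p_transition = 0.08,
                              memory_strength = 0.4,
                              rate_jitter_sd = 10,
                              line_time = 0.1,
                              pixel_size = 0.075,
                              psf_sigma = 0.15,
                              photons_per_line_bound = 50,
                              background_rate = 2,
                              bead_band_pixels = 3,
                              bead_band_intensity = 500,
                              init_ds_fraction = 0.93,
                              eed_noise_sd = 0.002,
                              force_sample_rate = 20,
                              p_ssdna_binder = 0.02,
                              p_dsdna_binder = 0.02,
                              tau_ss = 6.5,
                              D_dsdna = 0.02,
                              D_ssdna = 0.003) {
  cfg <- as.list(environment())
  probs <- c("p_labeled", "p_pause_given_bind", "p_transition", "memory_strength")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must lie in [0, 1]", p))
  pos <- c("duration", "k_on", "tau_off", "tau_bleach", "line_time",
           "pixel_size", "psf_sigma", "force_sample_rate", "tau_ss")
  for (p in pos)
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0) stop(sprintf("%s must be positive", p))
  if (init_ds_fraction <= 0 || init_ds_fraction > 1)
    stop("init_ds_fraction must lie in (0, 1]")
  nonneg <- c("rate_jitter_sd", "photons_per_line_bound", "background_rate",
              "eed_noise_sd", "p_ssdna_binder", "p_dsdna_binder",
              "D_dsdna", "D_ssdna")
  for (p in nonneg)
    if (cfg[[p]] < 0) stop(sprintf("%s must be >= 0", p))
  if (rate_exo >= 0) stop("rate_exo must be negative (bp removal)")
  if (rate_pol <= 0) stop("rate_pol must be positive (bp incorporation)")
  if (!all(c("start_s", "force_pN") %in% names(force_schedule)) ||
      nrow(force_schedule) < 1 || force_schedule$start_s[1] != 0 ||
      any(diff(force_schedule$start_s) <= 0))
    stop("force_schedule needs columns start_s (0, increasing) and force_pN")
  structure(cfg, class = "simulation_config")
}

# independent substreams per rendered artifact, all < 2^31
.substream <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * k) %% 2147483629)
}

# nearest-sample lookup on a regular time grid starting at grid_t[1]
.grid_nearest <- function(grid_t, v, times) {
  dt <- grid_t[2] - grid_t[1]
  v[pmin(length(v), pmax(1L, round((times - grid_t[1]) / dt) + 1L))]
}

.force_at <- function(t, schedule) {
  idx <- findInterval(t, schedule$start_s)
  idx[idx < 1L] <- 1L
  schedule$force_pN[idx]
}

#' Simulate polymerase-exchange kinetics with full latent truth
#'
#' Alternating exponential unbound (mean `1/k_on`) and bound (mean `tau_off`)
#' intervals at the ssDNA/dsDNA junction. At each binding the activity class
#' is drawn force-dependently (>= 40 pN favours exonucleolysis, <= 20 pN
#' polymerisation, paused with probability `p_pause_given_bind`), except with
#' probability `memory_strength` the binder copies the previous binder's
#' class (the memory effect). Labels are Bernoulli(`p_labeled`); bleach times
#' exponential(`tau_bleach`). The base-pair count integrates the active rate
#' on a fine grid, clipped to `[0, total_bp]`, and the junction position
#' follows from the elasticity mixture.
#'
#' @param config a [simulation_config()].
#' @param params an [elasticity_params()] object.
#' @return an object of class `sim_truth`: `events` and `sub_intervals` data
#'   frames, the latent grid (`time`, `bp`, `ss_fraction`, `junction_um`,
#'   `eed_um` noiseless, `force_pN`, `rate_bps`, `occupied`, `visible`),
#'   truth pause intervals, and extra-binder records with trajectories.
#' @export
simulate_kinetics <- function(config, params = elasticity_params()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream(config$seed, 1L))
  dur <- config$duration

  ## --- junction binding events -------------------------------------------
  # accumulate plain vectors; data frames are assembled once at the end
  ev_t_bind <- ev_t_unbind <- ev_t_bleach <- numeric(0)
  ev_labeled <- ev_transitional <- logical(0)
  sub_event <- integer(0); sub_t0 <- sub_t1 <- sub_rate <- numeric(0)
  sub_class <- character(0)
  t <- 0; prev_class <- NULL; id <- 0L
  draw_class <- function(force) {
    if (force >= 40) {
      if (stats::runif(1) < config$p_pause_given_bind) "pause" else "exo"
    } else if (force <= 20) {
      if (stats::runif(1) < config$p_pause_given_bind) "pause" else "pol"
    } else "pause"   # undeclared middle band: no catalysis modeled
  }
  class_rate <- function(cl) {
    base <- switch(cl, exo = config$rate_exo, pol = config$rate_pol, pause = 0)
    if (cl == "pause") 0 else base + stats::rnorm(1, 0, config$rate_jitter_sd)
  }
  repeat {
    t_bind <- t + stats::rexp(1, rate = config$k_on)
    if (t_bind >= dur) break
    dwell <- stats::rexp(1, rate = 1 / config$tau_off)
    t_unbind <- min(t_bind + dwell, dur)
    force <- .force_at(t_bind, config$force_schedule)
    cl1 <- if (!is.null(prev_class) && stats::runif(1) < config$memory_strength)
      prev_class else draw_class(force)
    id <- id + 1L
    labeled <- stats::runif(1) < config$p_labeled
    t_bleach <- t_bind + stats::rexp(1, rate = 1 / config$tau_bleach)
    transitional <- stats::runif(1) < config$p_transition
    if (transitional && (t_unbind - t_bind) > 0.2) {
      t_mid <- t_bind + stats::runif(1, 0.25, 0.75) * (t_unbind - t_bind)
      cl2 <- cl1
      while (cl2 == cl1) cl2 <- draw_class(force)
      sub_event <- c(sub_event, id, id)
      sub_t0 <- c(sub_t0, t_bind, t_mid); sub_t1 <- c(sub_t1, t_mid, t_unbind)
      sub_class <- c(sub_class, cl1, cl2)
      sub_rate <- c(sub_rate, class_rate(cl1), class_rate(cl2))
      prev_class <- cl2
    } else {
      transitional <- FALSE
      sub_event <- c(sub_event, id)
      sub_t0 <- c(sub_t0, t_bind); sub_t1 <- c(sub_t1, t_unbind)
      sub_class <- c(sub_class, cl1)
      sub_rate <- c(sub_rate, class_rate(cl1))
      prev_class <- cl1
    }
    ev_t_bind <- c(ev_t_bind, t_bind); ev_t_unbind <- c(ev_t_unbind, t_unbind)
    ev_labeled <- c(ev_labeled, labeled); ev_t_bleach <- c(ev_t_bleach, t_bleach)
    ev_transitional <- c(ev_transitional, transitional)
    t <- t_unbind
  }
  events <- data.frame(event = seq_along(ev_t_bind), t_bind = ev_t_bind,
                       t_unbind = ev_t_unbind, labeled = ev_labeled,
                       t_bleach = ev_t_bleach, transitional = ev_transitional)
  subints <- data.frame(event = sub_event, t0 = sub_t0, t1 = sub_t1,
                        class = sub_class, rate_bps = sub_rate)

  ## --- integrate base pairs on a fine grid -------------------------------
  dt <- 0.005
  tg <- seq(0, dur, by = dt)
  ng <- length(tg)
  # first grid index with tg >= t0 / last with tg < t1 (grid is (i-1)*dt)
  gi0 <- function(t0) pmin(ng, pmax(1L, floor(t0 / dt + 1 - 1e-9) + 1L))
  gi1 <- function(t1) pmin(ng, pmax(0L, ceiling(t1 / dt + 1 - 1e-9) - 1L))
  rate <- numeric(ng)
  occupied <- logical(ng)
  visible <- logical(ng)
  for (i in seq_len(nrow(subints))) {
    i0 <- gi0(subints$t0[i]); i1 <- gi1(subints$t1[i])
    if (i1 >= i0) {
      rate[i0:i1] <- subints$rate_bps[i]
      occupied[i0:i1] <- TRUE
    }
  }
  for (i in seq_len(nrow(events))) {
    if (!events$labeled[i]) next
    t_vis <- min(events$t_unbind[i], events$t_bleach[i])
    i0 <- gi0(events$t_bind[i]); i1 <- gi1(t_vis)
    if (i1 >= i0) visible[i0:i1] <- TRUE
  }
  bp <- numeric(length(tg))
  bp[1] <- config$init_ds_fraction * params$total_bp
  for (i in seq_along(tg)[-1])
    bp[i] <- min(params$total_bp, max(0, bp[i - 1] + rate[i - 1] * dt))
  # effective rate: what the observable bp trace actually does (assigned
  # rates are nulled where bp saturates at the template boundaries)
  rate <- c(diff(bp) / dt, 0)
  rate[abs(rate) < 1e-9] <- 0
  ssf <- 1 - bp / params$total_bp
  force_g <- .force_at(tg, config$force_schedule)
  fjc <- fjc_extension(force_g, params)
  wlc <- wlc_extension(force_g, params)
  eed <- ssf * fjc + (1 - ssf) * wlc
  junc <- ifelse(eed > 0, ssf * fjc / (ssf * fjc + (1 - ssf) * wlc) * eed, 0)

  ## truth pauses: maximal zero-rate stretches (bound-paused or unbound)
  zero <- rate == 0
  r <- rle(zero)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  truth_pauses <- data.frame(t_start = tg[starts[keep]],
                             t_end = tg[pmin(ends[keep] + 1L, length(tg))])
  truth_pauses$duration <- truth_pauses$t_end - truth_pauses$t_start

  ## --- extra binders ------------------------------------------------------
  tl <- seq(0, dur - config$line_time, by = config$line_time)
  # nearest-sample lookup on the regular grid (approx() is too slow here)
  grid_at <- function(v, times) v[pmin(ng, pmax(1L, round(times / dt) + 1L))]
  make_binder <- function(kind, t_on, t_off, D) {
    lines_idx <- which(tl >= t_on & tl < t_off)
    if (!length(lines_idx)) return(NULL)
    jl <- grid_at(junc, tl[lines_idx]); el <- grid_at(eed, tl[lines_idx])
    lo <- if (kind == "ssDNA") rep(0, length(jl)) else jl
    hi <- if (kind == "ssDNA") jl else el
    hi <- pmax(hi, lo + 0.05)
    x <- numeric(length(lines_idx))
    x[1] <- stats::runif(1, lo[1], hi[1])
    if (length(x) > 1) {
      step_sd <- sqrt(2 * D * config$line_time)
      for (k in 2:length(x)) {
        xx <- x[k - 1] + stats::rnorm(1, 0, step_sd)
        # reflect into the current segment
        span <- hi[k] - lo[k]
        xx <- abs(xx - lo[k]) %% (2 * span)
        x[k] <- lo[k] + ifelse(xx > span, 2 * span - xx, xx)
      }
    }
    data.frame(line = lines_idx, time = tl[lines_idx], position_um = x)
  }
  binders <- list()
  for (kind in c("ssDNA", "dsDNA")) {
    lam <- if (kind == "ssDNA") config$p_ssdna_binder else config$p_dsdna_binder
    n_b <- stats::rpois(1, lam * dur)
    if (n_b == 0) next
    t_on <- sort(stats::runif(n_b, 0, dur))
    for (b in seq_len(n_b)) {
      dwell <- stats::rexp(1, rate = 1 / (if (kind == "ssDNA") config$tau_ss
                                          else config$tau_off * 3))
      t_off <- min(t_on[b] + dwell, dur)
      labeled <- stats::runif(1) < config$p_labeled
      t_bleach <- t_on[b] + stats::rexp(1, rate = 1 / config$tau_bleach)
      D <- if (kind == "ssDNA") config$D_ssdna else config$D_dsdna
      traj <- make_binder(kind, t_on[b], t_off, D)
      if (is.null(traj)) next
      binders[[length(binders) + 1L]] <-
        list(kind = kind, t_on = t_on[b], t_off = t_off, labeled = labeled,
             t_bleach = t_bleach, D = D, trajectory = traj)
    }
  }

  structure(list(events = events, sub_intervals = subints,
                 grid = data.frame(time = tg, bp = bp, ss_fraction = ssf,
                                   junction_um = junc, eed_um = eed,
                                   force_pN = force_g, rate_bps = rate,
                                   occupied = occupied, visible = visible),
                 truth_pauses = truth_pauses,
                 binders = binders,
                 line_times = tl,
                 config = config, params = params),
            class = "sim_truth")
}

#' Render a noisy force-extension trace from simulation truth
#'
#' Samples the latent ssDNA fraction at the trap data rate and forms
#' `EED = ss * FJC(F) + (1 - ss) * WLC(F) + N(0, eed_noise_sd)`.
#'
#' @param truth a [simulate_kinetics()] result.
#' @param config a [simulation_config()] (defaults to the one in `truth`).
#' @param params elasticity parameters (defaults to the ones in `truth`).
#' @return a [force_extension_trace()].
#' @export
render_force_trace <- function(truth, config = truth$config, params = truth$params) {
  set.seed(.substream(config$seed, 2L))
  ts <- seq(0, config$duration - 1 / config$force_sample_rate,
            by = 1 / config$force_sample_rate)
  ssf <- .grid_nearest(truth$grid$time, truth$grid$ss_fraction, ts)
  force <- .force_at(ts, config$force_schedule)
  eed <- ssf * fjc_extension(force, params) +
    (1 - ssf) * wlc_extension(force, params)
  if (config$eed_noise_sd > 0)
    eed <- eed + stats::rnorm(length(eed), 0, config$eed_noise_sd)
  eed <- pmax(eed, 1e-6)
  force_extension_trace(ts, force, eed)
}

#' Kymograph container
#'
#' @param photons integer matrix, lines x pixels.
#' @param line_time line-scan interval (s).
#' @param pixel_size pixel size (um).
#' @param origin_position physical position of the *lower edge* of pixel 1 (um).
#' @param bead_band_pixels width of the bead bands at each edge (pixels).
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(photons, line_time, pixel_size, origin_position = 0,
                      bead_band_pixels = 0) {
  stopifnot(is.matrix(photons), all(photons >= 0),
            line_time > 0, pixel_size > 0)
  structure(list(photons = photons, line_time = line_time,
                 pixel_size = pixel_size, origin_position = origin_position,
                 bead_band_pixels = as.integer(bead_band_pixels)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d lines x %d pixels, %.3g s/line, %g nm/pixel\n",
              nrow(x$photons), ncol(x$photons), x$line_time,
              1000 * x$pixel_size))
  invisible(x)
}

# line start times of a kymograph
kymo_times <- function(kymo) (seq_len(nrow(kymo$photons)) - 1L) * kymo$line_time

#' Render a photon-count kymograph from simulation truth
#'
#' Per line: Poisson background everywhere; each labeled, unbleached bound
#' emitter adds Poisson photons with a Gaussian spatial profile
#' (`psf_sigma`) integrated over pixels; saturating bright bands of
#' `bead_band_pixels` at both edges emulate the trapped-bead signal.
#' Deterministic for a fixed seed.
#'
#' @inheritParams render_force_trace
#' @return a [kymograph()].
#' @export
render_kymograph <- function(truth, config = truth$config, params = truth$params) {
  set.seed(.substream(config$seed, 3L))
  tl <- truth$line_times
  n_lines <- length(tl)
  bb <- config$bead_band_pixels
  max_pos <- max(truth$grid$eed_um) + 0.2
  n_interior <- ceiling(max_pos / config$pixel_size)
  n_pix <- n_interior + 2L * bb
  origin <- -bb * config$pixel_size
  edges <- origin + (0:n_pix) * config$pixel_size   # pixel i spans edges[i]..edges[i+1]

  M <- matrix(config$background_rate, nrow = n_lines, ncol = n_pix)
  add_emitter <- function(line_idx, pos, amp) {
    win <- ceiling(4 * config$psf_sigma / config$pixel_size)
    for (k in seq_along(line_idx)) {
      cpix <- floor((pos[k] - origin) / config$pixel_size) + 1L
      px <- max(1L, cpix - win):min(n_pix, cpix + win)
      frac <- stats::pnorm(edges[px + 1L], pos[k], config$psf_sigma) -
        stats::pnorm(edges[px], pos[k], config$psf_sigma)
      M[line_idx[k], px] <<- M[line_idx[k], px] + amp[k] * frac
    }
  }
  # junction binders; a line integrates over its scan interval, so the
  # brightness scales with the fraction of the line the emitter is visible
  jl <- .grid_nearest(truth$grid$time, truth$grid$junction_um, tl)
  lt <- config$line_time
  for (i in seq_len(nrow(truth$events))) {
    e <- truth$events[i, ]
    if (!e$labeled) next
    t_vis <- min(e$t_unbind, e$t_bleach)
    vis_frac <- pmax(0, pmin(tl + lt, t_vis) - pmax(tl, e$t_bind)) / lt
    li <- which(vis_frac > 0)
    if (length(li))
      add_emitter(li, jl[li], config$photons_per_line_bound * vis_frac[li])
  }
  # extra binders
  for (b in truth$binders) {
    if (!b$labeled) next
    tr <- b$trajectory
    vf <- pmax(0, pmin(tr$time + lt, min(b$t_off, b$t_bleach)) -
                 pmax(tr$time, b$t_on)) / lt
    vis <- vf > 0
    if (any(vis))
      add_emitter(tr$line[vis], tr$position_um[vis],
                  config$photons_per_line_bound * vf[vis])
  }
  if (bb > 0) {
    M[, c(seq_len(bb), n_pix - bb + seq_len(bb))] <- config$bead_band_intensity
  }
  photons <- matrix(stats::rpois(length(M), as.vector(M)),
                    nrow = n_lines, ncol = n_pix)
  kymograph(photons, config$line_time, config$pixel_size, origin, bb)
}

#' Per-line ground-truth states of a simulation
#'
#' Collapses the fine latent grid onto kymograph lines: a line is `visible`
#' (fluorescent emitter at the junction) or `active` (|effective rate| at or
#' above the regime pause cutoff) if the state holds for the majority of the
#' line's scan interval. This is the reference the per-line detector-quality
#' checks score against.
#'
#' @param truth a [simulate_kinetics()] result.
#' @param thresholds a [pause_thresholds()] object.
#' @return data frame `line`, `time`, `visible`, `visible_frac`, `active`,
#'   `occupied`.
#' @export
truth_line_states <- function(truth, thresholds = pause_thresholds()) {
  g <- truth$grid
  lt <- truth$config$line_time
  tl <- truth$line_times
  li <- floor(g$time / lt) + 1L
  ok <- li >= 1L & li <= length(tl)
  cutoff <- .regime_cutoff(g$force_pN, thresholds)
  act <- as.numeric(!is.na(cutoff) & abs(g$rate_bps) >= cutoff)
  agg <- function(v) as.numeric(rowsum(v[ok], li[ok]) /
                                  as.vector(table(li[ok])))
  vis_frac <- agg(as.numeric(g$visible))
  data.frame(line = seq_along(tl), time = tl,
             visible = as.integer(vis_frac >= 0.5),
             visible_frac = vis_frac,
             active = as.integer(agg(act) >= 0.5),
             occupied = as.integer(agg(as.numeric(g$occupied)) >= 0.5))
}

#' Run the full simulator: kinetics, force trace and kymograph
#'
#' @param config a [simulation_config()].
#' @param params an [elasticity_params()] object.
#' @return list with `truth`, `trace`, `kymo`.
#' @export
simulate_experiment <- function(config = simulation_config(),
                                params = elasticity_params()) {
  truth <- simulate_kinetics(config, params)
  list(truth = truth,
       trace = render_force_trace(truth, config, params),
       kymo = render_kymograph(truth, config, params))
}
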