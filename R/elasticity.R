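#' DNA elasticity parameters
#'
#' Container for the freely-jointed-chain (ssDNA) and extensible worm-like-
#' chain (dsDNA) model parameters used to convert force and end-to-end
#' distance into ssDNA fraction and junction position. The defaults are
#' standard literature values for the 10-50 pN operating regime of a
#' dual-trap assay; none of them is fitted here and all can be overridden.
#'
#' @param ss_contour_per_nt ssDNA contour length per nucleotide (nm/nt).
#' @param ss_kuhn_length ssDNA Kuhn (segment) length (nm).
#' @param ss_stretch_modulus ssDNA stretch modulus (pN).
#' @param ds_contour_per_bp dsDNA contour length per base pair (nm/bp).
#' @param ds_persistence_length dsDNA persistence length (nm).
#' @param ds_stretch_modulus dsDNA stretch modulus (pN).
#' @param kBT thermal energy (pN nm).
#' @param total_bp template length in base pairs.
#'
#' @return An object of class `elasticity_params`.
#' @export
elasticity_params <- function(ss_contour_per_nt = 0.56,
                              ss_kuhn_length = 1.5,
                              ss_stretch_modulus = 800,
                              ds_contour_per_bp = 0.338,
                              ds_persistence_length = 50,
                              ds_stretch_modulus = 1500,
                              kBT = 4.11,
                              total_bp = 8393) {
  p <- list(ss_contour_per_nt = ss_contour_per_nt,
            ss_kuhn_length = ss_kuhn_length,
            ss_stretch_modulus = ss_stretch_modulus,
            ds_contour_per_bp = ds_contour_per_bp,
            ds_persistence_length = ds_persistence_length,
            ds_stretch_modulus = ds_stretch_modulus,
            kBT = kBT,
            total_bp = total_bp)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) stop("all elasticity parameters must be finite scalars")
  if (any(unlist(p[setdiff(names(p), "total_bp")]) <= 0))
    stop("all lengths and moduli must be strictly positive")
  if (total_bp < 1) stop("total_bp must be >= 1")
  structure(p, class = "elasticity_params")
}

# full-template contour lengths in micrometres
.lc_ss_um <- function(params) params$ss_contour_per_nt * params$total_bp / 1000
.lc_ds_um <- function(params) params$ds_contour_per_bp * params$total_bp / 1000

#' Extensible freely-jointed-chain extension of the full ssDNA template
#'
#' Langevin-function FJC with a linear stretch correction:
#' `Lc_ss * (coth(F b / kBT) - kBT / (F b)) * (1 + F / S_ss)`.
#' Monotone increasing in force; used for the single-stranded portion of the
#' template.
#'
#' @param force tension (pN), strictly positive; vectorised.
#' @param params an [elasticity_params()] object.
#' @return extension of the full-length ssDNA template (um).
#' @export
fjc_extension <- function(force, params = elasticity_params()) {
  if (any(!is.finite(force)) || any(force <= 0))
    stop("fjc_extension: force must be strictly positive")
  x <- force * params$ss_kuhn_length / params$kBT
  .lc_ss_um(params) * (1 / tanh(x) - 1 / x) * (1 + force / params$ss_stretch_modulus)
}

#' Extensible worm-like-chain extension of the full dsDNA template
#'
#' Odijk high-force form `Lc_ds * (1 - sqrt(kBT/(F Lp))/2 + F/S_ds)`,
#' valid above ~5 pN (the assay operates at 10-50 pN).
#'
#' @param force tension (pN); vectorised.
#' @param params an [elasticity_params()] object.
#' @param force_min validity limit (pN) below which the high-force form is
#'   rejected.
#' @return extension of the full-length dsDNA template (um).
#' @export
wlc_extension <- function(force, params = elasticity_params(), force_min = 5) {
  if (any(!is.finite(force)) || any(force < force_min))
    stop(sprintf("wlc_extension: Odijk high-force form is only valid for force >= %g pN", force_min))
  .lc_ds_um(params) *
    (1 - sqrt(params$kBT / (force * params$ds_persistence_length)) / 2 +
       force / params$ds_stretch_modulus)
}

#' ssDNA fraction from end-to-end distance
#'
#' Inverts the two-component elasticity mixture: at tension F a template that
#' is a fraction `ss` single-stranded has end-to-end distance
#' `ss * FJC(F) + (1 - ss) * WLC(F)`, so
#' `ss = (EED - WLC(F)) / (FJC(F) - WLC(F))`. Values outside [0, 1]
#' (measurement noise at the boundaries) are clamped and the number of
#' clamped samples is reported in the `"n_clamped"` attribute.
#'
#' @param eed end-to-end distance (um); vectorised.
#' @param force tension (pN), same length as `eed` or scalar.
#' @param params an [elasticity_params()] object.
#' @return numeric vector of ssDNA fractions in [0, 1], with attribute
#'   `n_clamped`.
#' @export
ss_fraction_from_eed <- function(eed, force, params = elasticity_params()) {
  fjc <- fjc_extension(force, params)
  wlc <- wlc_extension(force, params)
  den <- fjc - wlc
  if (any(abs(den) < 1e-12))
    stop("ss_fraction_from_eed: degenerate force where FJC(F) = WLC(F)")
  raw <- (eed - wlc) / den
  clamped <- pmin(1, pmax(0, raw))
  structure(clamped, n_clamped = sum(raw < 0 | raw > 1))
}

#' dsDNA fraction as the complement of the ssDNA fraction
#' @param ss_fraction ssDNA fraction in [0, 1].
#' @return `1 - ss_fraction`.
#' @export
ds_fraction <- function(ss_fraction) {
  if (any(!is.finite(ss_fraction)) || any(ss_fraction < 0 | ss_fraction > 1))
    stop("ds_fraction: ss_fraction must lie in [0, 1]")
  1 - ss_fraction
}

#' Position of the ssDNA/dsDNA junction along the bead-to-bead axis
#'
#' With `orientation = "ss_top"` the origin (0 um) is the bead on the ssDNA
#' side and the junction sits at
#' `ss * FJC(F) / (ss * FJC(F) + (1 - ss) * WLC(F)) * EED`;
#' with `"ds_top"` it is the complement `EED - (that quantity)`. The two
#' orientations always sum to the end-to-end distance.
#'
#' @param ss_fraction ssDNA fraction in [0, 1]; vectorised.
#' @param force tension (pN).
#' @param eed end-to-end distance (um).
#' @param orientation which template end is at the origin of the position
#'   axis: `"ss_top"` (ssDNA side) or `"ds_top"`.
#' @param params an [elasticity_params()] object.
#' @return junction position (um), in [0, eed].
#' @export
junction_position <- function(ss_fraction, force, eed,
                              orientation = c("ss_top", "ds_top"),
                              params = elasticity_params()) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(ss_fraction)) || any(ss_fraction < 0 | ss_fraction > 1))
    stop("junction_position: ss_fraction must lie in [0, 1]")
  num <- ss_fraction * fjc_extension(force, params)
  den <- num + (1 - ss_fraction) * wlc_extension(force, params)
  if (any(den <= 0)) stop("junction_position: zero mixture denominator")
  pos <- num / den * eed
  if (orientation == "ds_top") pos <- eed - pos
  pos
}

#' Base pairs of remaining dsDNA from the ssDNA fraction
#'
#' `(1 - ss_fraction) * total_bp`, rounded half-up to the nearest integer so
#' that e.g. 4196.5 reports as 4197.
#'
#' @param ss_fraction ssDNA fraction in [0, 1]; vectorised.
#' @param params an [elasticity_params()] object.
#' @return integer base-pair counts.
#' @export
basepairs_from_fraction <- function(ss_fraction, params = elasticity_params()) {
  if (any(!is.finite(ss_fraction)) || any(ss_fraction < 0 | ss_fraction > 1))
    stop("basepairs_from_fraction: ss_fraction must lie in [0, 1]")
  floor((1 - ss_fraction) * params$total_bp + 0.5)
}

#' Force-extension trace constructor
#'
#' Synchronised trap observables: time (strictly increasing, s), force (pN)
#' and bead-to-bead end-to-end distance (um). EED is assumed pre-corrected
#' for bead radii.
#'
#' @param time,force,eed equal-length numeric vectors.
#' @return a `force_extension_trace` data frame with columns
#'   `time_s`, `force_pN`, `eed_um`.
#' @export
force_extension_trace <- function(time, force, eed) {
  n <- length(time)
  if (length(force) != n || length(eed) != n || n == 0)
    stop("force_extension_trace: time, force, eed must be equal-length, nonempty")
  if (any(diff(time) <= 0)) stop("force_extension_trace: time must be strictly increasing")
  if (any(force < 0)) stop("force_extension_trace: force must be >= 0")
  if (any(eed <= 0)) stop("force_extension_trace: eed must be > 0")
  structure(data.frame(time_s = time, force_pN = force, eed_um = eed),
            class = c("force_extension_trace", "data.frame"))
}

#' Reconstruct the ssDNA/dsDNA junction trajectory from a force trace
#'
#' Applies [ss_fraction_from_eed()], [junction_position()] and
#' [basepairs_from_fraction()] per sample. Samples where the elasticity
#' models are invalid (e.g. force below the Odijk validity limit) are flagged
#' `ok = FALSE` with NA outputs rather than aborting the trace; the number of
#' fraction clamps is reported in the `n_clamped` attribute.
#'
#' @param trace a [force_extension_trace()].
#' @param params an [elasticity_params()] object.
#' @param orientation see [junction_position()].
#' @param force_min validity limit passed to [wlc_extension()].
#' @return a `junction_trajectory` data frame with columns `time_s`,
#'   `ss_fraction`, `junction_um`, `basepairs_ds`, `ok`; attributes
#'   `n_clamped`, `n_flagged`, `orientation`.
#' @export
reconstruct_junction <- function(trace, params = elasticity_params(),
                                 orientation = c("ss_top", "ds_top"),
                                 force_min = 5) {
  orientation <- match.arg(orientation)
  stopifnot(nrow(trace) > 0)
  ok <- is.finite(trace$force_pN) & trace$force_pN >= force_min & is.finite(trace$eed_um)
  n <- nrow(trace)
  ssf <- rep(NA_real_, n); jpos <- rep(NA_real_, n); bp <- rep(NA_real_, n)
  n_clamped <- 0L
  if (any(ok)) {
    fr <- ss_fraction_from_eed(trace$eed_um[ok], trace$force_pN[ok], params)
    n_clamped <- attr(fr, "n_clamped")
    ssf[ok] <- as.numeric(fr)
    jpos[ok] <- junction_position(ssf[ok], trace$force_pN[ok], trace$eed_um[ok],
                                  orientation, params)
    bp[ok] <- basepairs_from_fraction(ssf[ok], params)
  }
  structure(data.frame(time_s = trace$time_s, ss_fraction = ssf,
                       junction_um = jpos, basepairs_ds = bp, ok = ok),
            class = c("junction_trajectory", "data.frame"),
            n_clamped = n_clamped, n_flagged = sum(!ok),
            orientation = orientation)
}
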