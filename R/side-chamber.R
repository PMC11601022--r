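# Side-chamber correction: the flowmeter's semi-accessible side chambers lag
# the main measurement path, contaminating the normalized signal. During
# washout inspirations the main path is tracer-free, so the residual signal
# there is pure chamber carry-over; it is fitted per inspiration, interpolated
# across expirations, scaled using the known first washin / first washout
# breath states, and removed.

#' Fit the chamber carry-over to each washout inspiration
#'
#' During washout inspirations the main path carries tracer-free supply gas,
#' so the normalized signal equals the (decaying) side-chamber contribution.
#' For each washout inspiration the model `s(v) = a * exp(-v / lambda)` is
#' fitted by bounded least squares over the inspiration's samples, `v` being
#' inspired volume; `a >= 0` is the carry-over at inspiration start and
#' `lambda > 0` the chamber washout volume constant (mL). Non-convergence or a
#' volume constant at its bound triggers a monotone-decreasing isotonic
#' fallback fit and flags the breath.
#'
#' @param norm A `normalized_signal` from [apply_tcc()].
#' @param breaths A `breath_table`.
#' @param phases A `phase_annotation`.
#' @return A list of class `inspiration_fits` with one element per washout
#'   breath: `breath`, `a` (value at v = 0), `lambda` (NA for isotonic fits),
#'   `end_val` (value at end-inspiratory volume), `method`, and `fun`, a
#'   function of inspired volume.
#' @export
fit_inspiration_minimum <- function(norm, breaths, phases) {
  wb <- phases$washout[1]:phases$washout[2]
  fits <- vector("list", length(wb))
  for (k in seq_along(wb)) {
    b <- wb[k]
    sel <- norm$breath == b & norm$phase == "insp"
    v <- norm$v_ml[sel]
    x <- norm$x[sel]
    # the first ~1 mL around the flow reversal still carries the previous
    # phase's gas front and boundary-assignment jitter; exclude it from fits
    keep <- v >= .FIT_V_MIN_ML
    fits[[k]] <- c(fit_exp_decay(v[keep], x[keep]), list(breath = b))
  }
  structure(fits, class = "inspiration_fits")
}

.FIT_V_MIN_ML <- 1

# Decay significance gate: the a >= 0 bound would rectify pure noise into a
# positive carry-over, so a decay is only fitted when the head of the
# inspiration exceeds its tail by more than twice the standard error of the
# difference. Insignificant inspirations get the flat fit a = 0.
has_significant_decay <- function(v, x) {
  head <- x[v <= stats::quantile(v, 0.2)]
  tail <- x[v >= stats::quantile(v, 0.7)]
  if (length(head) < 3 || length(tail) < 3) return(TRUE)
  se <- sqrt(stats::var(head) / length(head) + stats::var(tail) / length(tail))
  mean(head) - mean(tail) > 2 * se + 1e-9
}

# Bounded exponential-decay fit with isotonic fallback.
fit_exp_decay <- function(v, x) {
  v_max <- max(v)
  if (!has_significant_decay(v, x)) {
    return(list(a = 0, lambda = NA_real_, end_val = 0, method = "flat",
                fun = function(vv) rep(0, length(vv))))
  }
  a0 <- max(stats::median(x[v <= stats::quantile(v, 0.1)]), 1e-3)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      x ~ a * exp(-v / lambda),
      start = list(a = a0, lambda = 15),
      lower = c(0, 1), upper = c(1.5, 500),
      control = minpack.lm::nls.lm.control(maxiter = 60))
    cf <- stats::coef(m)
    if (cf[["lambda"]] > 499 || !m$convInfo$isConv) NULL else cf
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    a <- fit[["a"]]; lam <- fit[["lambda"]]
    return(list(a = a, lambda = lam, end_val = a * exp(-v_max / lam),
                method = "exponential",
                fun = local({
                  a_ <- a; l_ <- lam
                  function(vv) a_ * exp(-vv / l_)
                })))
  }
  # isotonic (monotone non-increasing) fallback
  o <- order(v)
  iso <- stats::isoreg(v[o], -x[o])
  yf <- -iso$yf
  yf <- pmax(yf, 0)
  f <- stats::approxfun(v[o], yf, rule = 2)
  list(a = yf[1], lambda = NA_real_, end_val = yf[length(yf)],
       method = "isotonic", fun = f)
}

#' Interpolate the minimum curve over the whole washout
#'
#' Inspiration segments take their fitted decay curves; each expiration is
#' linearly interpolated in time between the end value of the preceding
#' inspiration's fit and the start value of the following inspiration's fit,
#' which makes the curve continuous at breath boundaries. The last expiration
#' (no following fit) is extended one-sidedly at the preceding end value.
#'
#' @param fits An `inspiration_fits` object.
#' @param norm A `normalized_signal`.
#' @param phases A `phase_annotation`.
#' @return Numeric vector of the minimum-curve value at every washout sample
#'   of `norm` (aligned with `norm` rows restricted to washout breaths).
#' @export
interpolate_minimum_curve <- function(fits, norm, phases) {
  if (length(fits) < 2)
    stop_mbw("need at least 2 washout inspirations", "mbw_no_breaths")
  wsel <- norm$breath >= phases$washout[1]
  w <- norm[wsel, ]
  m <- rep(NA_real_, nrow(w))
  wb <- vapply(fits, function(f) f$breath, integer(1))
  for (k in seq_along(fits)) {
    b <- wb[k]
    si <- w$breath == b & w$phase == "insp"
    m[si] <- fits[[k]]$fun(w$v_ml[si])
    se <- w$breath == b & w$phase == "exp"
    if (!any(se)) next
    t0 <- w$time[se][1]
    t1 <- w$time[se][sum(se)]
    start_val <- fits[[k]]$end_val
    end_val <- if (k < length(fits)) fits[[k + 1]]$a else fits[[k]]$end_val
    if (t1 > t0) {
      m[se] <- start_val + (end_val - start_val) * (w$time[se] - t0) / (t1 - t0)
    } else m[se] <- start_val
  }
  m
}

#' Scale the maximum curve from the known first washin / washout breaths
#'
#' The maximum curve (normalized signal corresponding to the full tracer
#' concentration in the main path, given the current chamber state) is an
#' affine transform `alpha + beta * m(t)` of the minimum curve. The first
#' breaths of washin and washout have known compartment states and pin the two
#' parameters: at the first washin inspiration the main path is at the full
#' concentration while the chambers are still empty, so the v->0 extrapolation
#' of that inspiration's normalized trace equals `alpha`; at the first washout
#' inspiration the chambers are still full while the main path is tracer-free,
#' so the maximum curve there equals 1, giving `beta = (1 - alpha) / m0` with
#' `m0` the first washout inspiration's carry-over. In the ideal lumped
#' chamber model this yields `alpha = 1 - w`, `beta = 1`, with `w` the chamber
#' fraction of the measurement path.
#'
#' @param norm A `normalized_signal` (must cover the washin breaths).
#' @param phases A `phase_annotation`.
#' @param fits An `inspiration_fits` object (washout inspirations).
#' @param cfg An [analysis_config()]; `scale_mode = "proportional"` selects a
#'   single-scale-factor variant (`alpha = 0`) for sensitivity analysis.
#' @return A list of class `side_chamber_scaling`: `alpha`, `beta`, `m0`
#'   (first washout carry-over) and `chamber_fraction_hat` (= `1 - alpha`).
#' @export
scale_maximum_curve <- function(norm, phases, fits, cfg = analysis_config()) {
  b1 <- phases$washin[1]
  sel <- norm$breath == b1 & norm$phase == "insp"
  v <- norm$v_ml[sel]
  x <- norm$x[sel]
  keep <- v >= .FIT_V_MIN_ML
  v <- v[keep]; x <- x[keep]
  # the anchor trace rises toward its plateau as the chamber fills; with no
  # significant rise there is no chamber effect and alpha is the plateau mean
  rising <- has_significant_decay(v, -x)
  alpha <- if (!rising) mean(x) else tryCatch({
    m <- minpack.lm::nlsLM(
      x ~ c0 - a1 * exp(-v / l1),
      start = list(c0 = stats::median(x[v > 0.6 * max(v)]),
                   a1 = max(1e-3, stats::median(x[v > 0.6 * max(v)]) - x[1]),
                   l1 = 15),
      lower = c(0.5, 0, 1), upper = c(1.5, 1, 500),
      control = minpack.lm::nls.lm.control(maxiter = 60))
    cf <- stats::coef(m)
    cf[["c0"]] - cf[["a1"]]
  }, error = function(e) {
    # fall back to the earliest-volume samples, which carry the least
    # chamber contamination
    stats::median(x[v <= stats::quantile(v, 0.1)])
  })
  m0 <- fits[[1]]$a
  if (cfg$scale_mode == "proportional") {
    alpha_out <- 0
    beta <- if (m0 > 1e-3) 1 / m0 else 1
  } else {
    alpha_out <- alpha
    beta <- if (m0 > 1e-3) (1 - alpha) / m0 else 1
  }
  if (!is.finite(alpha_out) || !is.finite(beta) || alpha_out + beta * m0 < 0.05)
    stop_mbw("scaling anchors degenerate", "mbw_scaling_degenerate")
  structure(list(alpha = alpha_out, beta = beta, m0 = m0,
                 chamber_fraction_hat = 1 - alpha),
            class = "side_chamber_scaling")
}

#' Extract the SF6 signal
#'
#' Solves the two-compartment (main path + side chamber) mixing relation for
#' the main-path concentration:
#' `SF6(t) = C_max * (x(t) - m(t)) / (max_curve(t) - m(t))`, with
#' `max_curve = alpha + beta * m`. Values are clamped to `[0, 1.25 * C_max]`
#' and the clamped fraction reported. Per-breath end-tidal SF6 fractions are
#' computed over the last 5% of each breath's expired volume; the initial
#' (pre-washout plateau) end-tidal concentration is extracted from the last
#' washin breath under the full-chamber state.
#'
#' @param norm A `normalized_signal`.
#' @param min_curve Minimum curve from [interpolate_minimum_curve()].
#' @param scaling A `side_chamber_scaling`.
#' @param breaths A `breath_table`.
#' @param phases A `phase_annotation`.
#' @param c_max Tracer supply mole fraction (default 0.04).
#' @param cfg An [analysis_config()].
#' @return An object of class `sf6_signal`: a list with `index`, `time`,
#'   `breath`, `phase`, `sf6` (clamped mole fraction per washout sample),
#'   `et` (data frame of per-washout-breath end-tidal fractions),
#'   `et_initial`, `clamped_fraction` and `c_max`.
#' @export
extract_sf6 <- function(norm, min_curve, scaling, breaths, phases,
                        c_max = 0.04, cfg = analysis_config()) {
  wsel <- norm$breath >= phases$washout[1]
  w <- norm[wsel, ]
  den <- scaling$alpha + scaling$beta * min_curve - min_curve
  if (any(den < 0.05))
    stop_mbw("extraction denominator below minimum separation",
             "mbw_boundary_indistinct")
  sf6_raw <- c_max * (w$x - min_curve) / den
  sf6 <- pmin(pmax(sf6_raw, 0), 1.25 * c_max)
  # rectifying zero-mean noise around 0% is not meaningful signal loss; only
  # samples moved by more than 1% of C_max count as clamped
  clamped <- mean(abs(sf6 - sf6_raw) > 0.01 * c_max)

  # per-breath end-tidal SF6 over the last et_fraction of expired volume
  wb <- phases$washout[1]:phases$washout[2]
  et <- vapply(wb, function(b) {
    se <- w$breath == b & w$phase == "exp"
    v <- w$v_ml[se]
    y <- sf6[se]
    vtot <- max(v)
    stats::median(y[v >= (1 - cfg$et_fraction) * vtot])
  }, numeric(1))

  # plateau (initial) end-tidal: last washin breath, chamber still full
  lw <- phases$washin[2]
  sel <- norm$breath == lw & norm$phase == "exp"
  v <- norm$v_ml[sel]
  x_lw <- stats::median(norm$x[sel][v >= (1 - cfg$et_fraction) * max(v)])
  m_lw <- scaling$m0
  et_initial <- c_max * (x_lw - m_lw) /
    (scaling$alpha + scaling$beta * m_lw - m_lw)

  structure(list(index = w$index, time = w$time, breath = w$breath,
                 phase = w$phase, sf6 = sf6,
                 et = data.frame(washout_breath = seq_along(wb), breath = wb,
                                 et_sf6 = et),
                 et_initial = et_initial, clamped_fraction = clamped,
                 c_max = c_max),
            class = "sf6_signal")
}

#' Run the full side-chamber correction
#'
#' Convenience wrapper chaining [fit_inspiration_minimum()],
#' [interpolate_minimum_curve()], [scale_maximum_curve()] and
#' [extract_sf6()]. With `cfg$side_chamber_correction = FALSE` the normalized
#' signal is converted directly (`SF6 = C_max * x`), which is useful for
#' ablation studies.
#'
#' @inheritParams extract_sf6
#' @param rec A `raw_recording` (supplies the tracer fraction).
#' @return An `sf6_signal`; when the correction ran, the attribute
#'   `correction` carries the fits, minimum curve and scaling.
#' @export
side_chamber_correct <- function(norm, breaths, phases, rec,
                                 cfg = analysis_config()) {
  c_max <- cfg$tracer_fraction
  if (!cfg$side_chamber_correction) {
    wsel <- norm$breath >= phases$washout[1]
    w <- norm[wsel, ]
    sf6_raw <- c_max * w$x
    sf6 <- pmin(pmax(sf6_raw, 0), 1.25 * c_max)
    clamped <- mean(abs(sf6 - sf6_raw) > 0.01 * c_max)
    wb <- phases$washout[1]:phases$washout[2]
    et <- vapply(wb, function(b) {
      se <- w$breath == b & w$phase == "exp"
      v <- w$v_ml[se]
      stats::median(sf6[se][v >= (1 - cfg$et_fraction) * max(v)])
    }, numeric(1))
    lw <- phases$washin[2]
    sel <- norm$breath == lw & norm$phase == "exp"
    v <- norm$v_ml[sel]
    x_lw <- stats::median(norm$x[sel][v >= (1 - cfg$et_fraction) * max(v)])
    return(structure(list(index = w$index, time = w$time, breath = w$breath,
                          phase = w$phase, sf6 = sf6,
                          et = data.frame(washout_breath = seq_along(wb),
                                          breath = wb, et_sf6 = et),
                          et_initial = c_max * x_lw,
                          clamped_fraction = clamped,
                          c_max = c_max),
                     class = "sf6_signal"))
  }
  fits <- fit_inspiration_minimum(norm, breaths, phases)
  min_curve <- interpolate_minimum_curve(fits, norm, phases)
  scaling <- scale_maximum_curve(norm, phases, fits, cfg)
  out <- extract_sf6(norm, min_curve, scaling, breaths, phases, c_max, cfg)
  attr(out, "correction") <- list(fits = fits, min_curve = min_curve,
                                  scaling = scaling)
  out
}
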