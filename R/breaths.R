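# Breath segmentation and phase (pre / washin / washout) assignment.
#
# Breaths are cut at flow zero crossings after light moving-average smoothing
# (hysteresis against sensor noise); runs below a minimum volume or duration
# are merged into their neighbours. Phases are assigned on the per-breath
# end-tidal molar-mass series, which is robust to tidal confounders.

#' Cumulative volume trace
#'
#' Trapezoidal integral of the flow signal, in mL. No drift correction is
#' applied inside breaths.
#'
#' @param rec A `raw_recording`.
#' @return Numeric vector of cumulative volume (mL), same length as the
#'   recording.
#' @export
integrate_volume <- function(rec) {
  1000 * pracma::cumtrapz(rec$time, rec$flow)[, 1]
}

#' Detect breaths
#'
#' Segments the recording into breaths (inspiration followed by expiration)
#' from flow zero crossings with hysteresis. Candidate half-breaths below the
#' minimum volume or duration are merged into their neighbours. Each breath's
#' end-tidal molar mass is the median over the last `et_fraction` of its
#' expired volume.
#'
#' @param rec A `raw_recording`.
#' @param cfg An [analysis_config()].
#' @return A data frame of class `breath_table` with one row per breath:
#'   `breath`, `i_insp`, `i_exp`, `i_end` (sample indices of inspiration
#'   start, expiration start and breath end), `vol_insp_ml`, `vol_exp_ml`,
#'   `et_mm` and `duration_s`.
#' @export
detect_breaths <- function(rec, cfg = analysis_config()) {
  if (diff(range(rec$time)) < 2)
    stop_mbw("need at least 2 s of signal", "mbw_no_breaths")
  flow <- rec$flow
  w <- max(1L, round(cfg$flow_smooth_s * rec$sampling_rate))
  if (w > 1) {
    sm <- stats::filter(flow, rep(1 / w, w), sides = 2)
    sm[is.na(sm)] <- flow[is.na(sm)]
    flow_s <- as.numeric(sm)
  } else flow_s <- flow
  s <- sign(flow_s)
  # carry sign through exact zeros
  if (all(s == 0)) stop_mbw("no breaths detected (flow is zero)",
                            "mbw_no_breaths")
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  if (s[1] == 0) s[s == 0] <- s[which(s != 0)[1]]

  r <- rle(s)
  runs <- data.frame(len = r$lengths, sign = r$values)
  runs$end <- cumsum(runs$len)
  runs$start <- runs$end - runs$len + 1L

  dt <- 1 / rec$sampling_rate
  run_stats <- function(runs) {
    vol <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start[i]:runs$end[i]
      1000 * abs(pracma::trapz(rec$time[idx], rec$flow[idx]))
    }, numeric(1))
    dur <- runs$len * dt
    cbind(vol = vol, dur = dur)
  }
  st <- run_stats(runs)
  runs$vol <- st[, "vol"]; runs$dur <- st[, "dur"]

  # merge sub-threshold runs into neighbours until all runs are valid
  repeat {
    bad <- which(runs$vol < cfg$min_breath_volume_ml |
                   runs$dur < cfg$min_breath_duration_s)
    if (!length(bad) || nrow(runs) <= 1) break
    i <- bad[which.min(runs$vol[bad])]
    if (i == 1) {
      runs$start[2] <- runs$start[1]
      runs <- runs[-1, , drop = FALSE]
    } else if (i == nrow(runs)) {
      runs$end[i - 1] <- runs$end[i]
      runs <- runs[-i, , drop = FALSE]
    } else {
      # absorb run i and the following run into run i-1 (signs alternate)
      runs$end[i - 1] <- runs$end[i + 1]
      runs <- runs[-c(i, i + 1), , drop = FALSE]
    }
    runs$len <- runs$end - runs$start + 1L
    st <- run_stats(runs)
    runs$vol <- st[, "vol"]; runs$dur <- st[, "dur"]
  }

  # pair inspiration (+) runs with the following expiration (-) run
  first_pos <- which(runs$sign > 0)[1]
  if (is.na(first_pos)) stop_mbw("no breaths detected", "mbw_no_breaths")
  breaths <- list()
  i <- first_pos
  while (i + 1 <= nrow(runs)) {
    if (runs$sign[i] > 0 && runs$sign[i + 1] < 0) {
      breaths[[length(breaths) + 1]] <- c(
        i_insp = runs$start[i], i_exp = runs$start[i + 1],
        i_end = runs$end[i + 1],
        vol_insp = runs$vol[i], vol_exp = runs$vol[i + 1])
      i <- i + 2
    } else i <- i + 1
  }
  if (!length(breaths)) stop_mbw("no breaths detected", "mbw_no_breaths")
  b <- as.data.frame(do.call(rbind, breaths))
  names(b) <- c("i_insp", "i_exp", "i_end", "vol_insp_ml", "vol_exp_ml")
  b$breath <- seq_len(nrow(b))
  b$duration_s <- (b$i_end - b$i_insp) * dt
  b$et_mm <- vapply(seq_len(nrow(b)), function(k)
    end_tidal_value(rec$molar_mass, rec, b$i_exp[k], b$i_end[k],
                    cfg$et_fraction), numeric(1))
  b <- b[, c("breath", "i_insp", "i_exp", "i_end", "vol_insp_ml",
             "vol_exp_ml", "et_mm", "duration_s")]
  class(b) <- c("breath_table", "data.frame")
  b
}

# Median of `signal` over the last `frac` of expired volume of one expiration.
end_tidal_value <- function(signal, rec, i_exp, i_end, frac = 0.05) {
  idx <- i_exp:i_end
  v <- 1000 * pracma::cumtrapz(rec$time[idx], abs(rec$flow[idx]))[, 1]
  vtot <- v[length(v)]
  sel <- v >= (1 - frac) * vtot
  stats::median(signal[idx][sel])
}

#' Assign breaths to pre-phase, washin and washout
#'
#' Operates on the per-breath end-tidal molar-mass series. The pre-phase grows
#' from the start of the recording while end-tidal values stay within
#' `phase_k` spreads of the running pre-phase median; the first breath
#' exceeding that threshold starts the washin. The washout starts at the first
#' subsequent breath whose end-tidal value falls below the running washin
#' maximum by `washout_drop_frac` of the washin rise. Washin is flagged
#' complete when the last `plateau_breaths` washin end-tidals have relative
#' spread below `plateau_tol`.
#'
#' @param rec A `raw_recording`.
#' @param breaths A `breath_table` from [detect_breaths()].
#' @param cfg An [analysis_config()].
#' @return An object of class `phase_annotation`: a list with integer ranges
#'   `pre`, `washin`, `washout` (first and last breath numbers) and the flag
#'   `washin_complete`.
#' @export
detect_phases <- function(rec, breaths, cfg = analysis_config()) {
  et <- breaths$et_mm
  nb <- length(et)
  if (nb < 3) stop_mbw("need at least 3 breaths", "mbw_no_breaths")

  washin_start <- NA_integer_
  for (i in 2:nb) {
    prior <- et[1:(i - 1)]
    thr <- cfg$phase_k * max(stats::mad(prior), cfg$spread_floor_gmol)
    if (et[i] > stats::median(prior) + thr) { washin_start <- i; break }
  }
  if (is.na(washin_start))
    stop_mbw("no washin detected (no tracer rise in end-tidal molar mass)",
             "mbw_missing_washin")
  if (washin_start < 4)
    stop_mbw("missing pre-phase (fewer than 3 tracer-free breaths)",
             "mbw_missing_prephase")
  pre <- c(1L, washin_start - 1L)
  pre_med <- stats::median(et[1:(washin_start - 1)])
  pre_spread <- max(stats::mad(et[1:(washin_start - 1)]),
                    cfg$spread_floor_gmol)
  rise <- max(et[washin_start:nb]) - pre_med
  if (rise < cfg$min_rise_gmol)
    stop_mbw("washin rise below minimum detectable level",
             "mbw_missing_washin")

  washout_start <- NA_integer_
  if (washin_start < nb) {
    run_max <- et[washin_start]
    drop_thr <- max(cfg$phase_k * pre_spread, cfg$washout_drop_frac * rise)
    for (j in (washin_start + 1):nb) {
      if (et[j] < run_max - drop_thr) { washout_start <- j; break }
      run_max <- max(run_max, et[j])
    }
  }
  if (is.na(washout_start))
    stop_mbw("missing washout (end-tidal molar mass never falls)",
             "mbw_missing_washout")
  washin <- c(washin_start, washout_start - 1L)
  washout <- c(washout_start, nb)

  n_wi <- washin[2] - washin[1] + 1L
  m <- min(cfg$plateau_breaths, n_wi)
  tail_et <- et[(washin[2] - m + 1L):washin[2]]
  washin_complete <- n_wi >= 3 &&
    (max(tail_et) - min(tail_et)) / stats::median(tail_et) < cfg$plateau_tol

  structure(list(pre = pre, washin = washin, washout = washout,
                 washin_complete = washin_complete),
            class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  cat(sprintf(
    "<phase_annotation> pre %d-%d | washin %d-%d (complete: %s) | washout %d-%d\n",
    x$pre[1], x$pre[2], x$washin[1], x$washin[2], x$washin_complete,
    x$washout[1], x$washout[2]))
  invisible(x)
}

# Per-sample annotation: breath number, phase within breath and cumulative
# volume within the phase (mL). Samples outside any breath get breath = NA.
annotate_samples <- function(rec, breaths) {
  n <- length(rec$time)
  breath <- rep(NA_integer_, n)
  phase <- rep(NA_character_, n)
  v_ml <- rep(NA_real_, n)
  for (k in seq_len(nrow(breaths))) {
    ii <- breaths$i_insp[k]:(breaths$i_exp[k] - 1L)
    ie <- breaths$i_exp[k]:breaths$i_end[k]
    breath[ii] <- k; breath[ie] <- k
    phase[ii] <- "insp"; phase[ie] <- "exp"
    v_ml[ii] <- 1000 * pracma::cumtrapz(rec$time[ii], abs(rec$flow[ii]))[, 1]
    v_ml[ie] <- 1000 * pracma::cumtrapz(rec$time[ie], abs(rec$flow[ie]))[, 1]
  }
  data.frame(index = seq_len(n), time = rec$time, breath = breath,
             phase = phase, v_ml = v_ml)
}
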