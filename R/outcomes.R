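# Outcome computation: BTPS correction of flow, end-of-test detection, FRC,
# CEV and LCI.

#' BTPS-correct the flow signal
#'
#' Scales inspiration samples by the inspiration BTPS factor and expiration
#' samples by the expiration factor (phase taken from the detected breaths).
#' With `mode = "none"` (ATP; appropriate for a water-bath lung model without
#' a body compartment) the flow is returned unchanged.
#'
#' @param rec A `raw_recording`.
#' @param breaths A `breath_table`.
#' @param cond An `ambient_conditions` (defaults to the recording's metadata).
#' @param mode `"btps"` or `"none"`.
#' @return Corrected flow vector (L/s), same length as the recording.
#' @export
btps_correct_flow <- function(rec, breaths, cond = rec$meta$ambient,
                              mode = c("btps", "none")) {
  mode <- match.arg(mode)
  flow <- rec$flow
  if (mode == "none") return(flow)
  f_in <- btps_factor(cond, "inspiration")
  f_ex <- btps_factor(cond, "expiration")
  for (k in seq_len(nrow(breaths))) {
    ii <- breaths$i_insp[k]:(breaths$i_exp[k] - 1L)
    ie <- breaths$i_exp[k]:breaths$i_end[k]
    flow[ii] <- flow[ii] * f_in
    flow[ie] <- flow[ie] * f_ex
  }
  flow
}

#' Detect the end of test
#'
#' The test ends at the first washout breath whose end-tidal tracer
#' concentration falls below `ratio` times the initial concentration
#' (default 2.5%). With `consensus = TRUE` the value must stay below
#' threshold for that breath and the two following.
#'
#' @param et Numeric vector of per-washout-breath end-tidal SF6 fractions, or
#'   an `sf6_signal` (its `et$et_sf6` and `et_initial` are used).
#' @param ratio End-of-test ratio (default 0.025).
#' @param initial Initial end-tidal concentration; defaults to the stored
#'   plateau value for an `sf6_signal`, else to `et[1]`.
#' @param consensus Require three consecutive breaths below threshold.
#' @return The 1-based index of the end-of-test breath within the washout.
#' @export
detect_end_of_test <- function(et, ratio = 0.025, initial = NULL,
                               consensus = FALSE) {
  if (inherits(et, "sf6_signal")) {
    if (is.null(initial)) initial <- et$et_initial
    et <- et$et$et_sf6
  }
  if (is.null(initial)) initial <- et[1]
  below <- et < ratio * initial
  idx <- if (!consensus) which(below) else {
    n <- length(below)
    which(below & c(below[-1], FALSE) & c(below[-(1:2)], FALSE, FALSE))
  }
  if (!length(idx))
    stop_mbw("washout incomplete: end-tidal concentration never reached the end-of-test threshold",
             "mbw_washout_incomplete")
  idx[1]
}

#' Compute FRC
#'
#' Net expired tracer volume (expired minus re-inspired, integrated over the
#' washout samples through the end-of-test breath) divided by the end-tidal
#' concentration drop, minus the apparatus dead space:
#' `FRC = net_SF6_volume / (C_initial - C_final) - dead_space`.
#'
#' @param sf6 An `sf6_signal`.
#' @param flow_corr (BTPS-)corrected flow vector for the whole recording.
#' @param rec A `raw_recording`.
#' @param breaths A `breath_table`.
#' @param phases A `phase_annotation`.
#' @param eot End-of-test washout breath index from [detect_end_of_test()].
#' @param dead_space_ml Apparatus dead space (mL) to subtract.
#' @return FRC in mL.
#' @export
compute_frc <- function(sf6, flow_corr, rec, breaths, phases, eot,
                        dead_space_ml = 4.6) {
  wb <- phases$washout[1]:phases$washout[2]
  last_b <- wb[eot]
  sel <- sf6$breath <= last_b
  f <- flow_corr[sf6$index[sel]]
  dt <- 1 / rec$sampling_rate
  c_sf6 <- sf6$sf6[sel]
  expired <- sum(c_sf6[f < 0] * (-f[f < 0])) * dt * 1000
  reinspired <- sum(c_sf6[f > 0] * f[f > 0]) * dt * 1000
  et_final <- sf6$et$et_sf6[eot]
  denom <- sf6$et_initial - et_final
  if (denom <= 0)
    stop_mbw("FRC invalid: non-positive concentration drop", "mbw_frc_invalid")
  frc <- (expired - reinspired) / denom - dead_space_ml
  if (frc <= 0)
    stop_mbw("FRC invalid: non-positive after dead-space subtraction",
             "mbw_frc_invalid")
  frc
}

#' Compute CEV and LCI
#'
#' CEV is the cumulative expired volume from the washout start through the
#' end-of-test breath; with `subtract_dead_space = TRUE` (default) one
#' apparatus dead space is removed per breath so LCI reflects alveolar gas
#' turnover. LCI = CEV / FRC, in turnovers (TO).
#'
#' @param flow_corr Corrected flow vector.
#' @param rec A `raw_recording`.
#' @param breaths A `breath_table`.
#' @param phases A `phase_annotation`.
#' @param eot End-of-test washout breath index.
#' @param frc FRC in mL.
#' @param dead_space_ml Apparatus dead space (mL).
#' @param subtract_dead_space Subtract `dead_space_ml` per breath from CEV.
#' @return A list with `cev_ml` and `lci_to`.
#' @export
compute_cev_lci <- function(flow_corr, rec, breaths, phases, eot, frc,
                            dead_space_ml = 4.6, subtract_dead_space = TRUE) {
  wb <- phases$washout[1]:(phases$washout[1] + eot - 1L)
  dt <- 1 / rec$sampling_rate
  vol_exp <- vapply(wb, function(b) {
    idx <- breaths$i_exp[b]:breaths$i_end[b]
    f <- flow_corr[idx]
    sum(-f[f < 0]) * dt * 1000
  }, numeric(1))
  cev <- sum(vol_exp) - if (subtract_dead_space) length(wb) * dead_space_ml else 0
  list(cev_ml = cev, lci_to = cev / frc)
}

#' Analyze a washout recording end to end
#'
#' Runs the five algorithm stages in order: breath and phase detection, tidal
#' change correction, side-chamber correction, BTPS correction of flow, and
#' outcome calculation.
#'
#' @param rec A `raw_recording`.
#' @param cfg An [analysis_config()]. The recording's metadata supplies the
#'   ambient conditions and (unless overridden here) the dead space and tracer
#'   fraction.
#' @param strict If `TRUE` (default) an incomplete washin raises a QC error;
#'   if `FALSE` analysis proceeds and the trial is flagged.
#' @return An object of class `mbw_result`: a list with `outcomes` (an
#'   `mbw_outcomes`), plus the intermediates `breaths`, `phases`,
#'   `respirograms`, `normalized`, `sf6` and the `config` used.
#' @export
analyze_recording <- function(rec, cfg = analysis_config(), strict = TRUE) {
  breaths <- detect_breaths(rec, cfg)
  phases <- detect_phases(rec, breaths, cfg)
  flags <- character(0)
  if (!phases$washin_complete) {
    if (strict)
      stop_mbw("washin incomplete: end-tidal plateau not reached",
               "mbw_washin_incomplete")
    flags <- c(flags, "washin_incomplete")
  }
  if (cfg$tidal_change_correction) {
    rg <- build_respirograms(rec, breaths, phases, cfg)
    norm <- apply_tcc(rec, breaths, phases, rg, cfg)
  } else {
    rg <- NULL
    norm <- normalize_two_point(rec, breaths, phases, cfg)
  }
  if (length(attr(norm, "flagged_breaths")))
    flags <- c(flags, "over_range_breaths")
  sf6 <- side_chamber_correct(norm, breaths, phases, rec, cfg)
  if (sf6$clamped_fraction > cfg$qc_clamp_frac_max)
    flags <- c(flags, "clamping_excess")

  flow_corr <- btps_correct_flow(rec, breaths, rec$meta$ambient,
                                 mode = if (cfg$btps_mode == "btps") "btps" else "none")
  eot <- detect_end_of_test(sf6, ratio = cfg$end_of_test_ratio,
                            consensus = cfg$eot_consensus)
  frc <- compute_frc(sf6, flow_corr, rec, breaths, phases, eot,
                     dead_space_ml = cfg$dead_space_ml)
  cl <- compute_cev_lci(flow_corr, rec, breaths, phases, eot, frc,
                        dead_space_ml = cfg$dead_space_ml,
                        subtract_dead_space = cfg$subtract_dead_space_cev)

  # irregular-breathing stand-in for visual QC
  wo_vols <- breaths$vol_exp_ml[phases$washout[1]:phases$washout[2]]
  if (stats::sd(wo_vols) / mean(wo_vols) > cfg$qc_vol_cv_max)
    flags <- c(flags, "irregular_breathing")

  outcomes <- structure(list(
    frc_ml = frc, cev_ml = cl$cev_ml, lci_to = cl$lci_to,
    eot_breath = eot,
    breath_count = eot,
    et_initial = sf6$et_initial,
    et_final = sf6$et$et_sf6[eot],
    et_sf6 = sf6$et$et_sf6,
    dead_space_ml = cfg$dead_space_ml,
    clamped_fraction = sf6$clamped_fraction,
    washin_complete = phases$washin_complete,
    flags = flags), class = "mbw_outcomes")

  structure(list(outcomes = outcomes, breaths = breaths, phases = phases,
                 respirograms = rg, normalized = norm, sf6 = sf6,
                 config = cfg), class = "mbw_result")
}

#' @export
print.mbw_outcomes <- function(x, ...) {
  cat("<mbw_outcomes>\n")
  cat(sprintf("  FRC  %8.1f mL\n", x$frc_ml))
  cat(sprintf("  CEV  %8.1f mL\n", x$cev_ml))
  cat(sprintf("  LCI  %8.2f TO\n", x$lci_to))
  cat(sprintf("  end of test at washout breath %d (ET %.4f%% from %.3f%%)\n",
              x$eot_breath, 100 * x$et_final, 100 * x$et_initial))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mbw_result <- function(x, ...) {
  print(x$outcomes)
  invisible(x)
}
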