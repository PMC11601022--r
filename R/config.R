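# Analysis configuration: every tunable of the pipeline, with documented
# defaults, plus YAML round-tripping so a published analysis is reproducible
# from its config file alone.

#' Analysis configuration
#'
#' Collects every tunable parameter of the washout analysis pipeline. All
#' arguments have defaults suitable for infant SF6 recordings; pass only what
#' you want to change.
#'
#' @param dead_space_ml Total apparatus dead space in mL, subtracted from the
#'   raw FRC estimate (4.6 mL for infants, 9.6 mL for toddlers).
#' @param tracer_fraction Supply SF6 mole fraction at full washin (default 0.04).
#' @param end_of_test_ratio End-of-test threshold as a fraction of the initial
#'   end-tidal tracer concentration (default 0.025, i.e. 2.5%).
#' @param eot_consensus If `TRUE`, require the end-tidal concentration to stay
#'   below threshold for three consecutive breaths (consensus-guideline style);
#'   default `FALSE`: the first breath below threshold ends the test.
#' @param btps_mode `"none"` reports volumes at sensor (ATP) conditions, as
#'   appropriate for a water-bath lung model without a body compartment;
#'   `"btps"` applies phase-wise BTPS factors from the recording's ambient
#'   metadata.
#' @param min_breath_volume_ml,min_breath_duration_s Breaths smaller/shorter
#'   than this are merged into their neighbours.
#' @param flow_smooth_s Width (s) of the moving-average filter applied to flow
#'   before zero-crossing detection (hysteresis against noise).
#' @param et_fraction End-tidal window: fraction of expired volume (from the
#'   end) over which the median defines the end-tidal value.
#' @param phase_k Phase detection: a breath starts the washin when its
#'   end-tidal molar mass exceeds the pre-phase median by `phase_k` times the
#'   pre-phase spread.
#' @param spread_floor_gmol Noise floor (g/mol) for the pre-phase end-tidal
#'   spread, so noiseless recordings do not produce a zero threshold.
#' @param washout_drop_frac Washout starts at the first breath whose end-tidal
#'   molar mass falls below the running washin maximum by this fraction of the
#'   washin rise.
#' @param min_rise_gmol Minimum washin rise (g/mol) for a recording to contain
#'   a detectable washin at all.
#' @param plateau_breaths,plateau_tol Washin is complete when the last
#'   `plateau_breaths` washin end-tidals have relative spread below
#'   `plateau_tol`.
#' @param bin_width_ml Respirogram volume-bin width in mL.
#' @param max_boundary_breaths Number of late-washin breaths used for the
#'   maximum-concentration respirograms.
#' @param min_boundary_separation_gmol Minimum separation of the two boundary
#'   respirograms; below this the tidal-change correction is ill-posed.
#' @param over_range_breath_frac A breath with more than this fraction of
#'   samples beyond the respirogram volume range is flagged for QC.
#' @param tidal_change_correction Toggle for the respirogram-based correction.
#'   When off, a volume-independent two-point calibration (pre-phase vs washin
#'   plateau end-tidal medians) is used instead.
#' @param side_chamber_correction Toggle for the side-chamber correction.
#' @param scale_mode `"affine"` (two anchor conditions, default) or
#'   `"proportional"` (single scale factor) construction of the maximum
#'   side-chamber curve.
#' @param subtract_dead_space_cev Subtract the apparatus dead space from each
#'   breath's contribution to CEV (default `TRUE`, so LCI reflects alveolar
#'   gas turnover).
#' @param qc_clamp_frac_max Maximum tolerated fraction of clamped SF6 samples
#'   before a trial is QC-flagged.
#' @param qc_vol_cv_max Maximum tolerated within-phase coefficient of variation
#'   of breath volumes (irregular-breathing stand-in for visual QC).
#' @return An object of class `mbw_config` (a named list).
#' @export
analysis_config <- function(dead_space_ml = 4.6,
                            tracer_fraction = 0.04,
                            end_of_test_ratio = 0.025,
                            eot_consensus = FALSE,
                            btps_mode = c("none", "btps"),
                            min_breath_volume_ml = 2,
                            min_breath_duration_s = 0.3,
                            flow_smooth_s = 0.05,
                            et_fraction = 0.05,
                            phase_k = 5,
                            spread_floor_gmol = 0.02,
                            washout_drop_frac = 0.08,
                            min_rise_gmol = 1,
                            plateau_breaths = 5,
                            plateau_tol = 0.005,
                            bin_width_ml = 1,
                            max_boundary_breaths = 5,
                            min_boundary_separation_gmol = 0.05,
                            over_range_breath_frac = 0.10,
                            tidal_change_correction = TRUE,
                            side_chamber_correction = TRUE,
                            scale_mode = c("affine", "proportional"),
                            subtract_dead_space_cev = TRUE,
                            qc_clamp_frac_max = 0.05,
                            qc_vol_cv_max = 0.40) {
  btps_mode <- match.arg(btps_mode)
  scale_mode <- match.arg(scale_mode)
  if (end_of_test_ratio <= 0 || end_of_test_ratio >= 1)
    stop_mbw("end_of_test_ratio must lie in (0, 1)", "mbw_invalid_config")
  if (dead_space_ml < 0)
    stop_mbw("dead_space_ml must be >= 0", "mbw_invalid_config")
  if (tracer_fraction <= 0 || tracer_fraction > 0.1)
    stop_mbw("tracer_fraction must lie in (0, 0.1]", "mbw_invalid_config")
  cfg <- list(
    dead_space_ml = dead_space_ml,
    tracer_fraction = tracer_fraction,
    end_of_test_ratio = end_of_test_ratio,
    eot_consensus = eot_consensus,
    btps_mode = btps_mode,
    min_breath_volume_ml = min_breath_volume_ml,
    min_breath_duration_s = min_breath_duration_s,
    flow_smooth_s = flow_smooth_s,
    et_fraction = et_fraction,
    phase_k = phase_k,
    spread_floor_gmol = spread_floor_gmol,
    washout_drop_frac = washout_drop_frac,
    min_rise_gmol = min_rise_gmol,
    plateau_breaths = plateau_breaths,
    plateau_tol = plateau_tol,
    bin_width_ml = bin_width_ml,
    max_boundary_breaths = max_boundary_breaths,
    min_boundary_separation_gmol = min_boundary_separation_gmol,
    over_range_breath_frac = over_range_breath_frac,
    tidal_change_correction = tidal_change_correction,
    side_chamber_correction = side_chamber_correction,
    scale_mode = scale_mode,
    subtract_dead_space_cev = subtract_dead_space_cev,
    qc_clamp_frac_max = qc_clamp_frac_max,
    qc_vol_cv_max = qc_vol_cv_max
  )
  structure(cfg, class = "mbw_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return An `mbw_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop_mbw("config YAML must be a mapping", "mbw_parse_error")
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_mbw(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
             "mbw_parse_error")
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML
#'
#' @param cfg An `mbw_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.mbw_config <- function(x, ...) {
  cat("<mbw_config>\n")
  for (k in names(x)) cat(sprintf("  %-30s %s\n", k, format(x[[k]])))
  invisible(x)
}
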