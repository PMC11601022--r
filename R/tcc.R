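# Tidal change correction: normalise the molar-mass signal against
# volume-domain boundary respirograms recorded at known SF6 concentrations
# (pre-phase = 0%, end of washin = maximum), cancelling tidal temperature,
# humidity and gas-exchange confounders without a temperature model.

#' Build boundary respirograms
#'
#' For each of the four boundary conditions (minimum/maximum SF6 x
#' inspiration/expiration), re-indexes each contributing breath's molar-mass
#' samples by cumulative volume within the phase, bins them on a common
#' volume grid, and takes the per-bin median across breaths. Minimum-SF6
#' breaths are the pre-phase breaths; maximum-SF6 breaths are the last
#' `max_boundary_breaths` washin breaths.
#'
#' @param rec A `raw_recording`.
#' @param breaths A `breath_table`.
#' @param phases A `phase_annotation` (washin must be complete).
#' @param cfg An [analysis_config()].
#' @return An object of class `respirogram_set`: a list with elements
#'   `min_insp`, `min_exp`, `max_insp`, `max_exp`, each a list with `volume`
#'   (bin centres, mL), `mm` (median molar mass per bin, g/mol), `n_breaths`
#'   and `label`.
#' @export
build_respirograms <- function(rec, breaths, phases, cfg = analysis_config()) {
  ann <- annotate_samples(rec, breaths)
  sets <- list(
    min = phases$pre[1]:phases$pre[2],
    max = seq(max(phases$washin[1],
                  phases$washin[2] - cfg$max_boundary_breaths + 1L),
              phases$washin[2])
  )
  out <- list()
  for (cond in names(sets)) {
    bset <- sets[[cond]]
    if (length(bset) < 3)
      stop_mbw(sprintf("insufficient boundary breaths for %s condition (%d < 3)",
                       cond, length(bset)), "mbw_insufficient_boundary")
    for (ph in c("insp", "exp")) {
      sel <- ann$breath %in% bset & ann$phase == ph & !is.na(ann$v_ml)
      v <- ann$v_ml[sel]
      mm <- rec$molar_mass[ann$index[sel]]
      bid <- ann$breath[sel]
      bin <- floor(v / cfg$bin_width_ml)
      # per-breath median within each bin, then median across breaths
      key <- interaction(bid, bin, drop = TRUE)
      per <- tapply(mm, key, stats::median)
      kb <- do.call(rbind, strsplit(names(per), ".", fixed = TRUE))
      bin_of <- as.integer(kb[, 2])
      agg_n <- tapply(per, bin_of, length)
      agg_med <- tapply(per, bin_of, stats::median)
      bins <- as.integer(names(agg_med))
      keep <- agg_n >= max(2L, ceiling(length(bset) / 2))
      if (sum(keep) < 2)
        stop_mbw("insufficient volume coverage for respirogram",
                 "mbw_insufficient_boundary")
      o <- order(bins[keep])
      out[[paste(cond, ph, sep = "_")]] <- list(
        volume = (bins[keep][o] + 0.5) * cfg$bin_width_ml,
        mm = as.numeric(agg_med[keep][o]),
        n_breaths = length(bset),
        label = paste(cond, ph, sep = "_"))
    }
  }
  structure(out, class = "respirogram_set")
}

# Evaluate a respirogram at volumes v (linear interpolation between bins,
# clamped to the end bins outside the covered range).
eval_respirogram <- function(rg, v) {
  stats::approx(rg$volume, rg$mm, xout = v, rule = 2)$y
}

#' Apply the tidal change correction
#'
#' Normalises every sample between the matching-phase minimum and maximum
#' boundary respirograms: `x = (MM - MM0(v)) / (MMmax(v) - MM0(v))`, so that
#' 0 corresponds to 0% SF6 and 1 to the full washin concentration, at the
#' sample's phase and volume-in-breath. Samples whose volume exceeds the
#' respirogram range use the clamped end-bin values and are flagged; breaths
#' with more than `over_range_breath_frac` flagged samples are flagged for QC.
#'
#' @param rec A `raw_recording`.
#' @param breaths A `breath_table`.
#' @param phases A `phase_annotation`.
#' @param respirograms A `respirogram_set` from [build_respirograms()].
#' @param cfg An [analysis_config()].
#' @return An object of class `normalized_signal`: a data frame with columns
#'   `index`, `time`, `breath`, `phase`, `v_ml`, `x` and `over_range`, plus
#'   attributes `flagged_breaths` and `phases`.
#' @export
apply_tcc <- function(rec, breaths, phases, respirograms,
                      cfg = analysis_config()) {
  ann <- annotate_samples(rec, breaths)
  ann <- ann[!is.na(ann$breath), ]
  x <- rep(NA_real_, nrow(ann))
  over <- rep(FALSE, nrow(ann))
  for (ph in c("insp", "exp")) {
    sel <- ann$phase == ph
    v <- ann$v_ml[sel]
    lo <- eval_respirogram(respirograms[[paste0("min_", ph)]], v)
    hi <- eval_respirogram(respirograms[[paste0("max_", ph)]], v)
    den <- hi - lo
    wash_sel <- ann$breath[sel] >= phases$washout[1]
    if (any(abs(den[wash_sel]) < cfg$min_boundary_separation_gmol))
      stop_mbw("boundary traces indistinct (respirograms closer than minimum separation)",
               "mbw_boundary_indistinct")
    x[sel] <- (rec$molar_mass[ann$index[sel]] - lo) / den
    over[sel] <- v > max(respirograms[[paste0("min_", ph)]]$volume) |
      v > max(respirograms[[paste0("max_", ph)]]$volume)
  }
  ann$x <- x
  ann$over_range <- over
  frac_over <- tapply(over, ann$breath, mean)
  flagged <- as.integer(names(frac_over))[frac_over > cfg$over_range_breath_frac]
  structure(ann, class = c("normalized_signal", "data.frame"),
            flagged_breaths = flagged, phases = phases)
}

# Volume-independent fallback normalisation used when the tidal change
# correction is disabled: a global two-point calibration between the
# pre-phase and washin-plateau end-tidal medians.
normalize_two_point <- function(rec, breaths, phases, cfg = analysis_config()) {
  ann <- annotate_samples(rec, breaths)
  ann <- ann[!is.na(ann$breath), ]
  pre_et <- stats::median(breaths$et_mm[phases$pre[1]:phases$pre[2]])
  m <- min(cfg$max_boundary_breaths, phases$washin[2] - phases$washin[1] + 1L)
  hi_et <- stats::median(breaths$et_mm[(phases$washin[2] - m + 1L):phases$washin[2]])
  if (abs(hi_et - pre_et) < cfg$min_boundary_separation_gmol)
    stop_mbw("boundary levels indistinct", "mbw_boundary_indistinct")
  ann$x <- (rec$molar_mass[ann$index] - pre_et) / (hi_et - pre_et)
  ann$over_range <- FALSE
  structure(ann, class = c("normalized_signal", "data.frame"),
            flagged_breaths = integer(0), phases = phases)
}
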