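# Visit-level quality control: the numeric acceptability rule (at least two
# trials whose LCI and FRC both lie within 25% of the accepted-set mean) with
# automatic signal-quality flags standing in for visual QC.

#' Assess a study visit
#'
#' Trials whose QC flags failed are dropped first. Then, iteratively: the mean
#' LCI and mean FRC of the remaining trials are computed and any trial
#' deviating by more than `tolerance` from either mean is dropped; this
#' repeats to a fixed point. The rule depends only on the set of remaining
#' trials, so the result is independent of trial order. The visit is valid
#' if at least two trials remain.
#'
#' @param trials A list of `mbw_outcomes` objects, or a data frame with
#'   columns `frc_ml`, `lci_to` and optionally `flags_ok` (logical).
#' @param tolerance Maximum relative deviation from the accepted-set mean
#'   (default 0.25).
#' @return An object of class `visit_qc`: a list with `accepted` (trial
#'   indices), `rejected`, `valid` and `reasons` (character, per rejected
#'   trial).
#' @export
assess_visit <- function(trials, tolerance = 0.25) {
  if (is.data.frame(trials)) {
    df <- trials
    if (is.null(df$flags_ok)) df$flags_ok <- TRUE
  } else {
    df <- data.frame(
      frc_ml = vapply(trials, function(t) t$frc_ml, numeric(1)),
      lci_to = vapply(trials, function(t) t$lci_to, numeric(1)),
      flags_ok = vapply(trials, function(t) length(t$flags) == 0, logical(1)))
  }
  n <- nrow(df)
  reasons <- rep(NA_character_, n)
  active <- df$flags_ok
  reasons[!active] <- "failed signal-quality flags"

  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    mean_frc <- mean(df$frc_ml[idx])
    mean_lci <- mean(df$lci_to[idx])
    dev <- pmax(abs(df$frc_ml[idx] - mean_frc) / mean_frc,
                abs(df$lci_to[idx] - mean_lci) / mean_lci)
    if (max(dev) <= tolerance) break
    drop <- idx[dev > tolerance]
    active[drop] <- FALSE
    reasons[drop] <- sprintf("outcome deviates %.0f%% from set mean",
                             100 * dev[dev > tolerance])
  }
  accepted <- which(active)
  valid <- length(accepted) >= 2
  structure(list(accepted = accepted, rejected = which(!active),
                 valid = valid,
                 reasons = reasons[!active],
                 n_trials = n,
                 mean_frc_ml = if (length(accepted)) mean(df$frc_ml[accepted]) else NA_real_,
                 mean_lci_to = if (length(accepted)) mean(df$lci_to[accepted]) else NA_real_),
            class = "visit_qc")
}

#' @export
print.visit_qc <- function(x, ...) {
  cat(sprintf("<visit_qc> %s: %d/%d trials accepted\n",
              if (x$valid) "VALID" else "INVALID",
              length(x$accepted), x$n_trials))
  if (length(x$rejected))
    cat("  rejected:", paste(sprintf("#%d (%s)", x$rejected, x$reasons),
                             collapse = "; "), "\n")
  invisible(x)
}
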