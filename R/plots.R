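# Diagnostic plots: volume-domain boundary respirograms and the washout
# correction curves. Base graphics; callers open a device (png/svg) around
# these when writing files.

#' Plot the four boundary respirograms
#'
#' @param rg A `respirogram_set`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_respirograms <- function(rg, ...) {
  cols <- c(min_insp = "steelblue", min_exp = "firebrick",
            max_insp = "steelblue", max_exp = "firebrick")
  lts <- c(min_insp = 1, min_exp = 1, max_insp = 2, max_exp = 2)
  xr <- range(unlist(lapply(rg, `[[`, "volume")))
  yr <- range(unlist(lapply(rg, `[[`, "mm")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "volume in breath (mL)",
                 ylab = "molar mass (g/mol)",
                 main = "Boundary respirograms", ...)
  for (k in names(rg))
    graphics::lines(rg[[k]]$volume, rg[[k]]$mm, col = cols[[k]],
                    lty = lts[[k]])
  graphics::legend("topleft", bty = "n", cex = 0.8,
                   legend = c("inspiration 0%", "expiration 0%",
                              "inspiration max", "expiration max"),
                   col = cols, lty = lts)
  invisible(rg)
}

#' Plot the side-chamber correction for a stretch of the washout
#'
#' Shows the normalized signal, the fitted minimum (chamber carry-over) curve,
#' the scaled maximum curve, and the final extracted SF6 signal.
#'
#' @param result An `mbw_result` from [analyze_recording()] (with the
#'   side-chamber correction enabled).
#' @param t_range Time window (s) to display; default first 4 s of washout.
#' @export
plot_correction <- function(result, t_range = NULL) {
  sf6 <- result$sf6
  corr <- attr(sf6, "correction")
  if (is.null(corr))
    stop_mbw("result was computed without the side-chamber correction",
             "mbw_invalid_config")
  norm <- result$normalized
  wsel <- norm$breath >= result$phases$washout[1]
  w <- norm[wsel, ]
  if (is.null(t_range)) t_range <- w$time[1] + c(0, 4)
  sel <- w$time >= t_range[1] & w$time <= t_range[2]
  sc <- corr$scaling
  mx <- sc$alpha + sc$beta * corr$min_curve
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(w$time[sel], w$x[sel], type = "l",
                 xlab = "time (s)", ylab = "normalized signal",
                 main = "Side-chamber correction")
  graphics::lines(w$time[sel], corr$min_curve[sel], col = "steelblue")
  graphics::lines(w$time[sel], mx[sel], col = "steelblue", lty = 2)
  sels <- sf6$time >= t_range[1] & sf6$time <= t_range[2]
  graphics::plot(sf6$time[sels], 100 * sf6$sf6[sels], type = "l",
                 xlab = "time (s)", ylab = "SF6 (%)",
                 main = "Extracted SF6 signal")
  invisible(result)
}
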