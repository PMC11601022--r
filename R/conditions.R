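# Typed error conditions. Every failure mode of the pipeline raises a classed
# condition so callers (and the CLI) can map it to a machine-readable category.

stop_mbw <- function(message, class) {
  stop(structure(
    class = c(class, "mbw_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Map a caught pipeline error to its machine-readable category
#'
#' @param e A condition object.
#' @return A short category string, e.g. `"missing_washout"`.
#' @export
mbw_error_category <- function(e) {
  cls <- class(e)[1]
  if (startsWith(cls, "mbw_")) sub("^mbw_", "", cls) else "unknown"
}
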