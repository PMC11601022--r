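# Raw recording container and its open on-disk dialect: a comment header of
# `# key: value` metadata followed by CSV/TSV columns
# time_s, flow_lps, molar_mass_gmol.

#' Construct a raw washout recording
#'
#' @param time Sample times in seconds, a strictly increasing uniform grid.
#' @param flow Flow in L/s at the sensor; positive = inspiration.
#' @param molar_mass Displayed molar-mass signal in g/mol.
#' @param sampling_rate Sampling rate in Hz (>= 50).
#' @param meta A list of metadata: `ambient` (an [ambient_conditions()]),
#'   `dead_space_ml`, `weight_kg`, `tracer_fraction`, and optionally
#'   `frc_true_ml` (simulations only).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(time, flow, molar_mass, sampling_rate,
                          meta = list()) {
  n <- length(time)
  if (length(flow) != n || length(molar_mass) != n)
    stop_mbw("time, flow and molar_mass must have equal length",
             "mbw_parse_error")
  if (n < 2) stop_mbw("recording too short", "mbw_parse_error")
  if (!is.numeric(sampling_rate) || sampling_rate < 50)
    stop_mbw("sampling_rate must be a uniform rate >= 50 Hz", "mbw_parse_error")
  dt <- diff(time)
  if (any(dt <= 0))
    stop_mbw("non-monotonic time", "mbw_parse_error")
  if (any(abs(dt - 1 / sampling_rate) > 1e-6))
    stop_mbw("time grid not uniform at the declared sampling rate",
             "mbw_parse_error")
  bad <- which(molar_mass < 20 | molar_mass > 60)
  if (length(bad))
    stop_mbw(sprintf(
      "molar mass out of physiological range [20, 60] g/mol at row %d (%.3f)",
      bad[1], molar_mass[bad[1]]), "mbw_parse_error")
  defaults <- list(ambient = ambient_conditions(), dead_space_ml = 4.6,
                   weight_kg = NA_real_, tracer_fraction = 0.04,
                   frc_true_ml = NA_real_)
  meta <- utils::modifyList(defaults, meta)
  structure(list(time = as.numeric(time), flow = as.numeric(flow),
                 molar_mass = as.numeric(molar_mass),
                 sampling_rate = sampling_rate, meta = meta),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples @ %g Hz (%.1f s), MM %.2f-%.2f g/mol\n",
    length(x$time), x$sampling_rate, diff(range(x$time)),
    min(x$molar_mass), max(x$molar_mass)))
  invisible(x)
}

.header_keys <- c("sampling_rate_hz", "dead_space_ml", "weight_kg",
                  "tracer_fraction", "frc_true_ml", "temperature_k",
                  "pressure_pa", "relative_humidity", "body_temperature_k",
                  "flow_sign")

#' Write a recording to the open CSV/TSV dialect
#'
#' The file starts with a `# key: value` comment block carrying the metadata,
#' followed by a header line and the columns `time_s`, `flow_lps`,
#' `molar_mass_gmol`.
#'
#' @param rec A `raw_recording`.
#' @param path Output path.
#' @param sep Field separator: `","` (CSV, default) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  m <- rec$meta
  hdr <- c(
    sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate),
    sprintf("# dead_space_ml: %.10g", m$dead_space_ml),
    sprintf("# weight_kg: %.10g", m$weight_kg),
    sprintf("# tracer_fraction: %.10g", m$tracer_fraction),
    sprintf("# frc_true_ml: %.10g", m$frc_true_ml),
    sprintf("# temperature_k: %.10g", m$ambient$temperature),
    sprintf("# pressure_pa: %.10g", m$ambient$pressure),
    sprintf("# relative_humidity: %.10g", m$ambient$relative_humidity),
    sprintf("# body_temperature_k: %.10g", m$ambient$body_temperature),
    "# flow_sign: inspiration_positive"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("time_s", "flow_lps", "molar_mass_gmol"), collapse = sep),
             con)
  df <- data.frame(rec$time, rec$flow, rec$molar_mass)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a recording from the open CSV/TSV dialect
#'
#' @param path Path to a file written in the dialect of [write_recording()].
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab from
#'   the column header line.
#' @return A validated `raw_recording`. If the header declares
#'   `flow_sign: expiration_positive`, the flow sign is flipped on read so the
#'   in-memory convention is always inspiration-positive.
#' @export
read_recording <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_mbw(paste0("file not found: ", path),
                                   "mbw_parse_error")
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta_raw <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) meta_raw[[kv[2]]] <- trimws(kv[3])
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_mbw("no data rows", "mbw_parse_error")
  if (is.null(sep)) sep <- if (grepl("\t", body[1])) "\t" else ","
  cols <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  need <- c("time_s", "flow_lps", "molar_mass_gmol")
  miss <- setdiff(need, trimws(cols))
  if (length(miss))
    stop_mbw(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "mbw_parse_error")
  df <- utils::read.table(text = body[-1], sep = sep, col.names = trimws(cols),
                          colClasses = "numeric")
  num <- function(key, default = NA_real_) {
    v <- meta_raw[[key]]
    if (is.null(v)) default else suppressWarnings(as.numeric(v))
  }
  sr <- num("sampling_rate_hz")
  if (is.na(sr)) sr <- 1 / stats::median(diff(df$time_s))
  amb <- ambient_conditions(
    temperature = num("temperature_k", 296.15),
    pressure = num("pressure_pa", 101325),
    relative_humidity = num("relative_humidity", 0.3),
    body_temperature = num("body_temperature_k", 310.15))
  flow <- df$flow_lps
  if (identical(meta_raw[["flow_sign"]], "expiration_positive")) flow <- -flow
  raw_recording(df$time_s, flow, df$molar_mass_gmol, sampling_rate = sr,
                meta = list(ambient = amb,
                            dead_space_ml = num("dead_space_ml", 4.6),
                            weight_kg = num("weight_kg"),
                            tracer_fraction = num("tracer_fraction", 0.04),
                            frc_true_ml = num("frc_true_ml")))
}
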