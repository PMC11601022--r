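# Outcome report I/O: versioned JSON documents plus a structural validator
# driven by the shipped schema file.

#' Write an outcomes report to JSON
#'
#' @param outcomes An `mbw_outcomes` (or the `outcomes` element of an
#'   `mbw_result`).
#' @param path Output path.
#' @param config Optional `mbw_config` echoed into the document.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path, config = NULL) {
  doc <- list(
    schema = "sf6mbw-outcomes-1",
    software_version = as.character(utils::packageVersion("sf6mbw")),
    frc_ml = outcomes$frc_ml,
    cev_ml = outcomes$cev_ml,
    lci_to = outcomes$lci_to,
    eot_breath = outcomes$eot_breath,
    breath_count = outcomes$breath_count,
    et_initial = outcomes$et_initial,
    et_final = outcomes$et_final,
    et_sf6 = outcomes$et_sf6,
    dead_space_ml = outcomes$dead_space_ml,
    clamped_fraction = outcomes$clamped_fraction,
    washin_complete = outcomes$washin_complete,
    flags = as.list(outcomes$flags),
    config = if (!is.null(config)) unclass(config) else NULL
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an outcomes report from JSON
#'
#' @param path Path to a report written by [write_outcomes()].
#' @return An `mbw_outcomes`.
#' @export
read_outcomes <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_outcomes_report(doc)
  structure(list(
    frc_ml = doc$frc_ml, cev_ml = doc$cev_ml, lci_to = doc$lci_to,
    eot_breath = doc$eot_breath, breath_count = doc$breath_count,
    et_initial = doc$et_initial, et_final = doc$et_final,
    et_sf6 = as.numeric(doc$et_sf6),
    dead_space_ml = doc$dead_space_ml,
    clamped_fraction = doc$clamped_fraction,
    washin_complete = doc$washin_complete,
    flags = as.character(unlist(doc$flags))), class = "mbw_outcomes")
}

#' Validate an outcomes report against the shipped schema
#'
#' Structural validation (required fields and primitive types) driven by the
#' JSON schema file shipped at `inst/extdata/outcomes-schema.json`.
#'
#' @param doc A parsed report (list) or a path to a JSON file.
#' @return `TRUE` invisibly; raises a classed error on violation.
#' @export
validate_outcomes_report <- function(doc) {
  if (is.character(doc)) doc <- jsonlite::read_json(doc, simplifyVector = TRUE)
  schema_path <- system.file("extdata", "outcomes-schema.json",
                             package = "sf6mbw")
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  for (field in names(schema$properties)) {
    req <- field %in% schema$required
    present <- !is.null(doc[[field]])
    if (req && !present)
      stop_mbw(paste0("outcomes report missing required field: ", field),
               "mbw_schema_violation")
    if (!present) next
    type <- schema$properties[[field]]$type
    ok <- switch(type,
                 number = is.numeric(doc[[field]]) && length(doc[[field]]) == 1,
                 integer = is.numeric(doc[[field]]) && length(doc[[field]]) == 1,
                 boolean = is.logical(doc[[field]]) && length(doc[[field]]) == 1,
                 string = is.character(doc[[field]]) && length(doc[[field]]) == 1,
                 array = is.vector(doc[[field]]) || is.list(doc[[field]]),
                 object = is.list(doc[[field]]),
                 TRUE)
    if (!ok)
      stop_mbw(sprintf("outcomes report field '%s' is not of type %s",
                       field, type), "mbw_schema_violation")
  }
  if (abs(doc$lci_to - doc$cev_ml / doc$frc_ml) > 1e-9 * max(1, doc$lci_to))
    stop_mbw("outcomes report inconsistent: lci_to != cev_ml / frc_ml",
             "mbw_schema_violation")
  invisible(TRUE)
}
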