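## Result tables and solution export. Tables carry a schema-version comment
## line; numbers are written with enough digits to round-trip exactly.

RESULTS_SCHEMA_VERSION <- 1L

#' Write a result table as CSV with a schema header
#'
#' @param tab a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tcosa_results_schema %d", RESULTS_SCHEMA_VERSION), con)
  fmt <- tab
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- formatC(fmt[[j]], digits = 17, format = "g")
  utils::write.csv(fmt, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [writeResultsTable()]
#'
#' @param path path to the CSV.
#' @return a data.frame.
#' @export
readResultsTable <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# tcosa_results_schema", first))
    stop("not a tcosa results table: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export a driving-force solution as JSON
#'
#' @param sol an [MdfSolution-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSolutionJson <- function(sol, path) {
  doc <- list(schema_version = RESULTS_SCHEMA_VERSION,
              objective = sol@objective,
              status = sol@status,
              B = sol@B,
              B_sub = if (length(sol@BSub)) sol@BSub else NULL,
              fluxes = as.list(sol@fluxes),
              log_concentrations = as.list(sol@logConc),
              driving_forces = as.list(sol@drivingForces),
              active_set = as.list(sol@activeSet))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a solution written by [writeSolutionJson()]
#'
#' @param path path to the JSON file.
#' @return an [MdfSolution-class].
#' @export
readSolutionJson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MdfSolution",
      B = as.numeric(doc$B),
      BSub = if (is.null(doc$B_sub)) numeric(0) else as.numeric(doc$B_sub),
      fluxes = unlist(doc$fluxes) %||% numeric(0),
      logConc = unlist(doc$log_concentrations) %||% numeric(0),
      z = numeric(0),
      drivingForces = unlist(doc$driving_forces) %||% numeric(0),
      status = doc$status, activeSet = as.character(doc$active_set %||% character(0)),
      objective = doc$objective)
}
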