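## Toy-JSON model dialect (schema version 1):
## {
##   "schema_version": 1,
##   "metabolites": [{"id", "external", "c_min", "c_max", "compartment"?}],
##   "reactions":   [{"id", "stoich": {"<met>": coef}, "lb", "ub",
##                    "dG0"?, "dG0_tag"?, "thermo_active"?}],
##   "objective": "<reaction id>",
##   "exchanges": [...]?,           # auto-detected when absent
##   "fixed_unit_species": [...]?,
##   "temperature_K": 298.15?
## }
## The canonical test format of the package; SBML support is exercised by
## exporting toys and re-importing them.

TOY_SCHEMA_VERSION <- 1L

#' Read a model in the toy-JSON dialect
#'
#' @param path path to a toy-JSON file.
#' @return list with elements `model` ([MetabolicModel-class]), `thermo`
#'   ([ThermoAnnotation-class]) and `thermoActive` (named logical).
#' @export
readToyModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("toy-JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  for (el in c("metabolites", "reactions"))
    if (is.null(doc[[el]])) stop("toy-JSON format error: missing element '", el, "'")
  if (is.null(doc$objective)) stop("configuration error: no objective reaction defined")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id %||% stop("metabolite without id"), ""),
    external = vapply(doc$metabolites, function(m) isTRUE(m$external), NA),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "c", ""),
    stringsAsFactors = FALSE)
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("toy-JSON format error: reaction without id")
    if (is.null(r$stoich) || !length(r$stoich))
      stop("toy-JSON format error: reaction '", r$id, "' has no stoichiometry")
    list(stoich = unlist(r$stoich), lb = r$lb %||% 0, ub = r$ub %||% 1000,
         reversible = if (is.null(r$reversible)) NULL else isTRUE(r$reversible))
  })
  names(rxns) <- vapply(doc$reactions, `[[`, "", "id")
  exch <- if (!is.null(doc$exchanges)) unlist(doc$exchanges) else NULL
  model <- metabolicModel(mets, rxns, objective = doc$objective, exchanges = exch)

  cMin <- vapply(doc$metabolites, function(m) as.numeric(m$c_min %||% DEFAULT_C_MIN), 0)
  cMax <- vapply(doc$metabolites, function(m) as.numeric(m$c_max %||% DEFAULT_C_MAX), 0)
  names(cMin) <- names(cMax) <- mets$id
  dg <- numeric(0); tags <- character(0)
  thermoActive <- stats::setNames(rep(TRUE, length(rxns)), names(rxns))
  for (r in doc$reactions) {
    if (!is.null(r$dG0)) {
      dg[r$id] <- as.numeric(r$dG0)
      tags[r$id] <- r$dG0_tag %||% "computed"
    } else if (!is.null(r$dG0_tag)) tags[r$id] <- r$dG0_tag
    if (!is.null(r$thermo_active)) thermoActive[r$id] <- isTRUE(r$thermo_active)
  }
  thermo <- thermoAnnotation(
    dG0 = dg, dG0Tag = if (length(tags)) tags else NULL,
    cMin = cMin, cMax = cMax,
    temperature = as.numeric(doc$temperature_K %||% DEFAULT_TEMPERATURE_K),
    fixedUnitSpecies = as.character(unlist(doc$fixed_unit_species %||% list())))
  list(model = model, thermo = thermo, thermoActive = thermoActive)
}

#' Write a model in the toy-JSON dialect
#'
#' @param model a [MetabolicModel-class].
#' @param thermo a [ThermoAnnotation-class] (optional).
#' @param path output path.
#' @param thermoActive optional named logical; reactions flagged `FALSE` are
#'   written with `"thermo_active": false`.
#' @return `path`, invisibly.
#' @export
writeToyModel <- function(model, path, thermo = NULL, thermoActive = NULL) {
  mets <- lapply(seq_along(model@metId), function(i) {
    m <- list(id = model@metId[i], external = model@metExternal[i],
              compartment = model@metCompartment[i])
    if (!is.null(thermo) && model@metId[i] %in% names(thermo@cMin)) {
      m$c_min <- unname(thermo@cMin[model@metId[i]])
      m$c_max <- unname(thermo@cMax[model@metId[i]])
    }
    m
  })
  rxns <- lapply(seq_along(model@rxnId), function(j) {
    id <- model@rxnId[j]
    r <- list(id = id, stoich = as.list(model@stoich[[j]]),
              lb = unname(model@lb[j]), ub = unname(model@ub[j]),
              reversible = unname(model@reversible[j]))
    if (!is.null(thermo)) {
      if (id %in% names(thermo@dG0)) r$dG0 <- unname(thermo@dG0[id])
      if (id %in% names(thermo@dG0Tag)) r$dG0_tag <- unname(thermo@dG0Tag[id])
    }
    if (!is.null(thermoActive) && id %in% names(thermoActive) && !thermoActive[[id]])
      r$thermo_active <- FALSE
    r
  })
  doc <- list(schema_version = TOY_SCHEMA_VERSION, metabolites = mets,
              reactions = rxns, objective = model@objectiveReaction,
              exchanges = as.list(model@exchangeReactions))
  if (!is.null(thermo)) {
    doc$fixed_unit_species <- as.list(thermo@fixedUnitSpecies)
    doc$temperature_K <- thermo@temperature
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a metabolic model from file
#'
#' Front door over the format-specific readers.
#'
#' @param path file path.
#' @param dialect `"toy"` (toy-JSON) or `"sbml"`; guessed from the file
#'   extension when missing.
#' @return a [MetabolicModel-class].
#' @export
loadModel <- function(path, dialect = c("auto", "toy", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "toy"
  switch(dialect,
         toy = readToyModel(path)$model,
         sbml = readSbmlModel(path)$model)
}
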