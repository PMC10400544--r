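## Minimal SBML Level 3 (+ FBC v2) reader/writer built on xml2. Covers the
## subset of SBML used by constraint-based models (species with boundary
## flags, reactions with stoichiometries and FBC flux bounds, an active FBC
## objective), which is sufficient for BiGG-style genome-scale models and for
## round-tripping the package's own exports. `M_`/`R_` id prefixes are
## stripped on read and re-added on write.

sbmlAttr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- at[names(at) %in% c(name, paste0("fbc:", name))]
  if (length(hit)) unname(hit[1]) else NA_character_
}

stripSbmlId <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

#' Read a metabolic model from SBML L3 (FBC)
#'
#' @param path path to an SBML file.
#' @return list with elements `model` ([MetabolicModel-class]) and `notes`
#'   (provenance annotations found in the file, if any).
#' @export
readSbmlModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path, "': ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(spNodes)) stop("SBML format error: no species found")
  mets <- data.frame(
    id = stripSbmlId(xml2::xml_attr(spNodes, "id"), "M"),
    external = tolower(xml2::xml_attr(spNodes, "boundaryCondition")) %in% "true",
    compartment = xml2::xml_attr(spNodes, "compartment"),
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pv <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))

  rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxNodes)) stop("SBML format error: no reactions found")
  rxns <- lapply(rxNodes, function(rn) {
    id <- stripSbmlId(xml2::xml_attr(rn, "id"), "R")
    sref <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rn, xp)
      if (!length(nodes)) return(numeric(0))
      s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      s[is.na(s)] <- 1
      stats::setNames(sign * s, stripSbmlId(xml2::xml_attr(nodes, "species"), "M"))
    }
    st <- c(sref("./listOfReactants/speciesReference", -1),
            sref("./listOfProducts/speciesReference", +1))
    if (!length(st)) stop("SBML format error: reaction '", id, "' has no participants")
    ## collapse species occurring on both sides
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[st != 0]
    rev <- tolower(xml2::xml_attr(rn, "reversible")) %in% "true"
    lbId <- sbmlAttr(rn, "lowerFluxBound"); ubId <- sbmlAttr(rn, "upperFluxBound")
    lb <- if (!is.na(lbId) && lbId %in% names(pv)) pv[[lbId]] else if (rev) -1000 else 0
    ub <- if (!is.na(ubId) && ubId %in% names(pv)) pv[[ubId]] else 1000
    list(id = id, stoich = st, lb = lb, ub = ub, reversible = rev || lb < 0)
  })
  ids <- vapply(rxns, `[[`, "", "id")
  names(rxns) <- ids

  ## FBC elements keep their own namespace even after stripping; match by
  ## local name
  objNode <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (inherits(objNode, "xml_missing"))
    stop("configuration error: SBML file declares no FBC objective")
  objective <- stripSbmlId(sbmlAttr(objNode, "reaction"), "R")

  notesNode <- xml2::xml_find_first(doc, ".//model/notes")
  notes <- if (inherits(notesNode, "xml_missing")) character(0)
           else xml2::xml_text(notesNode)
  model <- metabolicModel(mets, rxns, objective = objective)
  list(model = model, notes = notes)
}

#' Write a metabolic model to SBML L3 (FBC)
#'
#' @param model a [MetabolicModel-class].
#' @param path output path.
#' @param notes optional character scalar written into the model's `notes`
#'   element (used to carry reconfiguration provenance).
#' @return `path`, invisibly.
#' @export
writeSbmlModel <- function(model, path, notes = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="tcosa_model" fbc:strict="true">')
  if (!is.null(notes))
    out <- c(out, "    <notes><body xmlns=\"http://www.w3.org/1999/xhtml\"><p>",
             esc(notes), "</p></body></notes>")
  comps <- unique(model@metCompartment)
  out <- c(out, "    <listOfCompartments>",
           sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
           "    </listOfCompartments>", "    <listOfSpecies>")
  out <- c(out, sprintf(
    '      <species id="M_%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
    sanitize(model@metId), esc(model@metCompartment),
    ifelse(model@metExternal, "true", "false")),
    "    </listOfSpecies>", "    <listOfParameters>")
  rid <- sanitize(model@rxnId)
  out <- c(out,
    sprintf('      <parameter id="lb_%s" value="%.17g" constant="true"/>', rid, model@lb),
    sprintf('      <parameter id="ub_%s" value="%.17g" constant="true"/>', rid, model@ub),
    "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_along(model@rxnId)) {
    s <- model@stoich[[j]]
    sub <- s[s < 0]; prod <- s[s > 0]
    out <- c(out, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
      rid[j], ifelse(model@reversible[j], "true", "false"), rid[j], rid[j]))
    if (length(sub))
      out <- c(out, "        <listOfReactants>",
               sprintf('          <speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
                       sanitize(names(sub)), -unname(sub)),
               "        </listOfReactants>")
    if (length(prod))
      out <- c(out, "        <listOfProducts>",
               sprintf('          <speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
                       sanitize(names(prod)), unname(prod)),
               "        </listOfProducts>")
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            sanitize(model@objectiveReaction)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}
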