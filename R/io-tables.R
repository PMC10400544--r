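## Flat-file annotation tables.

#' Read a standard-Gibbs-energy annotation table
#'
#' TSV with columns `reaction_id`, `dG0_kJ_mol` and optionally `source_tag`.
#' Empty `dG0_kJ_mol` cells denote reactions without a value (the
#' reconfiguration pipeline later assigns the sentinel or an imputed median).
#'
#' @param path path to the TSV file.
#' @return list with `dG0` (named numeric) and `tags` (named character).
#' @export
readDeltaGTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "dG0_kJ_mol")
  if (!all(need %in% names(tab)))
    stop("dG table format error: need columns ", paste(need, collapse = ", "))
  keep <- !is.na(tab$dG0_kJ_mol)
  dg <- stats::setNames(as.numeric(tab$dG0_kJ_mol[keep]), tab$reaction_id[keep])
  tags <- if ("source_tag" %in% names(tab))
    stats::setNames(as.character(tab$source_tag[keep]), tab$reaction_id[keep])
  else stats::setNames(rep("computed", sum(keep)), tab$reaction_id[keep])
  list(dG0 = dg, tags = tags)
}

#' Write a standard-Gibbs-energy annotation table
#'
#' @param thermo a [ThermoAnnotation-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDeltaGTable <- function(thermo, path) {
  ids <- union(names(thermo@dG0), names(thermo@dG0Tag))
  tab <- data.frame(reaction_id = ids,
                    dG0_kJ_mol = ifelse(ids %in% names(thermo@dG0),
                                        thermo@dG0[ids], NA_real_),
                    source_tag = ifelse(ids %in% names(thermo@dG0Tag),
                                        thermo@dG0Tag[ids], NA_character_),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
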