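## Standard-Gibbs-energy assignment rules.

#' Convert a redox-potential difference to a Gibbs energy shift
#'
#' Returns `-n * F * dE` with the Faraday constant `F = 96.485 kJ V^-1 mol^-1`
#' and `dE` given in millivolts. For the NAD(P)H/NAD(P)+ couples at
#' `dE = -320 mV` and `n = 2` this is the 61.75 kJ/mol standard
#' formation-energy difference between reduced and oxidized cofactor.
#'
#' @param dE_mV potential difference in millivolts.
#' @param nElectrons number of transferred electrons (>= 1).
#' @return Gibbs energy shift in kJ/mol.
#' @examples
#' redoxPotentialToDGShift(-320, 2)  # 61.75 kJ/mol
#' @export
redoxPotentialToDGShift <- function(dE_mV, nElectrons = 2) {
  stopifnot(nElectrons >= 1)
  -nElectrons * FARADAY_KJ_PER_V * (dE_mV / 1000)
}

## A reaction is a pure transporter when its reactant multiset equals its
## product multiset up to the compartment suffix (the trailing "_<comp>"
## token), i.e. no chemical conversion takes place. Coupled translocators
## (ATP synthase etc.) do not satisfy this and keep their computed values.
isPureTransporter <- function(stoich) {
  strip <- function(x) sub("_[^_]+$", "", x)
  sub <- stoich[stoich < 0]; prod <- stoich[stoich > 0]
  if (!length(sub) || !length(prod)) return(FALSE)
  a <- sort(paste(strip(names(sub)), -unname(sub)))
  b <- sort(paste(strip(names(prod)), unname(prod)))
  length(a) == length(b) && all(a == b)
}

#' Assign default standard Gibbs energies
#'
#' Applies the defaulting rules: exchange and growth pseudo-reactions become
#' `unconstrained` (no value, excluded from driving-force constraints); pure
#' transporters and reactions without a computed value receive a low sentinel
#' (default -100 kJ/mol, tag `default_sentinel`) that imposes only minimal
#' constraints; computed entries pass through untouched.
#'
#' @param model a [MetabolicModel-class].
#' @param thermo a [ThermoAnnotation-class] holding the computed entries.
#' @param sentinel sentinel value in kJ/mol.
#' @return an updated [ThermoAnnotation-class].
#' @export
assignDefaultDG <- function(model, thermo, sentinel = DEFAULT_DG_SENTINEL) {
  dg <- thermo@dG0
  tags <- thermo@dG0Tag
  unconstrained <- union(model@exchangeReactions, model@objectiveReaction)
  for (j in seq_along(model@rxnId)) {
    id <- model@rxnId[j]
    if (id %in% unconstrained) {
      dg <- dg[setdiff(names(dg), id)]
      tags[id] <- "unconstrained"
    } else if (isPureTransporter(model@stoich[[j]]) || !(id %in% names(dg))) {
      dg[id] <- sentinel
      tags[id] <- "default_sentinel"
    } else if (!(id %in% names(tags))) {
      tags[id] <- "computed"
    }
  }
  methods::initialize(thermo, dG0 = dg, dG0Tag = tags)
}

## Cofactor species appearing as substrates (negative coefficient) of a
## reaction, restricted to the given pools.
cofactorSubstrates <- function(stoich, pools) {
  species <- unlist(lapply(pools, function(p) p[c("ox", "red")]), use.names = FALSE)
  sub <- names(stoich)[stoich < 0]
  intersect(sub, species)
}

#' Impute missing Gibbs energies of redox reactions from per-species medians
#'
#' For every cofactor-using reaction without a computed value, assigns the
#' median standard Gibbs energy over all computed-value reactions that consume
#' the same cofactor species (substrate side), tagged `median_imputed`. When a
#' reaction consumes several cofactor species (dual-pool reactions), the mean
#' of the applicable per-species medians is used. Operates on the pre-split
#' reaction set so that forward/backward copies are not double counted.
#'
#' @param model a [MetabolicModel-class].
#' @param thermo a [ThermoAnnotation-class] (after [assignDefaultDG()]).
#' @param cofactors a [CofactorSpec-class].
#' @return an updated [ThermoAnnotation-class].
#' @export
imputeRedoxMedians <- function(model, thermo, cofactors) {
  pools <- cofactors@pools
  dg <- thermo@dG0
  tags <- thermo@dG0Tag
  species <- unlist(lapply(pools, function(p) p[c("ox", "red")]), use.names = FALSE)

  computedIds <- names(tags)[tags == "computed"]
  medians <- stats::setNames(rep(NA_real_, length(species)), species)
  for (s in species) {
    consuming <- model@rxnId[vapply(model@stoich, function(st)
      s %in% names(st) && st[[s]] < 0, NA)]
    consuming <- intersect(consuming, computedIds)
    if (length(consuming)) medians[s] <- stats::median(dg[consuming])
  }

  for (j in seq_along(model@rxnId)) {
    id <- model@rxnId[j]
    st <- model@stoich[[j]]
    if (!any(species %in% names(st))) next
    tag <- if (id %in% names(tags)) tags[[id]] else NA_character_
    if (identical(tag, "computed") || identical(tag, "unconstrained")) next
    used <- cofactorSubstrates(st, pools)
    if (!length(used)) next
    if (anyNA(medians[used]))
      stop("imputation error: no computed dG0 available for cofactor species ",
           paste(used[is.na(medians[used])], collapse = ", "))
    dg[id] <- mean(medians[used])
    tags[id] <- "median_imputed"
  }
  methods::initialize(thermo, dG0 = dg, dG0Tag = tags)
}
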