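## Deterministic toy-network generation. The generator emulates the canonical
## small-network situation of the method: a linear catabolic backbone fed by
## an external substrate, optional redox-coupled steps (NAD+ reduction in
## catabolism, NADPH consumption in anabolism), lumped cofactor-regeneration
## reactions, and a biomass-like sink with cofactor demands.

#' Specification of a generated toy network
#'
#' @param nSteps number of linear-pathway steps (substrate to product).
#' @param stepDG0 numeric standard Gibbs energies per step (kJ/mol), recycled
#'   to length `nSteps`.
#' @param stepRedox per-step cofactor coupling: `NA` (none), `"NAD_red"`
#'   (reduces NAD+ to NADH), `"NADP_red"`, `"NAD_ox"` (consumes NADH),
#'   `"NADP_ox"` (consumes NADPH).
#' @param stepReversible logical per step.
#' @param boundary molar concentration bounds c(cMin, cMax) applied to all
#'   metabolites.
#' @param biomass `NULL` (a plain product sink is the objective) or a list
#'   with `nadph` and `nad` demands per unit growth; the biomass reaction then
#'   uses both pools and is never duplicated.
#' @param regenDG0 named Gibbs energies of the lumped regeneration reactions
#'   (kJ/mol, in the thermodynamically favorable written direction).
#' @param stepUb common flux upper bound (mmol gDW^-1 h^-1).
#' @param seed stored for provenance of randomized specs.
#' @return a `toyNetworkSpec` list.
#' @export
toyNetworkSpec <- function(nSteps, stepDG0 = 0, stepRedox = NULL,
                           stepReversible = NULL,
                           boundary = c(DEFAULT_C_MIN, DEFAULT_C_MAX),
                           biomass = NULL,
                           regenDG0 = c(NAD = -40, NADP = -30),
                           stepUb = 10, seed = NA_integer_) {
  stopifnot(nSteps >= 1)
  spec <- list(
    nSteps = as.integer(nSteps),
    stepDG0 = rep_len(as.numeric(stepDG0), nSteps),
    stepRedox = rep_len(if (is.null(stepRedox)) NA_character_ else stepRedox, nSteps),
    stepReversible = rep_len(if (is.null(stepReversible)) FALSE else stepReversible, nSteps),
    boundary = boundary, biomass = biomass, regenDG0 = regenDG0,
    stepUb = stepUb, seed = seed)
  ok <- is.na(spec$stepRedox) |
    spec$stepRedox %in% c("NAD_red", "NADP_red", "NAD_ox", "NADP_ox")
  if (!all(ok))
    stop("configuration error: unknown redox tag(s): ",
         paste(unique(spec$stepRedox[!ok]), collapse = ", "))
  if (!is.null(biomass) &&
      is.null(biomass[["nadph"]]) && is.null(biomass[["nad"]]))
    stop("configuration error: biomass demands must name nadph and/or nad")
  class(spec) <- "toyNetworkSpec"
  spec
}

#' Generate a toy metabolic network with known thermodynamics
#'
#' Deterministic for a given spec: builds the linear pathway, attaches the
#' requested cofactor couplings, adds lumped regeneration reactions so that
#' every cofactor pool can be balanced at steady state, and installs either a
#' plain product sink or a cofactor-consuming biomass reaction as objective.
#'
#' @param spec a [toyNetworkSpec()].
#' @return list with `model` ([MetabolicModel-class]), `thermo`
#'   ([ThermoAnnotation-class]) and `cofactors` ([CofactorSpec-class]).
#' @export
generateToy <- function(spec) {
  stopifnot(inherits(spec, "toyNetworkSpec"))
  n <- spec$nSteps
  pools <- defaultCofactors()@pools
  ## [[ ]] access throughout: $ would partial-match "nad" onto "nadph"
  usesNAD <- any(spec$stepRedox %in% c("NAD_red", "NAD_ox")) ||
    (!is.null(spec$biomass[["nad"]]) && spec$biomass[["nad"]] > 0)
  usesNADP <- any(spec$stepRedox %in% c("NADP_red", "NADP_ox")) ||
    (!is.null(spec$biomass[["nadph"]]) && spec$biomass[["nadph"]] > 0)

  chainMets <- c("S_e", paste0("M", seq_len(n - 1)), "P")[seq_len(n + 1)]
  if (n == 1) chainMets <- c("S_e", "P")
  metIds <- chainMets
  ## both pools' species whenever any redox chemistry is requested, so that
  ## cofactor duplication always has a substitution target
  if (usesNAD || usesNADP)
    metIds <- c(metIds, unlist(lapply(pools[c("NAD", "NADP")],
                                      function(p) p[c("ox", "red")]),
                               use.names = FALSE))
  mets <- data.frame(id = metIds, external = metIds == "S_e",
                     compartment = ifelse(grepl("_e$", metIds), "e", "c"),
                     stringsAsFactors = FALSE)

  rxns <- list()
  netRed <- c(NAD = 0, NADP = 0)  # reduced-species production per unit flux
  for (i in seq_len(n)) {
    st <- stats::setNames(c(-1, 1), c(chainMets[i], chainMets[i + 1]))
    tag <- spec$stepRedox[i]
    if (!is.na(tag)) {
      pool <- sub("_.*$", "", tag)
      pp <- pools[[pool]]
      if (grepl("_red$", tag)) {  # M + ox -> M' + red
        st[pp[["ox"]]] <- -1; st[pp[["red"]]] <- 1
        netRed[pool] <- netRed[pool] + 1
      } else {                    # M + red -> M' + ox
        st[pp[["red"]]] <- -1; st[pp[["ox"]]] <- 1
        netRed[pool] <- netRed[pool] - 1
      }
    }
    rev <- spec$stepReversible[i]
    rxns[[paste0("R", i)]] <- list(stoich = st,
                                   lb = if (rev) -spec$stepUb else 0,
                                   ub = spec$stepUb, reversible = rev)
  }

  dg <- stats::setNames(spec$stepDG0, paste0("R", seq_len(n)))

  if (!is.null(spec$biomass)) {
    dn <- spec$biomass[["nad"]] %||% 0
    dp <- spec$biomass[["nadph"]] %||% 0
    st <- c(P = -1)
    if (dn > 0) { st[pools$NAD[["ox"]]] <- -dn; st[pools$NAD[["red"]]] <- dn }
    if (dp > 0) { st[pools$NADP[["red"]]] <- -dp; st[pools$NADP[["ox"]]] <- dp }
    rxns[["BM"]] <- list(stoich = st, lb = 0, ub = spec$stepUb, reversible = FALSE)
    netRed["NAD"] <- netRed["NAD"] + dn
    netRed["NADP"] <- netRed["NADP"] - dp
    objective <- "BM"
  } else {
    rxns[["SINK_P"]] <- list(stoich = c(P = -1), lb = 0, ub = spec$stepUb,
                             reversible = FALSE)
    objective <- "SINK_P"
  }

  ## lumped regeneration so each touched pool can close at steady state
  for (pool in c("NAD", "NADP")) {
    if (!(if (pool == "NAD") usesNAD else usesNADP)) next
    pp <- pools[[pool]]
    if (netRed[pool] >= 0) {      # net reduction -> oxidize back
      id <- paste0("ROX_", pool)
      st <- stats::setNames(c(-1, 1), c(pp[["red"]], pp[["ox"]]))
    } else {                      # net oxidation -> reduce back
      id <- paste0("RRED_", pool)
      st <- stats::setNames(c(-1, 1), c(pp[["ox"]], pp[["red"]]))
    }
    rxns[[id]] <- list(stoich = st, lb = 0, ub = spec$stepUb, reversible = FALSE)
    dg[id] <- unname(spec$regenDG0[pool])
  }

  model <- metabolicModel(mets, rxns, objective = objective, exchanges = character(0))
  cMin <- stats::setNames(rep(spec$boundary[1], nrow(mets)), mets$id)
  cMax <- stats::setNames(rep(spec$boundary[2], nrow(mets)), mets$id)
  thermo <- thermoAnnotation(dG0 = dg, cMin = cMin, cMax = cMax)
  list(model = model, thermo = thermo, cofactors = defaultCofactors())
}

#' Random toy-network spec for property-style test suites
#'
#' Draws a small random pathway (2-4 steps, up to two redox couplings on
#' distinct pools, at most one reversible non-redox step, step Gibbs energies
#' uniform in [-30, 5]) deterministically from the seed. The resulting
#' networks stay within the exhaustive oracle's size guard after splitting
#' and duplication.
#'
#' @param seed integer seed.
#' @return a [toyNetworkSpec()].
#' @export
toyRandomSpec <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  n <- sample(2:4, 1)
  redox <- rep(NA_character_, n)
  kRedox <- sample(0:min(2, n), 1)
  if (kRedox >= 1) redox[sample(n, 1)] <- sample(c("NAD_red", "NAD_ox"), 1)
  if (kRedox == 2) {
    free <- which(is.na(redox))
    redox[free[sample(length(free), 1)]] <- sample(c("NADP_ox", "NADP_red"), 1)
  }
  rev <- rep(FALSE, n)
  nonRedox <- which(is.na(redox))
  if (length(nonRedox) && stats::runif(1) < 0.5)
    rev[nonRedox[sample(length(nonRedox), 1)]] <- TRUE
  toyNetworkSpec(n, stepDG0 = round(stats::runif(n, -30, 5), 2),
                 stepRedox = redox, stepReversible = rev, seed = as.integer(seed))
}

#' Build a reconfigured toy model in one call
#'
#' [generateToy()] followed by the reconfiguration pipeline
#' ([buildTcosaModel()]).
#'
#' @param spec a [toyNetworkSpec()].
#' @param ... passed to [buildTcosaModel()].
#' @return a [TcosaModel-class].
#' @export
buildToyTcosa <- function(spec, ...) {
  toy <- generateToy(spec)
  buildTcosaModel(toy$model, toy$thermo, toy$cofactors, ...)
}

#' The packaged catabolic/anabolic fixture
#'
#' A wild-type-like pathway used across the package's examples and tests: a
#' catabolic NAD+-reducing step, an anabolic NADPH-consuming step with a
#' markedly positive standard Gibbs energy, lumped NADH oxidation and NADPH
#' regeneration, and a biomass sink consuming both pools. Its cofactor-ratio
#' analysis reproduces the qualitative in vivo trend of a more oxidized
#' NAD(H) than NADP(H) pool.
#'
#' @return a [toyNetworkSpec()].
#' @export
toyRedoxFixtureSpec <- function() {
  toyNetworkSpec(3,
                 stepDG0 = c(-10, -20, 15),
                 stepRedox = c(NA, "NAD_red", "NADP_ox"),
                 biomass = list(nadph = 0.05, nad = 0.05))
}
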