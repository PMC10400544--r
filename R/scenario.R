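## Specificity scenarios, growth-rate discretization, random sampling,
## activity census and the three-cofactor comparison.

## originals of all duplicated redox reactions, with their wild-type pool
redoxOriginals <- function(tc) {
  prov <- tc@provenance
  orig <- prov[!is.na(prov$role) & prov$role == "ORIGINAL", c("original", "pool")]
  orig <- unique(orig)
  stats::setNames(orig$pool, orig$original)
}

#' Wild-type specificity assignment
#'
#' Each duplicated redox reaction keeps its original cofactor pool; all
#' swapped variants are blocked.
#'
#' @param tcosa a [TcosaModel-class].
#' @return a [SpecificityAssignment-class].
#' @export
wildTypeAssignment <- function(tcosa) {
  new("SpecificityAssignment", choices = redoxOriginals(tcosa),
      scenario = "wild_type")
}

#' Flexible specificity assignment
#'
#' All cofactor variants stay open; variant-group exclusivity alone decides
#' which one is used, so any optimization may pick specificities freely.
#'
#' @param tcosa a [TcosaModel-class].
#' @return a [SpecificityAssignment-class].
#' @export
flexibleAssignment <- function(tcosa) {
  ch <- redoxOriginals(tcosa)
  ch[] <- "flexible"
  new("SpecificityAssignment", choices = ch, scenario = "flexible")
}

#' Single-cofactor-pool assignment
#'
#' Every redox reaction is forced onto one pool (NAD(H) by default); the
#' growth reaction's consumption of the other pool is rerouted to the single
#' pool and the remaining dual-cofactor reactions are blocked, since with one
#' pool they would couple the pool to itself.
#'
#' @param tcosa a [TcosaModel-class].
#' @param pool name of the remaining pool.
#' @return a [SpecificityAssignment-class].
#' @export
singlePoolAssignment <- function(tcosa, pool = "NAD") {
  ch <- redoxOriginals(tcosa)
  ch[] <- pool
  new("SpecificityAssignment", choices = ch, scenario = "single_pool")
}

#' Apply a specificity assignment to the model
#'
#' Blocks the cofactor variants excluded by the assignment (bounds fixed to
#' zero). In the single-pool scenario the objective reaction's stoichiometric
#' coefficients on the other pools are transferred one-to-one onto the
#' remaining pool and dual-cofactor reactions other than the objective are
#' blocked.
#'
#' @param tcosa a [TcosaModel-class].
#' @param assignment a [SpecificityAssignment-class].
#' @return the constrained [TcosaModel-class].
#' @export
applyScenario <- function(tcosa, assignment) {
  prov <- tcosa@provenance
  known <- unique(prov$original[!is.na(prov$role)])
  unknown <- setdiff(names(assignment@choices), known)
  if (length(unknown))
    stop("configuration error: assignment references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  m <- tcosa@model
  lb <- m@lb; ub <- m@ub
  blocked <- character(0)
  for (k in names(assignment@choices)) {
    choice <- assignment@choices[[k]]
    if (identical(choice, "flexible")) next
    members <- prov[prov$original == k & !is.na(prov$role), , drop = FALSE]
    drop <- if (identical(choice, "blocked")) members$id
            else members$id[members$pool != choice]
    blocked <- c(blocked, drop)
  }
  singlePool <- identical(assignment@scenario, "single_pool")
  stoich <- m@stoich
  if (singlePool) {
    pool <- unique(assignment@choices)
    pool <- pool[pool %in% names(tcosa@cofactors@pools)][1]
    tgt <- tcosa@cofactors@pools[[pool]]
    obj <- m@objectiveReaction
    s <- stoich[[obj]]
    for (q in setdiff(names(tcosa@cofactors@pools), pool)) {
      other <- tcosa@cofactors@pools[[q]]
      for (side in c("ox", "red")) {
        id <- other[[side]]
        if (id %in% names(s)) {
          tid <- tgt[[side]]
          s[tid] <- (if (tid %in% names(s)) s[[tid]] else 0) + s[[id]]
          s <- s[names(s) != id]
        }
      }
    }
    s <- s[s != 0]
    stoich[[obj]] <- s
    blocked <- c(blocked, setdiff(tcosa@dualCofactorReactions, obj))
  }
  blocked <- unique(blocked)
  lb[blocked] <- 0; ub[blocked] <- 0
  newModel <- methods::initialize(m, lb = lb, ub = ub, stoich = stoich)
  methods::initialize(tcosa, model = newModel)
}

#' Growth-rate discretization grid
#'
#' Set points start at 99% of the maximal growth rate and descend in fixed
#' steps until the floor would be crossed; the floor itself (0.05 h^-1 by
#' default, the smallest growth rate considered) is appended. Values are
#' rounded to three decimals and deduplicated.
#'
#' @param muMax maximal growth rate (h^-1).
#' @param step step size (h^-1).
#' @param floor smallest growth rate considered (h^-1).
#' @return descending numeric vector of set points, with attributes `muMax`,
#'   `step`, `floor`.
#' @examples
#' length(growthGrid(0.877))  # 18 set points
#' length(growthGrid(0.375))  # 8 set points
#' @export
growthGrid <- function(muMax, step = 0.05, floor = 0.05) {
  start <- round(0.99 * muMax, 3)
  if (muMax <= floor) {
    pts <- start
  } else {
    pts <- start - step * (0:1000)
    pts <- round(pts[pts >= floor - 1e-9], 3)
    pts <- sort(unique(c(pts, floor)), decreasing = TRUE)
  }
  structure(pts, muMax = muMax, step = step, floor = floor)
}

#' Sample random specificity assignments
#'
#' Free mode flips an independent fair coin per duplicated redox reaction;
#' fixed mode draws uniformly among the assignments whose per-pool reaction
#' counts equal the wild type's. Sampling is deterministic given the seed
#' (sample `k` uses `seed + k - 1`, recorded in the assignment). Assignments
#' that later turn out stoichiometrically infeasible or thermodynamically
#' (near-)infeasible are meant to be disregarded by the caller, not resampled.
#'
#' @param tcosa a two-pool [TcosaModel-class].
#' @param nSamples number of assignments.
#' @param seed integer seed.
#' @param poolMode `"free"` or `"fixed"`.
#' @return list of [SpecificityAssignment-class] objects.
#' @export
sampleRandomSpecificity <- function(tcosa, nSamples, seed,
                                    poolMode = c("free", "fixed")) {
  poolMode <- match.arg(poolMode)
  wt <- redoxOriginals(tcosa)
  if (!length(wt)) stop("model has no duplicated redox reactions")
  poolNames <- names(tcosa@cofactors@pools)[1:2]
  if (poolMode == "fixed") {
    n1 <- sum(wt == poolNames[1])
    if (n1 > length(wt))
      stop("configuration error: pool counts exceed reaction count")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  lapply(seq_len(nSamples), function(k) {
    sk <- as.integer(seed + k - 1L)
    set.seed(sk)
    ch <- wt
    if (poolMode == "free") {
      ch[] <- poolNames[1 + stats::rbinom(length(wt), 1, 0.5)]
    } else {
      ch[] <- poolNames[2]
      ch[sample(length(wt), sum(wt == poolNames[1]))] <- poolNames[1]
    }
    new("SpecificityAssignment", choices = ch, scenario = "random",
        seed = sk, poolMode = poolMode)
  })
}

#' Census of redox reactions that can participate in optimal solutions
#'
#' For every growth set point, fixes the (Sub)MDF at its optimum and asks,
#' reaction by reaction, whether a feasible solution exists in which that
#' redox reaction carries flux (accounting for multiplicity of optimal
#' solutions). Returns the union over set points.
#'
#' @param tcosa a [TcosaModel-class].
#' @param assignment a [SpecificityAssignment-class].
#' @param grid growth set points from [growthGrid()].
#' @param objective `"MDF"` or `"SubMDF"`.
#' @param config a [MilpConfig-class].
#' @param band demanded-optimum tolerance (kJ/mol).
#' @return character vector of derived reaction ids (map to originals via
#'   [provenance()]).
#' @export
activeReactionCensus <- function(tcosa, assignment, grid,
                                 objective = c("MDF", "SubMDF"),
                                 config = milpConfig(),
                                 band = MDF_EQUALITY_BAND) {
  objective <- match.arg(objective)
  tc <- applyScenario(tcosa, assignment)
  subset <- if (objective == "SubMDF") redoxSubset(tc) else NULL
  candidates <- redoxSubset(tc)
  candidates <- candidates[tc@model@ub[candidates] > 0]
  census <- character(0)
  for (g in as.numeric(grid)) {
    cons <- list(growthMin = g)
    opt <- if (objective == "MDF") solveMdf(tc, cons, config)
           else solveSubMdf(tc, subset, cons, config)
    if (!identical(opt@status, "optimal")) next
    level <- if (objective == "MDF") opt@B else opt@BSub
    todo <- setdiff(candidates, census)
    if (!length(todo)) break
    probs <- lapply(todo, function(id) buildDfProblem(
      tc, cons, config,
      objective = list(vars = paste0("r_", id), coefs = 1, maximize = TRUE),
      subset = subset,
      fixLevel = list(kind = if (objective == "MDF") "B" else "BSub",
                      value = level, band = band)))
    res <- solveMilpBatch(probs, config)
    hit <- vapply(res, function(r)
      identical(r$status, "optimal") && r$objective > config@epsActive, NA)
    census <- c(census, todo[hit])
  }
  sort(census)
}

#' Compare two- and three-cofactor models over a growth grid
#'
#' Computes the flexible-specificity (Sub)MDF of the two-pool model and of
#' each supplied three-pool variant at every set point and reports the deltas
#' relative to the two-pool model. Adding a cofactor pool can never decrease
#' the flexible optimum; the delta is zero when the third pool's redox
#' potential matches NAD(P)H's.
#'
#' @param twoPool a two-pool [TcosaModel-class].
#' @param threePool a named list of three-pool [TcosaModel-class] objects
#'   (e.g. built at several redox-potential shifts).
#' @param grid growth set points.
#' @param objective `"MDF"` or `"SubMDF"`.
#' @param config a [MilpConfig-class].
#' @return data.frame with columns `growth`, `model`, `objective`, `value`,
#'   `delta`, `status`.
#' @export
compareThreeCofactor <- function(twoPool, threePool, grid,
                                 objective = c("MDF", "SubMDF"),
                                 config = milpConfig()) {
  objective <- match.arg(objective)
  models <- c(list(two_pool = twoPool), threePool)
  out <- list()
  for (g in as.numeric(grid)) {
    base <- NA_real_
    for (nm in names(models)) {
      tc <- applyScenario(models[[nm]], flexibleAssignment(models[[nm]]))
      cons <- list(growthMin = g)
      sol <- if (objective == "MDF") solveMdf(tc, cons, config)
             else solveSubMdf(tc, redoxSubset(tc), cons, config)
      val <- if (!identical(sol@status, "optimal")) NA_real_
             else if (objective == "MDF") sol@B else sol@BSub
      if (nm == "two_pool") base <- val
      out[[length(out) + 1L]] <- data.frame(
        growth = g, model = nm, objective = objective, value = val,
        delta = val - base, status = sol@status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' (Sub)MDF sweep over scenarios and growth set points
#'
#' Long-format driver: for every combination of assignment, growth set point
#' and objective, applies the scenario and solves the corresponding MILP.
#'
#' @param tcosa a [TcosaModel-class].
#' @param assignments named list of [SpecificityAssignment-class] objects.
#' @param grid growth set points from [growthGrid()].
#' @param objectives subset of `c("MDF", "SubMDF")`.
#' @param config a [MilpConfig-class].
#' @return data.frame with columns `growth`, `scenario`, `objective`,
#'   `value_kJ_mol`, `status`, `seed`.
#' @export
mdfSweep <- function(tcosa, assignments, grid, objectives = c("MDF", "SubMDF"),
                     config = milpConfig()) {
  stopifnot(length(names(assignments)) == length(assignments))
  out <- list()
  for (nm in names(assignments)) {
    asg <- assignments[[nm]]
    tc <- applyScenario(tcosa, asg)
    subset <- redoxSubset(tc)
    for (g in as.numeric(grid)) for (obj in objectives) {
      sol <- if (obj == "MDF") solveMdf(tc, list(growthMin = g), config)
             else solveSubMdf(tc, subset, list(growthMin = g), config)
      val <- if (!identical(sol@status, "optimal")) NA_real_
             else if (obj == "MDF") sol@B else sol@BSub
      out[[length(out) + 1L]] <- data.frame(
        growth = g, scenario = nm, objective = obj, value_kJ_mol = val,
        status = sol@status, seed = asg@seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
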