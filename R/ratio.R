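## Variability analysis of the cofactor reduction-ratio quotient.

#' Feasible extremes of the cofactor-ratio quotient at fixed (Sub)MDF
#'
#' Computes the feasible range of
#' `rho = ln((red1/ox1) / (red2/ox2))` — by default the
#' `[NADH]/[NAD+] : [NADPH]/[NADP+]` quotient — while the MDF (or SubMDF) is
#' held at its previously found optimum for the given growth set point. The
#' two extremes are obtained by two independent MILPs (maximize and minimize
#' `rho`); only the driving-force level is fixed, the flux distribution and
#' activity pattern are free to differ between the two solves.
#'
#' @param tcosa a [TcosaModel-class].
#' @param assignment a [SpecificityAssignment-class].
#' @param growth growth set point (h^-1).
#' @param objective `"MDF"` or `"SubMDF"`.
#' @param optimum the previously computed optimum; computed on the fly when
#'   `NULL`.
#' @param pools length-2 character: names of the numerator and denominator
#'   cofactor pools (defaults to `NAD` over `NADP`).
#' @param config a [MilpConfig-class].
#' @param band tolerance on the fixed optimum (kJ/mol).
#' @return a [RatioRange-class].
#' @export
ratioRange <- function(tcosa, assignment, growth,
                       objective = c("MDF", "SubMDF"), optimum = NULL,
                       pools = NULL, config = milpConfig(),
                       band = MDF_EQUALITY_BAND) {
  objective <- match.arg(objective)
  tc <- applyScenario(tcosa, assignment)
  subset <- if (objective == "SubMDF") redoxSubset(tc) else NULL
  cons <- list(growthMin = growth)
  if (is.null(optimum)) {
    sol <- if (objective == "MDF") solveMdf(tc, cons, config)
           else solveSubMdf(tc, subset, cons, config)
    if (!identical(sol@status, "optimal"))
      stop("cannot fix the optimum: (Sub)MDF solve returned ", sol@status)
    optimum <- if (objective == "MDF") sol@B else sol@BSub
  }
  pn <- names(tc@cofactors@pools)
  if (is.null(pools))
    pools <- c(if ("NAD" %in% pn) "NAD" else pn[1],
               if ("NADP" %in% pn) "NADP" else pn[2])
  p1 <- tc@cofactors@pools[[pools[1]]]
  p2 <- tc@cofactors@pools[[pools[2]]]
  rhoVars <- paste0("x_", c(p1[["red"]], p1[["ox"]], p2[["red"]], p2[["ox"]]))
  rhoCoefs <- c(1, -1, -1, 1)
  fix <- list(kind = if (objective == "MDF") "B" else "BSub",
              value = optimum, band = band)
  probs <- lapply(c(TRUE, FALSE), function(mx) buildDfProblem(
    tc, cons, config,
    objective = list(vars = rhoVars, coefs = rhoCoefs, maximize = mx),
    subset = subset, fixLevel = fix))
  res <- solveMilpBatch(probs, config)
  bad <- !vapply(res, function(r) identical(r$status, "optimal"), NA)
  if (any(bad))
    stop("contract error: fixed-optimum constraint infeasible (stale optimum?)")
  hi <- res[[1]]$objective; lo <- res[[2]]$objective
  new("RatioRange", rhoMin = lo, rhoMax = hi, ratioMin = exp(lo),
      ratioMax = exp(hi), fixedObjective = optimum, objective = objective,
      growth = growth)
}
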