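## Shared fixtures, all generated in code.

RT_TEST <- 8.314462618e-3 * 298.15
CONC_SPAN <- log(0.02 / 1e-6)  # ln(2e4)

chainTcosa <- function(n, dG0 = 0) buildToyTcosa(toyNetworkSpec(n, stepDG0 = dG0))

redoxTcosa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildToyTcosa(toyRedoxFixtureSpec())
    cache
  }
})

## manual toy: a redox route strictly worse (endergonic) than a cofactor-free
## bypass of the same conversion, so the redox reaction is inactive in every
## optimal solution
bypassToy <- function() {
  mets <- data.frame(
    id = c("S_e", "A", "P", "nad_c", "nadh_c", "nadp_c", "nadph_c"),
    external = c(TRUE, rep(FALSE, 6)))
  rxns <- list(
    R1 = list(stoich = c(S_e = -1, A = 1), lb = 0, ub = 10),
    BYP = list(stoich = c(A = -1, P = 1), lb = 0, ub = 10),
    RED = list(stoich = c(A = -1, nad_c = -1, P = 1, nadh_c = 1), lb = 0, ub = 10),
    OX = list(stoich = c(nadh_c = -1, nad_c = 1), lb = 0, ub = 10),
    SINK_P = list(stoich = c(P = -1), lb = 0, ub = 10))
  model <- metabolicModel(mets, rxns, objective = "SINK_P",
                          exchanges = character(0))
  ids <- mets$id
  thermo <- thermoAnnotation(
    dG0 = c(R1 = -10, BYP = -10, RED = 10, OX = -40),
    cMin = stats::setNames(rep(1e-6, length(ids)), ids),
    cMax = stats::setNames(rep(0.02, length(ids)), ids))
  buildTcosaModel(model, thermo)
}

## toy with a misrouted wild-type specificity: a strongly endergonic
## NADH-consuming step shares the NAD pool with the step that reduces it,
## an irreconcilable ratio conflict; the flexible scenario moves the consumer
## onto the NADP pool, whose regeneration reaction (present for the biomass
## NADPH demand) supplies it
misroutedToy <- function() {
  buildToyTcosa(toyNetworkSpec(3, stepDG0 = c(-20, -5, 25),
                               stepRedox = c(NA, "NAD_red", "NAD_ox"),
                               biomass = list(nadph = 0.05)))
}

## exhaustive reference for the minimal-swap count: tries every subset of
## specificity flips and returns the smallest one reaching the target
exhaustiveMinSwaps <- function(tc, assignment, target, growth,
                               band = 1e-3) {
  originals <- names(specificityChoices(assignment))
  pools2 <- c("NAD", "NADP")
  best <- Inf
  for (mask in 0:(2^length(originals) - 1)) {
    flip <- originals[bitwAnd(bitwShiftR(mask, seq_along(originals) - 1L), 1L) == 1L]
    asg <- assignment
    for (k in flip)
      asg@choices[[k]] <- setdiff(pools2, asg@choices[[k]])
    sol <- solveMdf(applyScenario(tc, asg), list(growthMin = growth))
    if (identical(solutionStatus(sol), "optimal") && mdfValue(sol) >= target - band)
      best <- min(best, length(flip))
  }
  best
}
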