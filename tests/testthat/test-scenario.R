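test_that("growth grids discretize from 99% of the maximum down to the floor", {
  g <- growthGrid(0.877)
  expect_length(g, 18)
  expect_equal(g[1], 0.868)
  expect_equal(g[length(g)], 0.05)
  expect_true(all(diff(as.numeric(g)) < 0))
  expect_equal(diff(as.numeric(g))[1:16], rep(-0.05, 16))
  expect_length(growthGrid(0.375), 8)
  expect_equal(as.numeric(growthGrid(0.10)), c(0.099, 0.05))
  ## below-floor degenerate case: single set point at 99% of the maximum,
  ## subject to the 3-decimal rounding rule (0.0297 -> 0.03)
  expect_equal(as.numeric(growthGrid(0.03)), 0.03)
})

test_that("assignments block the right variants", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  expect_equal(specificityChoices(wt)[c("R2", "R3")], c(R2 = "NAD", R3 = "NADP"))
  tw <- applyScenario(tc, wt)
  rx <- reactions(tw)
  expect_equal(rx$ub[rx$id == "R2_VARIANT_NADP_TCOSA"], 0)
  expect_equal(rx$ub[rx$id == "R2_ORIGINAL_NAD_TCOSA"], 10)
  tf <- applyScenario(tc, flexibleAssignment(tc))
  expect_true(all(reactions(tf)$ub[grepl("VARIANT", reactions(tf)$id)] > 0))
  expect_error(applyScenario(tc, new("SpecificityAssignment",
                                     choices = c(NOPE = "NAD"),
                                     scenario = "wild_type")),
               "unknown reaction")
})

test_that("the single-pool scenario reroutes the biomass cofactor demand", {
  tc <- redoxTcosa()
  ts <- applyScenario(tc, singlePoolAssignment(tc))
  s <- stoichiometry(ts, "BM")
  expect_false(any(c("nadp_c", "nadph_c") %in% names(s)))
  ## the 0.05 NADPH demand rerouted onto NADH cancels the 0.05 NADH
  ## production of the NAD+ demand, so the rewritten biomass reaction keeps
  ## no cofactor terms at all
  expect_false(any(c("nad_c", "nadh_c") %in% names(s)))
  expect_equal(s[["P"]], -1)
  ## all NADP variants closed
  rx <- reactions(ts)
  expect_true(all(rx$ub[grepl("_NADP_TCOSA$", rx$id)] == 0))
})

test_that("FBA growth respects flux bounds and scenario blocking", {
  tc <- redoxTcosa()
  res <- maxGrowth(tc, wildTypeAssignment(tc))
  expect_identical(res$status, "optimal")
  ## the regeneration reactions carry 1.05x the growth flux, so the common
  ## flux cap of 10 limits wild-type growth to 10/1.05
  expect_equal(res$growth, 10 / 1.05, tolerance = 1e-6)
  ## the single-pool scenario skips the regeneration overhead (the rerouted
  ## biomass demands cancel) and grows faster -- the stoichiometric-efficiency
  ## effect of collapsing the pools
  expect_equal(maxGrowth(tc, singlePoolAssignment(tc))$growth, 10,
               tolerance = 1e-6)
  blockedModel <- applyScenario(tc, wildTypeAssignment(tc))
  blockedModel@model@ub[["R1"]] <- 0
  expect_equal(maxGrowth(blockedModel)$growth, 0)
})

test_that("scenario ordering holds at every set point", {
  tc <- redoxTcosa()
  asgs <- list(single_pool = singlePoolAssignment(tc),
               wild_type = wildTypeAssignment(tc),
               flexible = flexibleAssignment(tc))
  tab <- mdfSweep(tc, asgs, growthGrid(2, step = 1), "MDF")
  for (g in unique(tab$growth)) {
    v <- with(tab[tab$growth == g, ], stats::setNames(value_kJ_mol, scenario))
    expect_lte(v[["single_pool"]], v[["wild_type"]] + 1e-3)
    expect_lte(v[["wild_type"]], v[["flexible"]] + 1e-3)
  }
})

test_that("random sampling is reproducible and respects pool sizes", {
  tc <- redoxTcosa()
  a <- sampleRandomSpecificity(tc, 6, seed = 11, poolMode = "fixed")
  b <- sampleRandomSpecificity(tc, 6, seed = 11, poolMode = "fixed")
  expect_identical(lapply(a, specificityChoices), lapply(b, specificityChoices))
  wt <- specificityChoices(wildTypeAssignment(tc))
  for (asg in a) {
    ch <- specificityChoices(asg)
    expect_equal(sum(ch == "NAD"), sum(wt == "NAD"))
    expect_equal(sum(ch == "NADP"), sum(wt == "NADP"))
  }
  ## free mode: per-reaction NAD frequency is binomial around 1/2
  free <- sampleRandomSpecificity(tc, 10000, seed = 3, poolMode = "free")
  freq <- rowMeans(sapply(free, function(x) specificityChoices(x) == "NAD"))
  expect_true(all(abs(freq - 0.5) < 0.02))
  ## a random specificity never beats the flexible optimum
  flex <- mdfValue(solveMdf(applyScenario(tc, flexibleAssignment(tc)),
                            list(growthMin = 1)))
  for (asg in a[1:3]) {
    s <- solveMdf(applyScenario(tc, asg), list(growthMin = 1))
    if (identical(solutionStatus(s), "optimal"))
      expect_lte(mdfValue(s), flex + 1e-3)
  }
})

test_that("the activity census covers the optimal pathway and solution multiplicity", {
  tc <- redoxTcosa()
  cen <- activeReactionCensus(tc, wildTypeAssignment(tc), 1, "MDF")
  expect_setequal(cen, c("R2_ORIGINAL_NAD_TCOSA", "R3_ORIGINAL_NADP_TCOSA",
                         "ROX_NAD_ORIGINAL_NAD_TCOSA",
                         "RRED_NADP_ORIGINAL_NADP_TCOSA"))
  ## under flexible specificity a symmetric network admits both variants
  sym <- buildToyTcosa(toyNetworkSpec(2, stepDG0 = c(-10, -10),
                                      stepRedox = c(NA, "NAD_red")))
  cenSym <- activeReactionCensus(sym, flexibleAssignment(sym), 1, "MDF")
  expect_true(all(c("R2_ORIGINAL_NAD_TCOSA", "R2_VARIANT_NADP_TCOSA") %in% cenSym))
  ## census superset: reactions active in the returned optimum are included
  sol <- solveMdf(applyScenario(sym, flexibleAssignment(sym)), list(growthMin = 1))
  expect_true(all(intersect(activeReactions(sol), tcosa:::redoxSubset(sym)) %in% cenSym))
})

test_that("a third cofactor pool at identical potential brings no MDF advantage", {
  toy <- generateToy(toyRedoxFixtureSpec())
  two <- redoxTcosa()
  three0 <- buildTcosaModel(toy$model, toy$thermo, defaultCofactors(nadz = TRUE),
                            dEShift_mV = 0)
  tab <- compareThreeCofactor(two, list(same_potential = three0), 1, "MDF")
  expect_equal(tab$delta[tab$model == "same_potential"], 0, tolerance = 1e-6)
  ## adding options never hurts
  expect_gte(min(tab$delta, na.rm = TRUE), -1e-6)
})

test_that("a low-potential third pool raises the SubMDF of a hard reduction", {
  ## the NADPH regenerator has a large thermodynamic slack, which a
  ## concentration ratio alone cannot pass on to the endergonic consumer
  ## (the ratio is capped by the concentration bounds); a lower-potential
  ## cofactor moves the slack into the standard Gibbs energies directly
  toy <- generateToy(toyNetworkSpec(2, stepDG0 = c(-5, 20),
                                    stepRedox = c(NA, "NADP_ox"),
                                    regenDG0 = c(NAD = -40, NADP = -60)))
  two <- buildTcosaModel(toy$model, toy$thermo, toy$cofactors)
  strong <- buildTcosaModel(toy$model, toy$thermo, defaultCofactors(nadz = TRUE),
                            dEShift_mV = -155)
  tab <- compareThreeCofactor(two, list(strong_donor = strong), 1, "SubMDF")
  delta <- tab$delta[tab$model == "strong_donor"]
  expect_gt(delta, 1)
  ## oracle confirmation on the expanded model
  flexed <- applyScenario(strong, flexibleAssignment(strong))
  oracle <- bruteForceMdf(flexed, list(growthMin = 1), objective = "SubMDF")
  expect_equal(tab$value[tab$model == "strong_donor"], as.numeric(oracle),
               tolerance = 1e-4)
})
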