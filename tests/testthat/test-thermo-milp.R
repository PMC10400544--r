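test_that("driving forces follow -dG0 - RT S'x", {
  tc <- chainTcosa(1, dG0 = 0)
  x0 <- c(S_e = log(1e-3), P = log(1e-3))
  expect_equal(drivingForce("R1", x0, tc), 0)
  x1 <- c(S_e = log(0.02), P = log(1e-6))
  expect_equal(drivingForce("R1", x1, tc), RT_TEST * CONC_SPAN, tolerance = 1e-10)
  tc2 <- chainTcosa(1, dG0 = -34.37)
  expect_equal(drivingForce("R1", x0, tc2), 34.37)
  ## thermo-inactive reactions have no driving force
  expect_error(drivingForce("SINK_P", x0, tc), "contract error")
})

test_that("big-M is certified and solutions are insensitive to doubling it", {
  tc <- chainTcosa(1, dG0 = 0)
  expect_equal(computeBigM(tc), 2 * RT_TEST * max(abs(log(1e-6)), abs(log(0.02))) + 1,
               tolerance = 1e-9)
  expect_equal(computeBigM(tc, milpConfig(bigM = 1e5)), 1e5)
  s1 <- solveMdf(tc, list(growthMin = 1))
  expect_lt(max(drivingForces(s1)), computeBigM(tc))
  tcr <- redoxTcosa()
  sA <- solveMdf(tcr, list(growthMin = 1))
  sB <- solveMdf(tcr, list(growthMin = 1),
                 milpConfig(bigM = 2 * computeBigM(tcr)))
  expect_equal(mdfValue(sA), mdfValue(sB), tolerance = 1e-6)
})

test_that("MDF reproduces the closed-form chain optima", {
  s1 <- solveMdf(chainTcosa(1), list(growthMin = 1))
  expect_equal(mdfValue(s1), RT_TEST * CONC_SPAN, tolerance = 1e-6)
  s2 <- solveMdf(chainTcosa(2), list(growthMin = 1))
  expect_equal(mdfValue(s2), RT_TEST * CONC_SPAN / 2, tolerance = 1e-6)
})

test_that("stoichiometric infeasibility is distinguished from negative MDF", {
  tc <- chainTcosa(1)
  blocked <- solveMdf(tc, list(growthMin = 1, blocked = "R1"))
  expect_identical(solutionStatus(blocked), "infeasible")
  expect_true(is.na(mdfValue(blocked)))
  hard <- chainTcosa(2, dG0 = c(0, 200))
  s <- solveMdf(hard, list(growthMin = 1))
  expect_identical(solutionStatus(s), "optimal")
  expect_lt(mdfValue(s), 0)
  expect_equal(mdfValue(s), as.numeric(bruteForceMdf(hard, list(growthMin = 1))),
               tolerance = 1e-6)
})

test_that("widening concentration bounds never decreases the MDF", {
  base <- solveMdf(redoxTcosa(), list(growthMin = 1))
  toy <- generateToy(toyNetworkSpec(3, stepDG0 = c(-10, -20, 15),
                                    stepRedox = c(NA, "NAD_red", "NADP_ox"),
                                    boundary = c(1e-7, 0.05),
                                    biomass = list(nadph = 0.05, nad = 0.05)))
  wide <- buildTcosaModel(toy$model, toy$thermo, toy$cofactors)
  sWide <- solveMdf(wide, list(growthMin = 1))
  expect_gte(mdfValue(sWide), mdfValue(base) - 1e-6)
})

test_that("SubMDF dominates MDF and matches the restricted-chain oracle", {
  tcr <- redoxTcosa()
  sub <- tcosa:::redoxSubset(tcr)
  mdf <- solveMdf(tcr, list(growthMin = 1))
  smdf <- solveSubMdf(tcr, sub, list(growthMin = 1))
  expect_identical(solutionStatus(smdf), "optimal")
  expect_gte(subMdfValue(smdf), mdfValue(mdf) - 1e-6)
  expect_gte(mdfValue(smdf), 0.1 - 1e-9)
  ## subnetwork of one downhill reaction in a two-step chain: its floor
  ## exceeds the full-network MDF
  tc <- chainTcosa(2, dG0 = c(0, -30))
  full <- solveMdf(tc, list(growthMin = 1))
  one <- solveSubMdf(tc, "R2", list(growthMin = 1))
  expect_gt(subMdfValue(one), mdfValue(full) + 1)
  oracle <- bruteForceMdf(tc, list(growthMin = 1), objective = "SubMDF",
                          subset = "R2")
  expect_equal(subMdfValue(one), as.numeric(oracle), tolerance = 1e-6)
  ## subset = all thermo-active reactions collapses to the MDF when that is
  ## above the feasibility floor
  all <- solveSubMdf(tcr, names(drivingForces(mdf)), list(growthMin = 1))
  expect_equal(subMdfValue(all), mdfValue(mdf), tolerance = 1e-6)
})

test_that("at most one member of each variant group is active", {
  tcr <- applyScenario(redoxTcosa(), flexibleAssignment(redoxTcosa()))
  sol <- solveMdf(tcr, list(growthMin = 1))
  act <- activeReactions(sol)
  for (g in variantGroups(tcr))
    expect_lte(length(intersect(g, act)), 1L)
})

test_that("solver misuse and bad backends fail loudly", {
  expect_error(solveSubMdf(redoxTcosa(), character(0), list(growthMin = 1)),
               "non-empty")
  expect_error(solveMdf(redoxTcosa(), list(growthMin = 1),
                        milpConfig(solver = "cplex")),
               "unknown solver")
  expect_error(bruteForceMdf(redoxTcosa(), maxReactions = 3L), "too large")
})
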