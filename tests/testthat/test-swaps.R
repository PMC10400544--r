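test_that("single-swap scan flags infeasible swaps and matches re-solves", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  scan <- singleSwapScan(tc, wt, 1, "MDF")
  ## swapping either regeneration reaction removes the only recycling route
  ## for its pool: stoichiometrically infeasible, flagged and excluded
  expect_false(scan$feasible[scan$reaction == "ROX_NAD"])
  expect_false(scan$feasible[scan$reaction == "RRED_NADP"])
  expect_true(all(is.na(scan$delta[!scan$feasible])))
  ## feasible swaps match an explicit re-solve
  for (k in scan$reaction[scan$feasible]) {
    flipped <- wt
    flipped@choices[[k]] <- setdiff(c("NAD", "NADP"), wt@choices[[k]])
    ref <- solveMdf(applyScenario(tc, flipped), list(growthMin = 1))
    expect_equal(scan$value[scan$reaction == k], mdfValue(ref), tolerance = 1e-6)
  }
  expect_true(all(scan$delta[scan$feasible] <= 1e-3))
})

test_that("swapping a reaction outside every optimal solution changes nothing", {
  tc <- bypassToy()
  wt <- wildTypeAssignment(tc)
  scan <- singleSwapScan(tc, wt, 1, "MDF")
  row <- scan[scan$reaction == "RED", ]
  expect_true(row$feasible)
  expect_equal(row$delta, 0, tolerance = 1e-6)
})

test_that("minimal swap count is zero exactly when the wild type attains the flexible optimum", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  flexOpt <- mdfValue(solveMdf(applyScenario(tc, flexibleAssignment(tc)),
                               list(growthMin = 1)))
  wtOpt <- mdfValue(solveMdf(applyScenario(tc, wt), list(growthMin = 1)))
  ms <- minSwapsToTarget(tc, wt, flexOpt, 1, "MDF")
  expect_identical(ms$status, "optimal")
  expect_identical(ms$count == 0L, abs(wtOpt - flexOpt) <= 1e-3)
})

test_that("minimal swap sets match the exhaustive subset search", {
  ## misrouted wild type: the flexible optimum requires moving the hard
  ## NADH-consuming step onto the NADP pool, which takes at least one swap
  tc <- misroutedToy()
  wt <- wildTypeAssignment(tc)
  expect_equal(unname(specificityChoices(wt)[c("R2", "R3")]), c("NAD", "NAD"))
  flexOpt <- mdfValue(solveMdf(applyScenario(tc, flexibleAssignment(tc)),
                               list(growthMin = 1)))
  wtOpt <- mdfValue(solveMdf(applyScenario(tc, wt), list(growthMin = 1)))
  expect_gt(flexOpt, wtOpt + 1e-3)
  ms <- minSwapsToTarget(tc, wt, flexOpt, 1, "MDF")
  expect_identical(ms$status, "optimal")
  expect_gt(ms$count, 0L)
  ref <- exhaustiveMinSwaps(tc, wt, flexOpt, 1)
  expect_equal(ms$count, ref)
  ## the returned swap set really reaches the target
  asg <- wt
  for (k in ms$swaps)
    asg@choices[[k]] <- setdiff(c("NAD", "NADP"), asg@choices[[k]])
  reached <- mdfValue(solveMdf(applyScenario(tc, asg), list(growthMin = 1)))
  expect_gte(reached, flexOpt - 1e-3)
})

test_that("SubMDF swap targets are honored too", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  tf <- applyScenario(tc, flexibleAssignment(tc))
  flexSub <- subMdfValue(solveSubMdf(tf, tcosa:::redoxSubset(tf),
                                     list(growthMin = 1)))
  ms <- minSwapsToTarget(tc, wt, flexSub, 1, "SubMDF")
  expect_identical(ms$status, "optimal")
  expect_gte(ms$count, 0L)
})
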