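test_that("pinned cofactor concentrations force a unit ratio quotient", {
  toy <- generateToy(toyRedoxFixtureSpec())
  cofs <- c("nad_c", "nadh_c", "nadp_c", "nadph_c")
  thermo <- toy$thermo
  thermo@cMin[cofs] <- 1e-4
  thermo@cMax[cofs] <- 1e-4
  tc <- buildTcosaModel(toy$model, thermo, toy$cofactors)
  sol <- solveMdf(applyScenario(tc, wildTypeAssignment(tc)), list(growthMin = 1))
  rr <- ratioRange(tc, wildTypeAssignment(tc), 1, "MDF", optimum = mdfValue(sol))
  b <- ratioBounds(rr)
  expect_equal(unname(b["rhoMin"]), 0, tolerance = 1e-9)
  expect_equal(unname(b["rhoMax"]), 0, tolerance = 1e-9)
  expect_equal(unname(b["ratioMin"]), 1, tolerance = 1e-9)
})

test_that("unconstrained cofactors reach the pure bound arithmetic", {
  toy <- generateToy(toyRedoxFixtureSpec())
  ## only the first pathway step keeps its driving-force constraint, so no
  ## thermodynamic constraint touches the cofactor concentrations
  ta <- c(R1 = TRUE, R2 = FALSE, R3 = FALSE, BM = FALSE,
          ROX_NAD = FALSE, RRED_NADP = FALSE)
  tc <- buildTcosaModel(toy$model, toy$thermo, toy$cofactors, thermoActive = ta)
  wt <- wildTypeAssignment(tc)
  sol <- solveMdf(applyScenario(tc, wt), list(growthMin = 1))
  rr <- ratioRange(tc, wt, 1, "MDF", optimum = mdfValue(sol))
  b <- ratioBounds(rr)
  expect_equal(unname(b["ratioMax"]), (0.02 / 1e-6)^2, tolerance = 1e-6)
  expect_equal(unname(b["ratioMin"]), (1e-6 / 0.02)^2, tolerance = 1e-6)
})

test_that("ratio ranges match the exhaustive oracle on the packaged fixture", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  tw <- applyScenario(tc, wt)
  opt <- mdfValue(solveMdf(tw, list(growthMin = 1)))
  rr <- ratioRange(tc, wt, 1, "MDF", optimum = opt)
  oracle <- bruteForceRatioRange(tw, level = opt, constraints = list(growthMin = 1))
  b <- ratioBounds(rr)
  expect_equal(unname(b["rhoMin"]), unname(oracle["rhoMin"]), tolerance = 1e-4)
  expect_equal(unname(b["rhoMax"]), unname(oracle["rhoMax"]), tolerance = 1e-4)
})

test_that("the catabolic/anabolic fixture keeps NAD(H) more oxidized than NADP(H)", {
  tc <- redoxTcosa()
  rr <- ratioRange(tc, wildTypeAssignment(tc), 1, "MDF")
  expect_lt(ratioBounds(rr)[["ratioMax"]], 1)
  rrSub <- ratioRange(tc, wildTypeAssignment(tc), 1, "SubMDF")
  expect_lt(ratioBounds(rrSub)[["ratioMax"]], 1)
})

test_that("swapping the pool roles negates the log-ratio interval", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  opt <- mdfValue(solveMdf(applyScenario(tc, wt), list(growthMin = 1)))
  a <- ratioBounds(ratioRange(tc, wt, 1, "MDF", optimum = opt))
  b <- ratioBounds(ratioRange(tc, wt, 1, "MDF", optimum = opt,
                              pools = c("NADP", "NAD")))
  expect_equal(unname(a["rhoMin"]), -unname(b["rhoMax"]), tolerance = 1e-6)
  expect_equal(unname(a["rhoMax"]), -unname(b["rhoMin"]), tolerance = 1e-6)
})

test_that("lowering the demanded driving force never shrinks the ratio range", {
  tc <- redoxTcosa()
  wt <- wildTypeAssignment(tc)
  opt <- mdfValue(solveMdf(applyScenario(tc, wt), list(growthMin = 1)))
  tight <- ratioBounds(ratioRange(tc, wt, 1, "MDF", optimum = opt))
  slack <- ratioBounds(ratioRange(tc, wt, 1, "MDF", optimum = opt - 2))
  expect_lte(slack[["rhoMin"]], tight[["rhoMin"]] + 1e-6)
  expect_gte(slack[["rhoMax"]], tight[["rhoMax"]] - 1e-6)
})

test_that("a stale optimum raises a contract error", {
  tc <- redoxTcosa()
  expect_error(ratioRange(tc, wildTypeAssignment(tc), 1, "MDF", optimum = 1e3),
               "contract error")
})
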