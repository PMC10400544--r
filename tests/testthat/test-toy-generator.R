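test_that("toy generation is deterministic and validated", {
  a <- generateToy(toyRedoxFixtureSpec())
  b <- generateToy(toyRedoxFixtureSpec())
  expect_equal(stoichiometry(a$model), stoichiometry(b$model))
  expect_equal(dG0(a$thermo), dG0(b$thermo))
  expect_true(validObject(a$model))
  ## random specs are reproducible from the seed and vary across seeds
  expect_equal(toyRandomSpec(5), toyRandomSpec(5))
  expect_false(identical(toyRandomSpec(5)$stepDG0, toyRandomSpec(6)$stepDG0))
  ## byte-identical files from the same spec
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeToyModel(a$model, f1, thermo = a$thermo)
  writeToyModel(b$model, f2, thermo = b$thermo)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("contradictory specs are rejected", {
  expect_error(toyNetworkSpec(2, stepRedox = c(NA, "FAD_red")), "redox tag")
  expect_error(toyNetworkSpec(2, biomass = list()), "biomass demands")
})

test_that("generated redox toys exercise both pools and every scenario", {
  tc <- redoxTcosa()
  wtPools <- specificityChoices(wildTypeAssignment(tc))
  expect_true(all(c("NAD", "NADP") %in% wtPools))
  ## every scenario and the swap machinery is applicable
  for (asg in list(wildTypeAssignment(tc), flexibleAssignment(tc),
                   singlePoolAssignment(tc)))
    expect_s4_class(applyScenario(tc, asg), "TcosaModel")
  expect_gt(length(tcosa:::complementarySet(tc, wildTypeAssignment(tc))), 0)
})

test_that("generated instances stay within the oracle's size guard", {
  for (s in c(1, 7, 13)) {
    tc <- buildToyTcosa(toyRandomSpec(s))
    expect_lte(nrow(reactions(tc)), 12)
    expect_true(is.finite(bruteForceMdf(tc, list(growthMin = 1))) ||
                  is.na(bruteForceMdf(tc, list(growthMin = 1))))
  }
})
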