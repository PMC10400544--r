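test_that("toy-JSON models round-trip through write and read", {
  toy <- generateToy(toyRedoxFixtureSpec())
  f <- withr::local_tempfile(fileext = ".json")
  writeToyModel(toy$model, f, thermo = toy$thermo)
  back <- readToyModel(f)
  expect_equal(metabolites(back$model), metabolites(toy$model))
  expect_equal(reactions(back$model), reactions(toy$model))
  expect_equal(stoichiometry(back$model), stoichiometry(toy$model))
  expect_equal(dG0(back$thermo), dG0(toy$thermo))
  expect_equal(objectiveReaction(back$model), "BM")
  expect_identical(loadModel(f)@rxnId, toy$model@rxnId)
})

test_that("model invariants reject inconsistent input", {
  mets <- data.frame(id = c("A", "B"), external = c(TRUE, FALSE))
  expect_error(
    metabolicModel(mets, list(R1 = list(stoich = c(A = -1, B = 1), lb = 5, ub = 1)),
                   objective = "R1"),
    "lower bound exceeds upper bound")
  expect_error(
    metabolicModel(mets, list(R1 = list(stoich = c(A = -1, C = 1), lb = 0, ub = 1)),
                   objective = "R1"),
    "unknown metabolite")
  expect_error(
    metabolicModel(mets, list(R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1)),
                   objective = "nope"),
    "objectiveReaction")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list(), reactions = list()), f)
  expect_error(readToyModel(f), "objective")
})

test_that("SBML export and re-import preserve the network", {
  toy <- generateToy(toyRedoxFixtureSpec())
  f <- withr::local_tempfile(fileext = ".xml")
  writeSbmlModel(toy$model, f, notes = "reconfiguration provenance")
  back <- readSbmlModel(f)
  expect_match(back$notes, "provenance")
  m2 <- back$model
  expect_setequal(m2@rxnId, toy$model@rxnId)
  expect_setequal(m2@metId, toy$model@metId)
  expect_equal(objectiveReaction(m2), objectiveReaction(toy$model))
  expect_equal(metabolites(m2)$external[match("S_e", m2@metId)], TRUE)
  for (id in toy$model@rxnId) {
    a <- stoichiometry(toy$model, id); b <- stoichiometry(m2, id)
    expect_equal(b[order(names(b))], a[order(names(a))])
  }
  fb <- fluxBounds(m2)[m2@rxnId %in% "BM", , drop = FALSE]
  expect_equal(unname(fb[1, ]), c(0, 10))
})

test_that("Gibbs-energy tables and result tables round-trip exactly", {
  toy <- generateToy(toyRedoxFixtureSpec())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDeltaGTable(toy$thermo, f)
  tab <- readDeltaGTable(f)
  expect_equal(tab$dG0[names(dG0(toy$thermo))], dG0(toy$thermo))

  res <- data.frame(growth = c(0.868, 0.05), value_kJ_mol = c(pi, exp(1) / 3),
                    scenario = c("wild_type", "flexible"))
  g <- withr::local_tempfile(fileext = ".csv")
  writeResultsTable(res, g)
  expect_identical(readResultsTable(g), res)

  empty <- res[0, ]
  writeResultsTable(empty, g)
  expect_identical(nrow(readResultsTable(g)), 0L)
  expect_identical(names(readResultsTable(g)), names(res))
})

test_that("solution JSON export validates and round-trips", {
  tc <- chainTcosa(2)
  sol <- solveMdf(tc, list(growthMin = 1))
  f <- withr::local_tempfile(fileext = ".json")
  writeSolutionJson(sol, f)
  back <- readSolutionJson(f)
  expect_equal(mdfValue(back), mdfValue(sol))
  expect_equal(fluxes(back), fluxes(sol))
  expect_equal(logConcentrations(back), logConcentrations(sol))
  expect_setequal(activeReactions(back), activeReactions(sol))
  ## re-validated against the solution invariants: mass balance and the
  ## driving-force floor over active reactions
  S <- stoichiometry(tc)
  internal <- metabolites(tc)$id[!metabolites(tc)$external]
  expect_lt(max(abs(S[internal, , drop = FALSE] %*% fluxes(back))), 1e-7)
  act <- intersect(activeReactions(back), names(drivingForces(back)))
  expect_true(all(drivingForces(back)[act] >= mdfValue(back) - 1e-6))
})
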