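makeModel <- function(rxns, metIds, external = "S_e",
                      objective = names(rxns)[length(rxns)],
                      exchanges = character(0)) {
  mets <- data.frame(id = metIds, external = metIds %in% external)
  metabolicModel(mets, rxns, objective = objective, exchanges = exchanges)
}

test_that("reversible splitting produces the forward/backward pair with negated dG0", {
  model <- makeModel(list(
    R1 = list(stoich = c(A = -1, B = 1), lb = -5, ub = 10),
    R2 = list(stoich = c(B = -1, C = 1), lb = 0, ub = 10),
    SINK = list(stoich = c(C = -1), lb = 0, ub = 10)),
    metIds = c("A", "B", "C"), external = "A", objective = "SINK")
  thermo <- thermoAnnotation(dG0 = c(R1 = 3, R2 = -7),
                             cMin = c(A = 1e-6, B = 1e-6, C = 1e-6),
                             cMax = c(A = 0.02, B = 0.02, C = 0.02))
  sp <- splitReversible(model, thermo)
  rx <- reactions(sp$model)
  expect_setequal(rx$id, c("R1_FWD", "R1_REV", "R2", "SINK"))
  expect_equal(rx$lb[rx$id == "R1_FWD"], 0)
  expect_equal(rx$ub[rx$id == "R1_FWD"], 10)
  expect_equal(rx$ub[rx$id == "R1_REV"], 5)
  expect_equal(dG0(sp$thermo)[["R1_FWD"]], 3)
  expect_equal(dG0(sp$thermo)[["R1_REV"]], -3)
  expect_equal(dG0(sp$thermo)[["R2"]], -7)
  ## round trip: merging FWD/REV recovers the original reaction
  sF <- stoichiometry(sp$model, "R1_FWD"); sR <- stoichiometry(sp$model, "R1_REV")
  expect_equal(sF[order(names(sF))], -sR[order(names(sR))])
  expect_equal(c(-rx$ub[rx$id == "R1_REV"], rx$ub[rx$id == "R1_FWD"]), c(-5, 10))
})

test_that("sentinel-tagged reactions keep the sentinel in both directions", {
  model <- makeModel(list(
    R1 = list(stoich = c(A = -1, B = 1), lb = -10, ub = 10),
    SINK = list(stoich = c(B = -1), lb = 0, ub = 10)),
    metIds = c("A", "B"), external = "A", objective = "SINK")
  thermo <- assignDefaultDG(model, thermoAnnotation(
    cMin = c(A = 1e-6, B = 1e-6), cMax = c(A = 0.02, B = 0.02)))
  expect_equal(dG0(thermo)[["R1"]], -100)
  expect_equal(unname(dG0Tags(thermo)["R1"]), "default_sentinel")
  sp <- splitReversible(model, thermo)
  expect_equal(dG0(sp$thermo)[["R1_FWD"]], -100)
  expect_equal(dG0(sp$thermo)[["R1_REV"]], -100)
})

test_that("default assignment distinguishes sentinel, transporter and unconstrained", {
  model <- makeModel(list(
    EXG = list(stoich = c(G_e = 1), lb = 0, ub = 10),
    TRANS = list(stoich = c(G_e = -1, G_c = 1), lb = 0, ub = 10),
    CONV = list(stoich = c(G_c = -1, X_c = 1), lb = 0, ub = 10),
    KNOWN = list(stoich = c(X_c = -1, Y_c = 1), lb = 0, ub = 10),
    GROWTH = list(stoich = c(Y_c = -1), lb = 0, ub = 10)),
    metIds = c("G_e", "G_c", "X_c", "Y_c"), external = "G_e",
    objective = "GROWTH", exchanges = "EXG")
  thermo <- thermoAnnotation(dG0 = c(KNOWN = 5.12, TRANS = -3),
                             cMin = stats::setNames(rep(1e-6, 4), c("G_e", "G_c", "X_c", "Y_c")),
                             cMax = stats::setNames(rep(0.02, 4), c("G_e", "G_c", "X_c", "Y_c")))
  out <- assignDefaultDG(model, thermo)
  tags <- dG0Tags(out)
  expect_equal(unname(tags[c("EXG", "GROWTH")]), rep("unconstrained", 2))
  expect_false(any(c("EXG", "GROWTH") %in% names(dG0(out))))
  ## the pure transporter loses its computed value in favor of the sentinel
  expect_equal(unname(tags["TRANS"]), "default_sentinel")
  expect_equal(dG0(out)[["TRANS"]], -100)
  expect_equal(unname(tags["CONV"]), "default_sentinel")
  expect_equal(dG0(out)[["CONV"]], -100)
  expect_equal(unname(tags["KNOWN"]), "computed")
  expect_equal(dG0(out)[["KNOWN"]], 5.12)
})

test_that("median imputation uses the consuming-species median", {
  rxns <- list(
    D1 = list(stoich = c(A = -1, nad_c = -1, B = 1, nadh_c = 1), lb = 0, ub = 10),
    D2 = list(stoich = c(B = -1, nad_c = -1, C = 1, nadh_c = 1), lb = 0, ub = 10),
    D3 = list(stoich = c(C = -1, nad_c = -1, D = 1, nadh_c = 1), lb = 0, ub = 10),
    DX = list(stoich = c(D = -1, nad_c = -1, E = 1, nadh_c = 1), lb = 0, ub = 10),
    SINK = list(stoich = c(E = -1), lb = 0, ub = 10))
  ids <- c("A", "B", "C", "D", "E", "nad_c", "nadh_c", "nadp_c", "nadph_c")
  model <- makeModel(rxns, metIds = ids, external = "A", objective = "SINK")
  thermo <- thermoAnnotation(dG0 = c(D1 = 2, D2 = 4, D3 = 9),
                             cMin = stats::setNames(rep(1e-6, length(ids)), ids),
                             cMax = stats::setNames(rep(0.02, length(ids)), ids))
  out <- imputeRedoxMedians(model, thermo, defaultCofactors())
  expect_equal(dG0(out)[["DX"]], 4)
  expect_equal(unname(dG0Tags(out)["DX"]), "median_imputed")
  expect_equal(dG0(out)[c("D1", "D2", "D3")], c(D1 = 2, D2 = 4, D3 = 9))
  ## all annotated: nothing changes
  out2 <- imputeRedoxMedians(model, out, defaultCofactors())
  expect_equal(dG0(out2), dG0(out))
  ## no computed value for a needed species: error naming it
  thermoNadp <- thermoAnnotation(
    dG0 = numeric(0),
    cMin = stats::setNames(rep(1e-6, length(ids)), ids),
    cMax = stats::setNames(rep(0.02, length(ids)), ids))
  expect_error(imputeRedoxMedians(model, thermoNadp, defaultCofactors()),
               "imputation error.*nad_c")
})

test_that("cofactor duplication builds variants and groups", {
  tc <- redoxTcosa()
  groups <- variantGroups(tc)
  expect_setequal(groups$R2, c("R2_ORIGINAL_NAD_TCOSA", "R2_VARIANT_NADP_TCOSA"))
  expect_setequal(groups$R3, c("R3_ORIGINAL_NADP_TCOSA", "R3_VARIANT_NAD_TCOSA"))
  expect_identical(groups$BM, "BM")
  expect_identical(dualCofactorReactions(tc), "BM")
  ## the variant only differs by the cofactor substitution
  s0 <- stoichiometry(tc, "R2_ORIGINAL_NAD_TCOSA")
  s1 <- stoichiometry(tc, "R2_VARIANT_NADP_TCOSA")
  expect_equal(s1[["nadp_c"]], s0[["nad_c"]])
  expect_equal(s1[["nadph_c"]], s0[["nadh_c"]])
  carbon0 <- s0[setdiff(names(s0), c("nad_c", "nadh_c"))]
  carbon1 <- s1[setdiff(names(s1), c("nadp_c", "nadph_c"))]
  expect_equal(carbon1, carbon0)
  ## identical bounds and dG0
  rx <- reactions(tc)
  expect_equal(rx$ub[rx$id == "R2_VARIANT_NADP_TCOSA"],
               rx$ub[rx$id == "R2_ORIGINAL_NAD_TCOSA"])
  expect_equal(dG0(tc)[["R2_VARIANT_NADP_TCOSA"]], dG0(tc)[["R2_ORIGINAL_NAD_TCOSA"]])
})

test_that("a reversible redox reaction yields four variants in its group", {
  tc <- buildToyTcosa(toyNetworkSpec(2, stepDG0 = c(-5, -10),
                                     stepRedox = c(NA, "NADP_red"),
                                     stepReversible = c(FALSE, TRUE)))
  g <- variantGroups(tc)$R2
  expect_length(g, 4)
  expect_setequal(g, c("R2_FWD_ORIGINAL_NADP_TCOSA", "R2_FWD_VARIANT_NAD_TCOSA",
                       "R2_REV_ORIGINAL_NADP_TCOSA", "R2_REV_VARIANT_NAD_TCOSA"))
  ## dG0 antisymmetry across the split, equality across the swap
  dg <- dG0(tc)
  expect_equal(dg[["R2_FWD_ORIGINAL_NADP_TCOSA"]], -10)
  expect_equal(dg[["R2_REV_ORIGINAL_NADP_TCOSA"]], 10)
  expect_equal(dg[["R2_FWD_VARIANT_NAD_TCOSA"]], dg[["R2_FWD_ORIGINAL_NADP_TCOSA"]])
})

test_that("redox-potential conversion follows -nF dE", {
  expect_equal(redoxPotentialToDGShift(-320, 2), 61.7504)
  expect_equal(redoxPotentialToDGShift(0, 2), 0)
  expect_equal(redoxPotentialToDGShift(155, 2), -2 * 96.485 * 0.155)
  expect_error(redoxPotentialToDGShift(-320, 0))
})

test_that("triplication adds a third variant with the potential-shifted dG0", {
  toy <- generateToy(toyRedoxFixtureSpec())
  tc0 <- buildTcosaModel(toy$model, toy$thermo, defaultCofactors(nadz = TRUE),
                         dEShift_mV = 0)
  expect_length(variantGroups(tc0)$R2, 3)
  expect_equal(dG0(tc0)[["R2_VARIANT_NADZ_TCOSA"]],
               dG0(tc0)[["R2_ORIGINAL_NAD_TCOSA"]])
  tc <- buildTcosaModel(toy$model, toy$thermo, defaultCofactors(nadz = TRUE),
                        dEShift_mV = -155)
  ## lower potential: reducing the new cofactor is harder by ~30 kJ/mol
  expect_equal(dG0(tc)[["R2_VARIANT_NADZ_TCOSA"]] - dG0(tc)[["R2_ORIGINAL_NAD_TCOSA"]],
               29.91035, tolerance = 1e-6)
  ## and oxidizing its reduced form easier by the same amount (R3 consumes
  ## the reduced species)
  expect_equal(dG0(tc)[["R3_VARIANT_NADZ_TCOSA"]] - dG0(tc)[["R3_ORIGINAL_NADP_TCOSA"]],
               -29.91035, tolerance = 1e-6)
  ## NADZ metabolites were added with pool-1 concentration bounds
  expect_true(all(c("nadz_c", "nadzh_c") %in% metabolites(tc)$id))
})

test_that("minimal relaxation identifies exactly the insurmountable reaction", {
  tc <- chainTcosa(2, dG0 = c(0, 200))
  out <- relaxToFeasibility(tc, demandedGrowth = 1)
  expect_identical(out$relaxed, "R2")
  expect_equal(unname(dG0Tags(out$model)["R2"]), "relaxed")
  expect_false(thermoActive(out$model)[["R2"]])
  post <- solveMdf(out$model, list(growthMin = 1))
  expect_gte(mdfValue(post), 0.1)
  ## brute force over single-reaction relaxations: only R2 works
  for (id in c("R1", "SINK_P")) {
    ta <- thermoActive(tc); ta[id] <- FALSE
    alt <- methods::initialize(tc, thermoActive = ta)
    s <- solveMdf(alt, list(growthMin = 1))
    expect_lt(mdfValue(s), 0.1)
  }
  ## already feasible: empty relaxation
  expect_length(relaxToFeasibility(chainTcosa(2), 1)$relaxed, 0)
  ## stoichiometric infeasibility is a distinct error
  expect_error(relaxToFeasibility(tc, demandedGrowth = 100),
               "stoichiometrically infeasible")
})
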