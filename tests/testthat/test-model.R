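test_that("the association model parses into the expected structure", {
  spec <- parseModel(modelAssociation)
  expect_equal(spec@observed, c("P1", "P2", "P3"))
  expect_equal(spec@latent, "L1")
  expect_equal(spec@covariates, "rs6040343")
  expect_equal(spec@components, c("p", "e"))
  expect_setequal(spec@vc$L1, c("p", "e"))
  expect_equal(spec@vc$P1, "e")
})

test_that("constraints land in fixed slots and free lists", {
  mm3 <- buildModelMatrices(parseModel(modelMultiLevel))
  ## stress has both variances fixed at 0.1 and out of theta
  expect_false(any(grepl("var\\(stress", parameterTable(mm3)$name)))
  expect_equal(mm3@Psi_v$p["stress", "stress"], 0.1)
  expect_equal(mm3@Psi_v$e["stress", "stress"], 0.1)
  ## a fixed variance does not release the loading anchor: stress is
  ## doubly pinned (first loading 1 and variances 0.1), second loading free
  expect_equal(mm3@Lambda_v["S1", "stress"], 1)
  expect_false("stress=~S1" %in% parameterTable(mm3)$name)
  expect_true("stress=~S2" %in% parameterTable(mm3)$name)

  mm4 <- buildModelMatrices(parseModel(modelPleiotropy))
  ## fixed path g1 -> z1 = 1, free path g1 -> z2
  expect_equal(mm4@B_v["z1", "g1"], 1)
  expect_equal(mm4@B_i["z1", "g1"], 0)
  expect_true("z2~g1" %in% parameterTable(mm4)$name)
})

test_that("default anchoring fixes the first loading to 1", {
  mm <- buildModelMatrices(parseModel(modelAssociation))
  expect_equal(mm@Lambda_v["P1", "L1"], 1)
  expect_equal(mm@Lambda_i["P1", "L1"], 0)
  expect_true(all(c("L1=~P2", "L1=~P3") %in% parameterTable(mm)$name))
  ## a latent with no indicators, no fixed path and no fixed variance
  ## cannot have its scale set
  expect_error(buildModelMatrices(parseModel(
    "latent(g)\nL1 =~ y1 + y2\nL1 ~ g\ng ~ <e>\nL1 ~ <e>")), "scale")
  ## observed ~ latent is an alternative spelling of a measurement edge
  alt <- buildModelMatrices(parseModel("latent(g)\ny1 ~ g\ny2 ~ g\ng ~ <e>"))
  expect_equal(alt@Lambda_v["y1", "g"], 1)
})

test_that("parse -> serialize -> parse is idempotent", {
  for (txt in canonicalModels()) {
    s1 <- parseModel(txt)
    s2 <- parseModel(serializeModel(s1))
    for (sl in c("observed", "latent", "covariates", "components", "vc"))
      expect_equal(methods::slot(s1, sl), methods::slot(s2, sl), info = sl)
    expect_equal(s1@measurement, s2@measurement)
    expect_equal(s1@structural[order(s1@structural$lhs, s1@structural$rhs), ],
                 s2@structural[order(s2@structural$lhs, s2@structural$rhs), ],
                 ignore_attr = TRUE)
  }
})

test_that("syntax errors carry line context; bad labels refused", {
  expect_error(parseModel("L1 =~ "), "measurement")
  expect_error(parseModel("P1 ~ <z>"), "component label")
  expect_error(parseModel("var(Q9, e) = 1\nP1 ~ <e>"), "declared component")
  expect_error(parseModel("coef(a, b) = 1\nP1 ~ <e>"), "does not match")
  expect_error(parseModel(""), "empty")
})

test_that("model matrices follow the LISREL-with-covariates layout", {
  mm <- buildModelMatrices(parseModel(modelAssociation))
  th <- thetaOne(mm)
  ev <- mmEval(mm, th)
  expect_equal(dim(ev$Lambda), c(3, 1))
  expect_equal(dim(ev$B), c(1, 1))
  expect_equal(unname(ev$B[1, 1]), 0)
  expect_equal(dim(ev$Ge), c(1, 1))
  expect_equal(unname(ev$Theta$e), diag(3), ignore_attr = TRUE)
  expect_equal(unname(ev$Psi$p[1, 1]), 1)
  ## p-component has no observed-level residual block
  expect_true(all(ev$Theta$p == 0))

  ## CFA with no structural part: (I - B)^{-1} = I
  cfa <- buildModelMatrices(parseModel("F1 =~ y1 + y2 + y3"))
  evc <- mmEval(cfa, thetaOne(cfa))
  expect_true(all(evc$B == 0))
})

test_that("roles partition the free parameters", {
  for (txt in canonicalModels()) {
    pt <- parameterTable(buildModelMatrices(parseModel(txt)))
    expect_true(all(pt$role %in% c("CO", "IN", "VC")))
    ## loadings and covariate slopes are CO, intercepts IN, variances VC
    expect_true(all(grepl("~1$", pt$name[pt$role == "IN"])))
    expect_true(all(grepl("^(var|cov)\\(", pt$name[pt$role == "VC"])))
    expect_false(any(grepl("^(var|cov)\\(", pt$name[pt$role == "CO"])))
  }
})

test_that("identification: df and rank verdicts", {
  for (txt in canonicalModels()) {
    mm <- buildModelMatrices(parseModel(txt))
    idc <- checkIdentification(mm)
    expect_gte(idc$df, 0)
    expect_true(idc$identified)
  }
  ## saturated single-trait model: df = 0
  sat <- buildModelMatrices(parseModel("y ~ <e>"))
  expect_equal(checkIdentification(sat)$df, 0)
  ## two aliased latents: df >= 0 but rank-deficient Jacobian
  alias <- buildModelMatrices(parseModel(paste(
    "L1 =~ y1 + y2 + y3 + y4 + y5 + y6",
    "L2 =~ y1 + y2 + y3 + y4 + y5 + y6",
    "L1 ~ <e>", "L2 ~ <e>", sep = "\n")))
  idc <- checkIdentification(alias)
  expect_gte(idc$df, 0)
  expect_false(idc$identified)
  ## negative df is an explicit under-identification error
  expect_error(checkIdentification(buildModelMatrices(parseModel(
    "L1 =~ y1 + y2 + y3\nL2 =~ y1 + y2 + y3\nL1 ~ <e>\nL2 ~ <e>"))),
    "under-identified")
})

test_that("constraint values never appear in theta", {
  mm <- buildModelMatrices(parseModel(modelMultiLevel))
  th <- thetaOne(mm, c(`bp~anger` = 0.4))
  ev <- mmEval(mm, th)
  expect_equal(ev$Psi$p["stress", "stress"], 0.1)
  expect_equal(ev$B["bp", "anger"], 0.4)
  expect_equal(nrow(parameterTable(mm)), length(th))
})
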