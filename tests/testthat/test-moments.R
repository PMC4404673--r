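test_that("implied component covariances match hand algebra", {
  mm <- buildModelMatrices(parseModel(modelAssociation))
  th <- thetaOne(mm)
  J3 <- matrix(1, 3, 3)
  expect_equal(impliedComponentCovariance(mm, th, "e"), J3 + diag(3),
               ignore_attr = TRUE)
  expect_equal(impliedComponentCovariance(mm, th, "p"), J3,
               ignore_attr = TRUE)
  ## B = 0, Lambda = I, Psi = 0 degenerates to Theta
  plain <- buildModelMatrices(parseModel("y1 ~ <e>\ny2 ~ <e>"))
  thp <- thetaOne(plain, c(`var(y1,e)` = 2, `var(y2,e)` = 3))
  expect_equal(impliedComponentCovariance(plain, thp, "e"), diag(c(2, 3)),
               ignore_attr = TRUE)
  expect_error(impliedComponentCovariance(mm, th, "c"), "unknown component")
})

test_that("implied means follow path tracing", {
  mm <- buildModelMatrices(parseModel(modelAssociation))
  th <- thetaOne(mm, c(`L1=~P2` = 0.5, `L1~rs6040343` = 2, `P3~1` = -1))
  mu <- impliedMean(mm, th, x = 1)
  ## mu_i = nu_i + lambda_i * gamma * x
  expect_equal(unname(mu), c(1 + 1 * 2, 1 + 0.5 * 2, -1 + 1 * 2))
  expect_equal(unname(impliedMean(mm, thetaOne(mm, c(`P1~1` = 0,
    `P2~1` = 0, `P3~1` = 0)), x = 0)), c(0, 0, 0))
  expect_error(impliedMean(mm, th, x = NA_real_), "missing")

  ## multi-level path: slope of SBP on the SNP is the product of the
  ## path coefficients summed over directed paths SNP -> stress -> bp -> SBP
  mm3 <- buildModelMatrices(parseModel(modelMultiLevel))
  th3 <- thetaOne(mm3, c(`stress~rs6040343` = 0.7, `bp~stress` = 0.6,
                         `bp=~DBP` = 0.9, `bp~anger` = 0.4,
                         `stress~anger` = 0.2))
  s <- momentMap(mm3, th3)
  expect_equal(unname(s["SBP~rs6040343"]), 0.7 * 0.6 * 1)
  expect_equal(unname(s["DBP~rs6040343"]), 0.7 * 0.6 * 0.9)
  expect_equal(unname(s["A1~rs6040343"]), 0)
})

test_that("Kronecker assembly equals the element-wise brute force", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 3; t <- 2
    rnd <- function(d) { A <- matrix(rnorm(d * d), d); crossprod(A) / d }
    V <- list(p = rnd(t), e = rnd(t))
    R <- list(p = rnd(n), e = rnd(n))
    S <- assemblePedigreeCovariance(V, R)
    expect_equal(S, t(S))
    brute <- matrix(0, n * t, n * t)
    for (i in 1:n) for (j in 1:n) for (a in 1:t) for (b in 1:t)
      brute[(i - 1) * t + a, (j - 1) * t + b] <-
        R$p[i, j] * V$p[a, b] + R$e[i, j] * V$e[a, b]
    expect_equal(S, brute)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  ## closed form: one trait, full sibs, sigma_p = sigma_e = 1
  S <- assemblePedigreeCovariance(
    list(p = matrix(1), e = matrix(1)),
    list(p = matrix(c(1, .5, .5, 1), 2), e = diag(2)))
  expect_equal(S, matrix(c(2, .5, .5, 2), 2))
  ## single individual: sum of component covariances
  S1 <- assemblePedigreeCovariance(list(p = matrix(2), e = matrix(3)),
                                   list(p = matrix(1), e = matrix(1)))
  expect_equal(S1, matrix(5))
  expect_error(assemblePedigreeCovariance(list(p = matrix(1)),
                                          list(e = matrix(1))), "names")
})

test_that("moment map is a pure function of theta with documented order", {
  mm <- buildModelMatrices(parseModel(modelAssociation))
  th <- thetaOne(mm)
  s <- momentMap(mm, th)
  expect_equal(names(s), momentNames(mm))
  expect_equal(unname(s[c("var(P1,p)", "var(P1,e)")]), c(1, 2))
  expect_equal(unname(s["cov(P1,P2,p)"]), 1)
  expect_equal(unname(s["P2~rs6040343"]), 1)
  ## repeated evaluation identical (no hidden state)
  expect_identical(s, momentMap(mm, th))

  ## linkage model at theta = 1: a-component covariance of each pair = 1
  mm2 <- buildModelMatrices(parseModel(modelLinkage))
  s2 <- momentMap(mm2, thetaOne(mm2))
  expect_equal(unname(s2["cov(P1,P2,a(m2))"]), 1)

  ## saturated model reproduces an arbitrary target exactly
  sat <- buildModelMatrices(parseModel(
    "y1 ~ <p,e>\ny2 ~ <p,e>\ncov(y1, y2, p)\ncov(y1, y2, e)"))
  target <- c(0.3, -0.2, 1.2, 0.8, 0.9, 1.1, 0.25, -0.1)
  nmT <- momentNames(sat)
  pt <- parameterTable(sat)$name
  thT <- setNames(target[match(pt, nmT)], pt)
  expect_equal(unname(momentMap(sat, thT)), target)
})

test_that("the fast sigma evaluator matches the reference moment map", {
  for (txt in canonicalModels()) {
    mm <- buildModelMatrices(parseModel(txt))
    sig <- pedsem:::.makeSigma(mm)
    set.seed(11)
    for (i in 1:5) {
      th <- thetaOne(mm) + rnorm(nFreeParameters(mm), 0, 0.3)
      expect_equal(sig(th), unname(momentMap(mm, th)), tolerance = 1e-12)
    }
  }
})

test_that("moment Jacobian: indicator columns, analytic loading check, rank", {
  mm <- buildModelMatrices(parseModel(modelAssociation))
  th <- thetaOne(mm)
  J <- momentJacobian(mm, th)
  ## a residual variance slot has a pure 0/1 indicator column
  jcol <- J[, "var(P2,e)"]
  expect_equal(unname(jcol[names(jcol) == "var(P2,e)"]), 1)
  expect_equal(sum(abs(jcol)), 1)
  ## d var(P2,p) / d lambda_2 = 2 * lambda_2 * psi_p (analytic)
  th2 <- thetaOne(mm, c(`L1=~P2` = 0.7, `var(L1,p)` = 1.3))
  J2 <- momentJacobian(mm, th2)
  expect_equal(unname(J2["var(P2,p)", "L1=~P2"]), 2 * 0.7 * 1.3,
               tolerance = 1e-6)
  ## identified model: full column rank
  sv <- svd(J)$d
  expect_gt(min(sv), 1e-8 * max(sv))
})
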