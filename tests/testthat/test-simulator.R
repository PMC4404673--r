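test_that("synthetic panel hits target MAF and adjacent LD", {
  p0 <- generateSyntheticPanel(10, 2000, mafRange = c(0.3, 0.3),
                               r2Adjacent = 0, seed = 3)
  f <- alleleFrequencies(p0)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_true(all(abs(f - 0.3) < 3.5 * se))
  ## r2 = 0: empirical adjacent r2 small
  H <- p0@haplotypes
  r2 <- vapply(seq_len(9), function(j) cor(H[, j], H[, j + 1])^2, 1)
  expect_lt(max(r2), 0.05)

  p1 <- generateSyntheticPanel(10, 2000, mafRange = c(0.3, 0.3),
                               r2Adjacent = 0.4, seed = 4)
  H1 <- p1@haplotypes
  r21 <- vapply(seq_len(9), function(j) cor(H1[, j], H1[, j + 1])^2, 1)
  expect_true(all(abs(r21 - 0.4) < 0.1))

  ## determinism and infeasibility
  expect_identical(generateSyntheticPanel(5, 50, seed = 9),
                   generateSyntheticPanel(5, 50, seed = 9))
  expect_error(generateSyntheticPanel(5, 50, mafRange = c(0.02, 0.45),
                                      r2Adjacent = 0.9, seed = 1),
               "infeasible")
})

test_that("panel text round trip is lossless", {
  p <- generateSyntheticPanel(4, 20, seed = 5)
  path <- tempfile(fileext = ".txt")
  writePanel(p, path)
  back <- readPanel(path)
  expect_equal(back@markers, p@markers)
  expect_equal(unname(back@haplotypes), unname(p@haplotypes))
})

test_that("gene dropping is Mendelian and matches panel frequencies", {
  panel <- generateSyntheticPanel(3, 400, mafRange = c(0.25, 0.35),
                                  r2Adjacent = 0.2, seed = 6)
  trio <- nuclearPed("T", 1)
  copies <- PedigreeSet(rep(list(trio), 3000))
  drop <- geneDrop(copies, panel, seed = 7)
  f <- alleleFrequencies(panel)
  ## founder allele frequency reproduces the panel's
  founderG <- t(vapply(drop$genotypes, function(g) g[1:2, 1], numeric(2)))
  fhat <- mean(founderG) / 2
  expect_lt(abs(fhat - f[1]), 3.5 * sqrt(f[1] * (1 - f[1]) / (2 * 6000)))
  ## both parents 0 => child 0 with certainty
  mendel <- vapply(drop$genotypes, function(g)
    all(g[3, g[1, ] == 0 & g[2, ] == 0] == 0), TRUE)
  expect_true(all(mendel))
  ## parent-offspring additive-genotype correlation about 0.5
  pg <- vapply(drop$genotypes, function(g) g[1, 2], 1)
  kg <- vapply(drop$genotypes, function(g) g[3, 2], 1)
  expect_lt(abs(cor(pg, kg) - 0.5), 3.5 / sqrt(3000))
  ## determinism
  drop2 <- geneDrop(copies, panel, seed = 7)
  expect_identical(drop$genotypes[[17]], drop2$genotypes[[17]])
})

test_that("true IBD from descent labels behaves like IBD", {
  panel <- generateSyntheticPanel(2, 50, seed = 8)
  sibs <- nuclearPed("S", 2)
  copies <- PedigreeSet(rep(list(sibs), 4000))
  drop <- geneDrop(copies, panel, seed = 9)
  pis <- vapply(seq_len(4000), function(k)
    trueIBDMatrix(sibs, drop$labels[[k]], "m1")["k1", "k2"], 1)
  ## full sibs share 0, 1/2 or 1 with mean 1/2
  expect_true(all(pis %in% c(0, 0.5, 1)))
  expect_lt(abs(mean(pis) - 0.5), 3.5 * sqrt(0.125 / 4000))
  ## founder pairs share nothing; diagonal is exactly 1
  m <- trueIBDMatrix(sibs, drop$labels[[1]], "m1")
  expect_equal(unname(m["f", "m"]), 0)
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_error(trueIBDMatrix(sibs, drop$labels[[1]], "nope"), "marker")
  ## IBDData store round trip through the CSV dialect
  ibd <- trueIBD(PedigreeSet(list(sibs)), drop$labels[1], c("m1", "m2"))
  path <- tempfile(fileext = ".csv")
  writeIBD(ibd, path)
  expect_equal(readIBD(path)@table$pi, ibd@table$pi)
})

test_that("phenotype simulation matches the model-implied moments", {
  panel <- testPanel()
  mm <- buildModelMatrices(parseModel(modelAssociation))
  th <- thetaOne(mm)
  cfg <- simulationConfig("nuclear75", 600, modelAssociation, th, panel,
                          seed = 12)
  dat <- simulatePedigreeData(cfg)
  Y <- do.call(rbind, lapply(dat$peds, phenotypes))
  G <- do.call(rbind, lapply(dat$peds, genotypes))[, "rs6040343"]
  n <- nrow(Y)
  ## marginal variance of P1: slope^2 var(g) + Vp[1,1] + Ve[1,1]
  expVar <- var(G) * 1 + 1 + 2
  expect_lt(abs(var(Y[, "P1"]) - expVar), 3.5 * expVar * sqrt(2 / n) * 1.5)
  ## regression of P1 on genotype about the implied slope 1
  expect_lt(abs(coef(lm(Y[, "P1"] ~ G))[2] - 1), 0.12)
  ## full-sib covariance of the single-trait polygenic model = 0.5
  m0 <- "P1 ~ <p,e>"
  mm0 <- buildModelMatrices(parseModel(m0))
  cfg0 <- simulationConfig(PedigreeSet(list(nuclearPed("N", 2))), 6000, m0,
                           thetaOne(mm0, c(`P1~1` = 0)), panel, seed = 13)
  dat0 <- simulatePedigreeData(cfg0)
  sib <- t(vapply(dat0$peds, function(p) p@phenotypes[c("k1", "k2"), 1],
                  numeric(2)))
  expect_lt(abs(cov(sib[, 1], sib[, 2]) - 0.5), 3.5 * 1.6 / sqrt(6000))
  ## all variance components zero: y deterministic in x (here constant)
  cfgD <- simulationConfig("extended5", 5, m0,
                           c(`P1~1` = 2, `var(P1,p)` = 0, `var(P1,e)` = 0),
                           panel, seed = 14)
  datD <- simulatePedigreeData(cfgD)
  expect_true(all(abs(do.call(rbind, lapply(datD$peds, phenotypes)) - 2) < 1e-12))
})

test_that("the simulator is a pure function of configuration and seed", {
  panel <- testPanel()
  cfg <- simulationConfig("extended5", 10, modelAssociation, 1, panel,
                          seed = 17)
  d1 <- simulatePedigreeData(cfg)
  d2 <- simulatePedigreeData(cfg)
  expect_identical(lapply(d1$peds, phenotypes), lapply(d2$peds, phenotypes))
  expect_identical(lapply(d1$peds, genotypes), lapply(d2$peds, genotypes))
  d3 <- simulatePedigreeData(simulationConfig("extended5", 10,
                                              modelAssociation, 1, panel,
                                              seed = 18))
  expect_false(identical(lapply(d1$peds, phenotypes),
                         lapply(d3$peds, phenotypes)))
})

test_that("simulated trait correlations match the assembled covariance", {
  panel <- testPanel()
  m0 <- "y ~ <p,e>"
  mm0 <- buildModelMatrices(parseModel(m0))
  th0 <- thetaOne(mm0, c(`y~1` = 0, `var(y,p)` = 1.5, `var(y,e)` = 0.5))
  ped <- threeGenPed("K")
  cfg <- simulationConfig(PedigreeSet(list(ped)), 4000, m0, th0, panel,
                          seed = 19)
  dat <- simulatePedigreeData(cfg)
  Y <- t(vapply(dat$peds, function(p) p@phenotypes[, 1], numeric(10)))
  emp <- cov(Y)
  pred <- assemblePedigreeCovariance(
    list(p = matrix(1.5), e = matrix(0.5)),
    list(p = relationshipMatrix(ped, "polygenic"),
         e = relationshipMatrix(ped, "environment")))
  expect_lt(max(abs(emp - pred)), 0.25)
})

test_that("ascertainment sampling calibrates to prevalence and retains correctly", {
  panel <- testPanel()
  m0 <- "P1 ~ <p,e>"
  mm0 <- buildModelMatrices(parseModel(m0))
  th <- thetaOne(mm0)
  thr <- affectionThreshold(mm0, th, panel, prevalence = 0.1,
                            nRef = 5e4, seed = 21)
  ## population affected fraction close to the prevalence
  cfg <- simulationConfig("nuclear75", 1500, m0, th, panel, seed = 22)
  dat <- simulatePedigreeData(cfg)
  scores <- unlist(lapply(dat$peds, function(p) p@phenotypes[, 1]))
  frac <- mean(scores > thr)
  expect_lt(abs(frac - 0.1), 3.5 * sqrt(0.09 / length(scores)) + 0.01)
  ## probandProbability = 1: every family with an affected member kept
  kept <- applyAscertainment(dat$peds, 0.1, 1, thr, seed = 23)
  hasAff <- sum(vapply(dat$peds, function(p)
    any(p@phenotypes[, 1] > thr), TRUE))
  expect_length(kept, hasAff)
  expect_true(all(vapply(kept, function(p) sum(p@members$proband) == 1, TRUE)))
  ## rare disease, weak ascertainment: most batches lose most pedigrees
  kept2 <- applyAscertainment(dat$peds, 0.001, 0.05,
                              affectionThreshold(mm0, th, panel, 0.001,
                                                 nRef = 5e4, seed = 24),
                              seed = 25)
  expect_lt(length(kept2), 0.5 * length(dat$peds))
})

test_that("simulation configs round trip through YAML", {
  panel <- generateSyntheticPanel(2, 12, seed = 26,
                                  markerNames = c("rs6040343", "m2"))
  cfg <- simulationConfig("extended5", 7, modelAssociation, 1, panel,
                          ascertainment = list(prevalence = 0.05,
                                               probandProbability = 0.1),
                          seed = 27)
  path <- tempfile(fileext = ".yaml")
  writeSimulationConfig(cfg, path)
  back <- readSimulationConfig(path)
  expect_equal(back@theta, cfg@theta)
  expect_equal(back@seed, cfg@seed)
  expect_equal(back@panel@haplotypes, cfg@panel@haplotypes)
  expect_equal(back@ascertainment$prevalence, 0.05)
  expect_equal(length(back@structures), length(cfg@structures))
  expect_equal(serializeModel(back@model), serializeModel(cfg@model))
  ## identical data from the reloaded config
  expect_identical(lapply(simulatePedigreeData(cfg)$peds, phenotypes),
                   lapply(simulatePedigreeData(back)$peds, phenotypes))
})
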