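test_that("pedigree CSV round-trips losslessly and splits families", {
  p1 <- nuclearPed("A", 3)
  p1@phenotypes <- matrix(rnorm(5 * 2), 5, 2,
                          dimnames = list(p1@members$id, c("y1", "y2")))
  p2 <- threeGenPed("B")
  p2@phenotypes <- matrix(rnorm(10 * 2), 10, 2,
                          dimnames = list(p2@members$id, c("y1", "y2")))
  path <- tempfile(fileext = ".csv")
  writePedigree(PedigreeSet(list(p1, p2)), path)
  back <- readPedigree(path, phenotypes = c("y1", "y2"))
  expect_length(back, 2)
  expect_equal(vapply(back, familyId, ""), c("A", "B"))
  expect_equal(back[[1]]@members, p1@members)
  expect_equal(back[[2]]@phenotypes, p2@phenotypes)
  ## second round trip is byte-identical
  path2 <- tempfile(fileext = ".csv")
  writePedigree(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("minimal trio reads; missing columns and unknown parents error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("family,id,father,mother,sex,y",
               "T,dad,0,0,1,1.0", "T,mum,0,0,2,2.0", "T,kid,dad,mum,1,3.0"),
             path)
  ped <- readPedigree(path)
  expect_length(ped, 1)
  expect_equal(pedSize(ped[[1]]), 3)
  expect_true(is.na(ped[[1]]@members$father[1]))
  expect_false(is.na(ped[[1]]@members$father[3]))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("fam,id,father,mother", "T,a,0,0"), bad)
  expect_error(readPedigree(bad), "family")

  ## a parent id absent from the family is auto-created with a warning
  orphan <- tempfile(fileext = ".csv")
  writeLines(c("family,id,father,mother,y",
               "T,kid,ghost,mum,1.0", "T,mum,0,0,2.0"), orphan)
  expect_warning(readPedigree(orphan), "ghost")
})

test_that("validatePedigree flags cycles, sex errors and multiple probands", {
  expect_equal(nrow(validatePedigree(nuclearPed())), 0)

  twoProb <- nuclearPed("P", 2)
  twoProb@members$proband <- c(FALSE, FALSE, TRUE, TRUE)
  d <- validatePedigree(twoProb)
  expect_equal(d$severity, "warning")
  expect_match(d$message, "proband")

  ## own-grandparent cycle must be refused at construction and flagged
  cyc <- data.frame(id = c("a", "b", "c"), father = c("c", "a", "b"),
                    mother = c("c", "a", "b"))
  expect_error(Pedigree("C", cyc), "cyclic")

  sexErr <- nuclearPed("S", 1)
  sexErr@members$sex[1] <- "female"   # father recorded as female
  d <- validatePedigree(sexErr)
  expect_true(any(d$severity == "error" & grepl("father", d$message)))
})

test_that("kinship matrix matches textbook closed forms", {
  ped <- threeGenPed()
  phi <- kinshipMatrix(ped)
  expect_equal(phi, t(phi))
  expect_equal(unname(phi["gf", "gm"]), 0)        # founder couple
  expect_equal(unname(diag(phi)), rep(0.5, 10))   # non-inbred
  expect_equal(unname(phi["gf", "c1"]), 0.25)     # parent-offspring
  expect_equal(unname(phi["c1", "c2"]), 0.25)     # full sibs
  expect_equal(unname(phi["g1", "g2"]), 0.25)
  expect_equal(unname(phi["g1", "g3"]), 0.0625)   # first cousins

  ## half sibs
  hs <- Pedigree("H", data.frame(id = c("f", "m1", "m2", "k1", "k2"),
                                 father = c(NA, NA, NA, "f", "f"),
                                 mother = c(NA, NA, NA, "m1", "m2")))
  expect_equal(unname(kinshipMatrix(hs)["k1", "k2"]), 0.125)

  ## full-sib mating: offspring self-kinship (1 + 0.25) / 2
  loop <- Pedigree("L", data.frame(
    id = c("f", "m", "s", "d", "x"),
    father = c(NA, NA, "f", "f", "s"),
    mother = c(NA, NA, "m", "m", "d")))
  expect_equal(unname(kinshipMatrix(loop)["x", "x"]), 0.625)
})

test_that("kinship properties hold on random pedigrees", {
  for (seed in 1:20) {
    ped <- randomPed(sample(6:12, 1), seed = seed)
    phi <- kinshipMatrix(ped)
    expect_equal(phi, t(phi))
    expect_true(all(phi >= 0 & phi <= 1))
    ev <- eigen(2 * phi, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)                  # 2*Phi PSD
    founders <- is.na(ped@members$father)
    expect_equal(unname(diag(phi)[founders]),
                 rep(0.5, sum(founders)))
  }
})

test_that("kinship recursion agrees with the gene-drop Monte-Carlo oracle", {
  nDrops <- 20000
  for (seed in c(99, 7)) {
    ped <- randomPed(if (seed == 99) 10 else 8, seed = seed)
    est <- geneDropKinshipOracle(ped, nDrops, seed = seed + 1)
    phi <- kinshipMatrix(ped)
    ## conservative MC band (allele-pair indicators are correlated)
    tol <- 4 * sqrt(0.25 / nDrops) + 2e-3
    expect_lt(max(abs(est - phi)), tol)
  }
})

test_that("relationship matrices implement the four component couplings", {
  ped <- nuclearPed("F", 2)
  expect_equal(relationshipMatrix(ped, "environment"),
               diag(1, 4), ignore_attr = TRUE)
  Rp <- relationshipMatrix(ped, "polygenic")
  expect_equal(unname(Rp[c("k1"), c("k2")]), 0.5)
  expect_equal(unname(diag(Rp)), rep(1, 4))
  ## whole family is one household when no household codes exist
  expect_equal(relationshipMatrix(ped, "household"),
               matrix(1, 4, 4), ignore_attr = TRUE)
  hh <- ped
  hh@members$household <- c("h1", "h1", "h1", "h2")
  Rh <- relationshipMatrix(hh, "household")
  expect_equal(unname(Rh[1, 4]), 0)
  expect_equal(unname(Rh[1, 2]), 1)
  expect_error(relationshipMatrix(ped, "linkage"), "ibd")
})

test_that("IBD store is symmetric, validated and complete-on-lookup", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("family,marker,id1,id2,pi", "F1,rs1,a,b,0.5"), path)
  ibd <- readIBD(path)
  m <- ibdMatrix(ibd, "F1", "rs1", c("a", "b"))
  expect_equal(m, matrix(c(1, .5, .5, 1), 2), ignore_attr = TRUE)
  ## reversed pair order resolves via symmetric storage
  m2 <- ibdMatrix(ibd, "F1", "rs1", c("b", "a"))
  expect_equal(unname(m2[1, 2]), 0.5)
  ## missing pair is an error, never imputed
  expect_error(ibdMatrix(ibd, "F1", "rs1", c("a", "b", "c")), "no IBD entry")
  ## out-of-range pi refused
  bad <- tempfile(fileext = ".csv")
  writeLines(c("family,marker,id1,id2,pi", "F1,rs1,a,b,1.3"), bad)
  expect_error(readIBD(bad), "\\[0, 1\\]")
  ## empty store reads fine; linkage request then fails upstream
  empty <- tempfile(fileext = ".csv")
  writeLines("family,marker,id1,id2,pi", empty)
  expect_equal(nrow(readIBD(empty)@table), 0)
})

test_that("the packaged example file holds 75 nuclear families, 477 individuals", {
  path <- system.file("extdata", "nuclear75_synthetic.csv",
                      package = "pedsem")
  peds <- readPedigree(path, phenotypes = c("P1", "P2", "P3"),
                       genotypes = "rs6040343")
  expect_length(peds, 75)
  expect_equal(sum(vapply(peds, pedSize, 1)), 477)
  expect_true(all(vapply(peds, function(p)
    sum(is.na(p@members$father)) == 2, TRUE)))   # two founders per family
  expect_true(all(unlist(lapply(peds, genotypes)) %in% 0:2))
})

test_that("preset structures carry the documented totals", {
  nuc <- pedigreePreset("nuclear75")
  expect_length(nuc, 75)
  expect_equal(sum(vapply(nuc, pedSize, 1)), 477)
  sibs <- vapply(nuc, pedSize, 1) - 2
  expect_true(all(sibs >= 4 & sibs <= 11))
  ext <- pedigreePreset("extended5")
  expect_length(ext, 5)
  expect_equal(sum(vapply(ext, pedSize, 1)), 50)
  ## every extended structure spans three generations
  gens <- vapply(ext, function(p) {
    m <- p@members
    depth <- setNames(rep(1L, nrow(m)), m$id)
    for (i in seq_len(nrow(m)))
      if (!is.na(m$father[i]))
        depth[i] <- 1L + max(depth[m$father[i]], depth[m$mother[i]])
    max(depth)
  }, 1L)
  expect_true(all(gens >= 3))
})
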