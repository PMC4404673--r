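## Shared fixtures: the four canonical analysis models (association with
## a latent trait, IBD linkage with a latent trait, multi-level SEM with
## polygenic effects, CFA with a pleiotropic SNP factor), a small
## synthetic founder panel, and tiny pedigree builders.

modelAssociation <- "
L1 =~ P1 + P2 + P3
L1 ~ rs6040343 + <p,e>
P1 ~ <e>
P2 ~ <e>
P3 ~ <e>
"

modelLinkage <- "
L1 =~ P1 + P2 + P3
L1 ~ <a(m2),p,e>
P1 ~ <e>
P2 ~ <e>
P3 ~ <e>
"

modelMultiLevel <- "
anger =~ A1 + A2
bp =~ SBP + DBP
stress =~ S1 + S2
bp ~ anger + stress + <p,e>
stress ~ anger + rs6040343 + <p,e>
anger ~ <p,e>
A1 ~ <p,e>
A2 ~ <p,e>
SBP ~ <p,e>
DBP ~ <p,e>
S1 ~ <p,e>
S2 ~ <p,e>
var(stress, p) = 0.1
var(stress, e) = 0.1
"

modelPleiotropy <- "
z1 =~ X1 + X2 + X3
z2 =~ X4 + X5 + X6
latent(g1)
z1 ~ g1
z2 ~ g1
g1 ~ rs6040343 + <p,e>
z1 ~ <e>
z2 ~ <e>
X1 ~ <e>
X2 ~ <e>
X3 ~ <e>
X4 ~ <e>
X5 ~ <e>
X6 ~ <e>
coef(g1, z1) = 1
"

canonicalModels <- function() {
  list(association = modelAssociation, linkage = modelLinkage,
       multilevel = modelMultiLevel, pleiotropy = modelPleiotropy)
}

## small panel containing the model SNP and the linkage marker
testPanel <- function(seed = 7) {
  generateSyntheticPanel(3, 200, mafRange = c(0.25, 0.4), r2Adjacent = 0.2,
                         seed = seed,
                         markerNames = c("m1", "rs6040343", "m2"))
}

thetaOne <- function(mm, overrides = NULL) {
  th <- setNames(rep(1, nFreeParameters(mm)), parameterTable(mm)$name)
  if (!is.null(overrides)) th[names(overrides)] <- overrides
  th
}

## founder couple + children
nuclearPed <- function(famId = "F1", nKids = 2) {
  Pedigree(famId, data.frame(
    id = c("f", "m", paste0("k", seq_len(nKids))),
    father = c(NA, NA, rep("f", nKids)),
    mother = c(NA, NA, rep("m", nKids)),
    sex = c("male", "female", rep("unknown", nKids)),
    stringsAsFactors = FALSE))
}

## three-generation pedigree: grandparents, two children (one married
## in), grandchildren including a first-cousin pair via two sibships
threeGenPed <- function(famId = "G1") {
  Pedigree(famId, data.frame(
    id = c("gf", "gm", "c1", "c2", "s1", "s2", "g1", "g2", "g3", "g4"),
    father = c(NA, NA, "gf", "gf", NA, NA, "c1", "c1", "s2", "s2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "s1", "s1", "c2", "c2"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "male", "female"),
    stringsAsFactors = FALSE))
}

## random valid pedigree: founders plus offspring of random earlier pairs
randomPed <- function(n, seed, famId = "R1") {
  stopifnot(n >= 3)
  set.seed(seed)
  id <- paste0("i", seq_len(n))
  father <- mother <- rep(NA_character_, n)
  sex <- c("male", "female", sample(c("male", "female"), n - 2, TRUE))
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) && length(females) && runif(1) < 0.75) {
      father[i] <- id[males[sample.int(length(males), 1)]]
      mother[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  Pedigree(famId, data.frame(id = id, father = father, mother = mother,
                             sex = sex, stringsAsFactors = FALSE))
}

## gene-drop Monte-Carlo estimate of the kinship matrix: drops one
## non-recombining marker through nDrops copies of the structure and
## averages descent-label identity over the four allele pairings
## (P(random allele of i IBD to random allele of j), valid under
## inbreeding; independent oracle for the kinship recursion)
geneDropKinshipOracle <- function(ped, nDrops, seed = 1) {
  panel <- generateSyntheticPanel(1, 4, mafRange = c(0.4, 0.45),
                                  r2Adjacent = 0, seed = seed)
  copies <- PedigreeSet(rep(list(ped), nDrops))
  drop <- geneDrop(copies, panel, recombination = FALSE, seed = seed)
  n <- pedSize(ped)
  acc <- matrix(0, n, n)
  for (b in seq_len(nDrops)) {
    a1 <- drop$labels[[b]][, 1, 1]
    a2 <- drop$labels[[b]][, 2, 1]
    acc <- acc + (outer(a1, a1, "==") + outer(a1, a2, "==") +
                  outer(a2, a1, "==") + outer(a2, a2, "==")) / 4
  }
  acc / nDrops
}
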