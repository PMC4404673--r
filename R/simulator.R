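## Integrated pedigree data simulator: synthetic founder haplotype
## panels, gene dropping with recombination and descent tracking, true
## IBD matrices, multi-component multivariate-normal trait simulation
## under an arbitrary model, and proband-based ascertainment sampling.
##
## Pedigrees sharing a structure are simulated in vectorized batches;
## this matters mostly for ascertainment sampling, where low prevalence
## means most simulated families are discarded.

## ---------------------------------------------------------------------
## Founder haplotype panel

#' Generate a synthetic phased haplotype panel
#'
#' First-order binary Markov chain per haplotype: marker allele
#' frequencies are drawn uniformly from \code{mafRange} and adjacent
#' markers are given correlation \eqn{\rho = \sqrt{r^2}} via transition
#' probabilities matched to the marginals, so the adjacent-pair
#' \eqn{r^2} equals the target exactly in expectation.  Combinations of
#' allele frequencies and \eqn{r^2} that admit no valid transition
#' probabilities raise a configuration error.
#'
#' @param nMarkers,nHaplotypes panel dimensions.
#' @param mafRange length-2 range for the coded (minor) allele
#'   frequency; allele 1 is the coded allele.
#' @param r2Adjacent target linkage-disequilibrium \eqn{r^2} between
#'   adjacent markers.
#' @param seed RNG seed (identical seeds give identical panels).
#' @param markerNames optional marker names (default m1, m2, ...).
#' @param spacingBp physical distance between adjacent markers in bp.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
generateSyntheticPanel <- function(nMarkers, nHaplotypes,
                                   mafRange = c(0.1, 0.45),
                                   r2Adjacent = 0.3, seed = 1,
                                   markerNames = NULL,
                                   spacingBp = 5e4) {
  stopifnot(nMarkers >= 1, nHaplotypes >= 2,
            mafRange[1] > 0, mafRange[2] < 0.5 + 1e-9,
            r2Adjacent >= 0, r2Adjacent < 1)
  rho <- sqrt(r2Adjacent)
  .withSeed(seed, {
    f <- runif(nMarkers, mafRange[1], mafRange[2])
    ## transition probabilities between adjacent markers
    if (nMarkers > 1) {
      s <- sqrt(f * (1 - f))
      f1 <- f[-nMarkers]; f2 <- f[-1]
      s1 <- s[-nMarkers]; s2 <- s[-1]
      ## cov(x1, x2) = rho * s1 * s2 fixes both conditionals
      p11 <- f2 + rho * s1 * s2 / f1        # P(x2=1 | x1=1)
      p10 <- f2 - rho * s1 * s2 / (1 - f1)
      if (any(p11 < 0 | p11 > 1 | p10 < 0 | p10 > 1))
        stop("infeasible MAF / r2 combination for the Markov panel ",
             "generator; lower r2Adjacent or narrow mafRange")
    }
    H <- matrix(0L, nHaplotypes, nMarkers)
    H[, 1] <- rbinom(nHaplotypes, 1, f[1])
    if (nMarkers > 1) {
      for (j in 2:nMarkers) {
        pj <- ifelse(H[, j - 1] == 1L, p11[j - 1], p10[j - 1])
        H[, j] <- rbinom(nHaplotypes, 1, pj)
      }
    }
    if (is.null(markerNames)) markerNames <- paste0("m", seq_len(nMarkers))
    markers <- data.frame(name = markerNames,
                          pos = seq_len(nMarkers) * spacingBp,
                          stringsAsFactors = FALSE)
    colnames(H) <- markerNames
    new("HaplotypePanel", markers = markers, haplotypes = H)
  })
}

#' Panel allele frequencies
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return named vector of coded-allele frequencies.
#' @export
alleleFrequencies <- function(panel) {
  setNames(colMeans(panel@haplotypes), panel@markers$name)
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@haplotypes), "haplotypes x",
      nrow(object@markers), "markers; MAF range",
      paste(round(range(alleleFrequencies(object)), 3), collapse = "-"), "\n")
})

#' Read/write a haplotype panel
#'
#' Text dialect: a header line \code{marker <names...>}, a line
#' \code{pos <bp positions...>}, then one haplotype per line as a string
#' of 0/1 characters.
#' @param path file path.
#' @export
writePanel <- function(panel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("marker", paste(panel@markers$name, collapse = " ")), con)
  writeLines(paste("pos", paste(panel@markers$pos, collapse = " ")), con)
  writeLines(apply(panel@haplotypes, 1, paste, collapse = ""), con)
  invisible(path)
}

#' @rdname writePanel
#' @param panel a \linkS4class{HaplotypePanel} (write) .
#' @export
readPanel <- function(path) {
  ln <- readLines(path)
  mk <- strsplit(ln[1], "\\s+")[[1]][-1]
  ps <- as.numeric(strsplit(ln[2], "\\s+")[[1]][-1])
  hp <- ln[-(1:2)]
  H <- do.call(rbind, lapply(strsplit(hp, ""), as.integer))
  colnames(H) <- mk
  new("HaplotypePanel",
      markers = data.frame(name = mk, pos = ps, stringsAsFactors = FALSE),
      haplotypes = H)
}

## ---------------------------------------------------------------------
## Pedigree structure presets

.nuclearFamily <- function(famId, nSibs) {
  ids <- c("f", "m", paste0("s", seq_len(nSibs)))
  Pedigree(famId, data.frame(
    id = ids,
    father = c(NA, NA, rep("f", nSibs)),
    mother = c(NA, NA, rep("m", nSibs)),
    sex = c("male", "female",
            rep(c("male", "female"), length.out = nSibs)),
    stringsAsFactors = FALSE))
}

## five 10-member three-generation structures (half-sib and cousin
## configurations included); stand-ins with the stated totals
.extendedStructures <- function() {
  ped <- function(famId, id, father, mother, sex)
    Pedigree(famId, data.frame(id = id, father = father, mother = mother,
                               sex = sex, stringsAsFactors = FALSE))
  list(
    ## cousin structure: grandparental couple, two married children,
    ## two grandchildren each
    ped("X1",
        c("gf", "gm", "c1", "c2", "s1", "s2", "g1", "g2", "g3", "g4"),
        c(NA, NA, "gf", "gf", NA, NA, "c1", "c1", "s2", "s2"),
        c(NA, NA, "gm", "gm", NA, NA, "s1", "s1", "c2", "c2"),
        c("male", "female", "male", "female", "female", "male",
          "male", "female", "male", "female")),
    ## half-sib structure: one father, two mothers, plus a third
    ## generation through one half-sib
    ped("X2",
        c("f", "m1", "m2", "h1", "h2", "h3", "h4", "sp", "g1", "g2"),
        c(NA, NA, NA, "f", "f", "f", "f", NA, "h1", "h1"),
        c(NA, NA, NA, "m1", "m1", "m2", "m2", NA, "sp", "sp"),
        c("male", "female", "female", "male", "female", "male",
          "female", "female", "male", "female")),
    ## three siblings, one with three children
    ped("X3",
        c("gf", "gm", "c1", "c2", "c3", "sp", "g1", "g2", "g3", "g4"),
        c(NA, NA, "gf", "gf", "gf", NA, "c1", "c1", "c1", "c1"),
        c(NA, NA, "gm", "gm", "gm", NA, "sp", "sp", "sp", "sp"),
        c("male", "female", "male", "female", "male", "female",
          "female", "male", "female", "male")),
    ## two sibships in generation two
    ped("X4",
        c("gf", "gm", "c1", "c2", "s1", "s2", "g1", "g2", "g3", "g4"),
        c(NA, NA, "gf", "gf", NA, NA, "c1", "c1", "c2", "c2"),
        c(NA, NA, "gm", "gm", NA, NA, "s1", "s1", "s2", "s2"),
        c("male", "female", "male", "male", "female", "female",
          "male", "female", "male", "female")),
    ## deep branch: grandchild with own child (three generations of
    ## transmissions)
    ped("X5",
        c("gf", "gm", "c1", "sp1", "g1", "g2", "g3", "sp2", "h1", "h2"),
        c(NA, NA, "gf", NA, "c1", "c1", "c1", NA, "g1", "g1"),
        c(NA, NA, "gm", NA, "sp1", "sp1", "sp1", NA, "sp2", "sp2"),
        c("male", "female", "male", "female", "male", "female",
          "male", "female", "female", "male"))
  )
}

#' Preset pedigree structures
#'
#' \code{"nuclear75"}: 75 nuclear families totalling 477 individuals,
#' sibship sizes 4 to 11 (68 families of 4 siblings plus one family each
#' of 5..11).  \code{"extended5"}: five 10-member three-generation
#' structures (50 individuals) including a half-sib and a cousin
#' configuration.
#'
#' @param name preset name.
#' @return A \linkS4class{PedigreeSet} of data-free structures.
#' @export
pedigreePreset <- function(name = c("nuclear75", "extended5")) {
  name <- match.arg(name)
  if (name == "nuclear75") {
    sizes <- c(rep(4, 69), 6:11)
    PedigreeSet(lapply(seq_along(sizes), function(i)
      .nuclearFamily(paste0("N", i), sizes[i])))
  } else {
    PedigreeSet(.extendedStructures())
  }
}

## recycle structures to n pedigrees with fresh unique family ids
.recycleStructures <- function(structures, n, prefix = "F") {
  idx <- rep(seq_along(structures), length.out = n)
  PedigreeSet(lapply(seq_len(n), function(k) {
    p <- structures[[idx[k]]]
    p@familyId <- paste0(prefix, k)
    p
  }))
}

## ---------------------------------------------------------------------
## Gene dropping

.structureSignature <- function(ped) {
  m <- ped@members
  paste(nrow(m), paste(match(m$father, m$id), collapse = ","),
        paste(match(m$mother, m$id), collapse = ","), sep = "|")
}

## transmit one gamete from a parent to B offspring at M markers
## hapA, hapB: B x M allele matrices; labA, labB: B x M label matrices
## rprob: length M-1 recombination fractions
.transmit <- function(hapA, hapB, labA, labB, rprob) {
  B <- nrow(hapA); M <- ncol(hapA)
  start <- rbinom(B, 1, 0.5)
  if (M == 1) {
    sel <- matrix(start, B, 1)
  } else {
    xo <- matrix(rbinom(B * (M - 1), 1, rep(rprob, each = B)), B)
    ## marker j accumulates crossovers in intervals 1..j-1
    acc <- outer(seq_len(M - 1), seq_len(M), function(i, j) as.numeric(i < j))
    sel <- (matrix(start, B, M) + xo %*% acc) %% 2
  }
  list(hap = hapA * (sel == 0) + hapB * (sel == 1),
       lab = labA * (sel == 0) + labB * (sel == 1))
}

#' Gene dropping through pedigrees
#'
#' Founders draw two phased haplotypes uniformly (with replacement) from
#' the panel; every meiosis transmits a recombinant of the parent's two
#' haplotypes under the Haldane model (recombination fraction
#' \eqn{(1 - e^{-2d})/2} at \eqn{d} Morgans, 1 cM/Mb by default).
#' Founder-haplotype descent labels are tracked per transmitted allele,
#' giving exact identity by descent at every marker.
#'
#' @param peds a \linkS4class{PedigreeSet} (structures; data ignored).
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param cMperMb genetic-map density.
#' @param recombination set \code{FALSE} to transmit whole haplotypes.
#' @param seed RNG seed.
#' @return list with \code{genotypes} (per pedigree, n x M coded-allele
#'   count matrix) and \code{labels} (per pedigree, n x 2 x M array of
#'   founder-haplotype labels).
#' @export
geneDrop <- function(peds, panel, cMperMb = 1, recombination = TRUE,
                     seed = 1) {
  M <- nrow(panel@markers)
  if (!M) stop("empty haplotype panel")
  H <- panel@haplotypes
  nhap <- nrow(H)
  d <- diff(panel@markers$pos) / 1e6 * cMperMb / 100   # Morgans
  rprob <- if (recombination) 0.5 * (1 - exp(-2 * d)) else rep(0, max(M - 1, 0))
  sig <- vapply(peds, .structureSignature, "")
  groups <- split(seq_along(peds), sig)
  genotypes <- vector("list", length(peds))
  labels <- vector("list", length(peds))
  .withSeed(seed, {
    for (grp in groups) {
      p1 <- peds[[grp[1]]]
      m <- p1@members
      n <- nrow(m)
      B <- length(grp)
      fa <- match(m$father, m$id)
      mo <- match(m$mother, m$id)
      hap1 <- hap2 <- lab1 <- lab2 <- vector("list", n)
      fCount <- 0L
      for (i in seq_len(n)) {
        if (is.na(fa[i])) {
          fCount <- fCount + 1L
          r1 <- sample.int(nhap, B, replace = TRUE)
          r2 <- sample.int(nhap, B, replace = TRUE)
          hap1[[i]] <- H[r1, , drop = FALSE]
          hap2[[i]] <- H[r2, , drop = FALSE]
          lab1[[i]] <- matrix(2L * fCount - 1L, B, M)
          lab2[[i]] <- matrix(2L * fCount, B, M)
        } else {
          tp <- .transmit(hap1[[fa[i]]], hap2[[fa[i]]],
                          lab1[[fa[i]]], lab2[[fa[i]]], rprob)
          tm <- .transmit(hap1[[mo[i]]], hap2[[mo[i]]],
                          lab1[[mo[i]]], lab2[[mo[i]]], rprob)
          hap1[[i]] <- tp$hap; lab1[[i]] <- tp$lab
          hap2[[i]] <- tm$hap; lab2[[i]] <- tm$lab
        }
      }
      for (b in seq_len(B)) {
        g <- matrix(0, n, M, dimnames = list(m$id, panel@markers$name))
        lab <- array(0L, c(n, 2, M),
                     dimnames = list(m$id, NULL, panel@markers$name))
        for (i in seq_len(n)) {
          g[i, ] <- hap1[[i]][b, ] + hap2[[i]][b, ]
          lab[i, 1, ] <- lab1[[i]][b, ]
          lab[i, 2, ] <- lab2[[i]][b, ]
        }
        genotypes[[grp[b]]] <- g
        labels[[grp[b]]] <- lab
      }
    }
  })
  list(genotypes = genotypes, labels = labels)
}

## maximal-matching IBD allele count between two label pairs
.ibdShare <- function(a1, a2, b1, b2) {
  if (a1 == b1) 1L + (a2 == b2)
  else if (a1 == b2) 1L + (a2 == b1)
  else if (a2 == b1 || a2 == b2) 1L
  else 0L
}

#' True IBD matrix from descent labels
#'
#' \eqn{\pi_{ij}} = (number of alleles shared identical by descent by i
#' and j at the marker) / 2, from the founder-haplotype labels tracked
#' during gene dropping; the diagonal is set to 1.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param labels n x 2 x M label array for this pedigree (from
#'   \code{\link{geneDrop}}).
#' @param marker marker name.
#' @return symmetric matrix with unit diagonal.
#' @export
trueIBDMatrix <- function(ped, labels, marker) {
  if (!(marker %in% dimnames(labels)[[3]]))
    stop("marker '", marker, "' not present in descent labels")
  lab <- labels[, , marker, drop = FALSE]
  n <- pedSize(ped)
  out <- diag(1, n)
  dimnames(out) <- list(ped@members$id, ped@members$id)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      out[i, j] <- out[j, i] <-
        .ibdShare(lab[i, 1, 1], lab[i, 2, 1], lab[j, 1, 1], lab[j, 2, 1]) / 2
  }
  out
}

#' Assemble an IBDData store from gene-drop labels
#'
#' @param peds a \linkS4class{PedigreeSet}.
#' @param labels list of label arrays parallel to \code{peds}.
#' @param markers marker names to include.
#' @return An \linkS4class{IBDData} covering every within-family pair.
#' @export
trueIBD <- function(peds, labels, markers) {
  rows <- vector("list", length(peds))
  for (k in seq_along(peds)) {
    p <- peds[[k]]
    ids <- p@members$id
    n <- length(ids)
    if (n < 2) next
    ut <- which(upper.tri(diag(n)))
    ri <- row(diag(n))[ut]; ci <- col(diag(n))[ut]
    rows[[k]] <- do.call(rbind, lapply(markers, function(mk) {
      pim <- trueIBDMatrix(p, labels[[k]], mk)
      data.frame(family = p@familyId, marker = mk,
                 id1 = ids[ri], id2 = ids[ci], pi = pim[ut],
                 stringsAsFactors = FALSE)
    }))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  IBDData(if (length(rows)) do.call(rbind, rows) else NULL)
}
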