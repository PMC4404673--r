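## Multivariate trait simulation under a model, ascertainment sampling,
## and the SimulationConfig front end.

## symmetric PSD square root (tolerates zero eigenvalues, e.g. the
## household block-of-ones matrix)
.symSqrt <- function(M, what = "matrix") {
  if (!nrow(M)) return(M)
  ee <- .symEig(M)
  if (min(ee$values) < -1e-8 * max(abs(ee$values), 1))
    stop(what, " is not positive semidefinite at the supplied true values")
  ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
}

## reshape n x (L*B) (component-draw columns l fastest within pedigree b)
## to (n*B) x L with rows (b-1)*n + i
.stackDraws <- function(A, n, L, B) {
  matrix(aperm(array(A, c(n, L, B)), c(1, 3, 2)), n * B, L)
}

#' Simulate phenotypes under a model
#'
#' For each pedigree draws, per variance component \eqn{c}, latent
#' residuals \eqn{\zeta_c \sim MVN(0, R_{c,k} \otimes \Psi_c)} and trait
#' residuals \eqn{\epsilon_c \sim MVN(0, R_{c,k} \otimes \Theta_c)}
#' (via symmetric square roots of both factors), then propagates
#' \deqn{\eta = (I-B)^{-1}(\alpha + \Gamma_\eta x + \textstyle\sum_c
#'   \zeta_c), \qquad y = \nu + \Lambda\eta + \Gamma_y x +
#'   \textstyle\sum_c \epsilon_c}
#' per individual.  Covariate values \eqn{x} (e.g. SNP allele counts)
#' are taken from each pedigree's covariate/genotype columns.  Unlike
#' estimation, simulation requires every \eqn{\Psi_c}, \eqn{\Theta_c}
#' positive semidefinite.  Pedigrees sharing a structure are simulated
#' in one vectorized batch; marker-specific (linkage) components, whose
#' coupling matrix differs per pedigree, are added per family.
#'
#' @param peds a \linkS4class{PedigreeSet} carrying genotype/covariate
#'   columns for the model's covariates.
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta named true parameter vector (every free slot).
#' @param relmats per-pedigree named lists of relationship matrices
#'   (components as in \code{mm@components}).
#' @param seed RNG seed.
#' @return A new \linkS4class{PedigreeSet} with the phenotype matrices
#'   filled (columns = observed variables).
#' @export
simulatePhenotypes <- function(peds, mm, theta, relmats, seed = 1) {
  theta <- .alignTheta(mm, theta)
  ev <- mmEval(mm, theta)
  t <- length(mm@observed); L <- length(mm@latent)
  q <- length(mm@covariates)
  comps <- mm@components
  SPsi <- lapply(ev$Psi, .symSqrt, what = "Psi")
  STheta <- lapply(ev$Theta, .symSqrt, what = "Theta")
  H <- if (L) solve(diag(L) - ev$B) else NULL
  perPed <- grepl("^a\\(", comps)
  sharedC <- comps[!perPed]; linkC <- comps[perPed]
  sig <- vapply(peds, .structureSignature, "")
  groups <- split(seq_along(peds), sig)
  out <- vector("list", length(peds))
  .withSeed(seed, {
    for (grp in groups) {
      B <- length(grp)
      n <- pedSize(peds[[grp[1]]])
      X <- if (q) do.call(rbind, lapply(grp, function(k) {
        p <- peds[[k]]
        xk <- vapply(mm@covariates, function(nm) .covColumn(p, nm), numeric(n))
        if (q == 1) matrix(xk, ncol = 1) else xk
      })) else matrix(0, n * B, 0)
      zeta <- matrix(0, n * B, L)
      eps <- matrix(0, n * B, t)
      for (c. in sharedC) {
        SR <- .symSqrt(relmats[[grp[1]]][[c.]], what = paste("R", c.))
        if (L && any(SPsi[[c.]] != 0)) {
          Z <- matrix(rnorm(n * L * B), n)
          zeta <- zeta + .stackDraws(SR %*% Z, n, L, B) %*% SPsi[[c.]]
        }
        if (any(STheta[[c.]] != 0)) {
          Z <- matrix(rnorm(n * t * B), n)
          eps <- eps + .stackDraws(SR %*% Z, n, t, B) %*% STheta[[c.]]
        }
      }
      for (c. in linkC) {
        for (bi in seq_len(B)) {
          SR <- .symSqrt(relmats[[grp[bi]]][[c.]], what = paste("R", c.))
          rows <- (bi - 1) * n + seq_len(n)
          if (L && any(SPsi[[c.]] != 0))
            zeta[rows, ] <- zeta[rows, ] +
              SR %*% matrix(rnorm(n * L), n) %*% SPsi[[c.]]
          if (any(STheta[[c.]] != 0))
            eps[rows, ] <- eps[rows, ] +
              SR %*% matrix(rnorm(n * t), n) %*% STheta[[c.]]
        }
      }
      Y <- matrix(ev$nu, n * B, t, byrow = TRUE) + eps
      if (q) Y <- Y + X %*% t(ev$Gy)
      if (L) {
        etaIn <- matrix(ev$alpha, n * B, L, byrow = TRUE) + zeta
        if (q) etaIn <- etaIn + X %*% t(ev$Ge)
        Y <- Y + (etaIn %*% t(H)) %*% t(ev$Lambda)
      }
      colnames(Y) <- mm@observed
      for (bi in seq_len(B)) {
        k <- grp[bi]
        p <- peds[[k]]
        ph <- Y[(bi - 1) * n + seq_len(n), , drop = FALSE]
        rownames(ph) <- p@members$id
        p@phenotypes <- ph
        out[[k]] <- p
      }
    }
  })
  PedigreeSet(out)
}

.alignTheta <- function(mm, theta) {
  nm <- mm@par$name
  if (is.null(names(theta))) {
    if (length(theta) == 1) return(setNames(rep(theta, length(nm)), nm))
    stopifnot(length(theta) == length(nm))
    return(setNames(theta, nm))
  }
  miss <- setdiff(nm, names(theta))
  if (length(miss))
    stop("true values missing for parameter(s): ", paste(miss, collapse = ", "))
  theta[nm]
}

#' Affection threshold from a reference population
#'
#' Simulates \code{nRef} unrelated individuals at the true parameter
#' values and returns the upper-\code{prevalence} empirical quantile of
#' the per-individual mean of the affection traits.  An empirical
#' reference is used (rather than a normal quantile) because the trait
#' mean is a genotype mixture.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta named true parameter vector.
#' @param panel a \linkS4class{HaplotypePanel} supplying the model's SNP
#'   covariates.
#' @param prevalence population proportion affected, in (0, 1).
#' @param traits trait names entering the affection score (default: all
#'   observed variables).
#' @param nRef reference-population size.
#' @param seed RNG seed.
#' @return scalar threshold.
#' @export
affectionThreshold <- function(mm, theta, panel, prevalence,
                               traits = NULL, nRef = 1e5, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1)
  if (is.null(traits)) traits <- mm@observed
  single <- Pedigree("ref", data.frame(id = "i", father = NA, mother = NA))
  refs <- .recycleStructures(PedigreeSet(list(single)), nRef, prefix = "ref")
  seeds <- .subSeeds(seed, 2)
  drop <- geneDrop(refs, panel, seed = seeds[1])
  refs <- PedigreeSet(lapply(seq_along(refs), function(k) {
    p <- refs[[k]]; p@genotypes <- drop$genotypes[[k]]; p
  }))
  one <- matrix(1, 1, 1)
  rel <- lapply(mm@components, function(c.) one)
  names(rel) <- mm@components
  relmats <- rep(list(rel), nRef)
  sim <- simulatePhenotypes(refs, mm, theta, relmats, seed = seeds[2])
  score <- vapply(sim, function(p)
    mean(p@phenotypes[1, traits]), 1)
  unname(quantile(score, 1 - prevalence, type = 7))
}

#' Proband-based ascertainment sampling
#'
#' An individual is affected when the mean of its affection-trait values
#' exceeds \code{threshold}; each affected member becomes a proband
#' candidate independently with probability \code{probandProbability};
#' the first candidate in member order is flagged as the proband and
#' pedigrees without a proband are discarded.
#'
#' @param peds a \linkS4class{PedigreeSet} with simulated phenotypes.
#' @param prevalence nominal prevalence (recorded; the threshold must be
#'   computed at the same value, see \code{\link{affectionThreshold}}).
#' @param probandProbability per-affected ascertainment probability in
#'   (0, 1].
#' @param threshold affection threshold on the trait mean.
#' @param traits trait names entering the affection score (default: all
#'   phenotype columns).
#' @param seed RNG seed.
#' @return A \linkS4class{PedigreeSet} of retained pedigrees with the
#'   proband flags set (possibly empty).
#' @export
applyAscertainment <- function(peds, prevalence, probandProbability,
                               threshold, traits = NULL, seed = 1) {
  stopifnot(probandProbability > 0, probandProbability <= 1)
  out <- list()
  .withSeed(seed, {
    for (p in peds) {
      ph <- p@phenotypes
      if (is.null(traits)) traits <- colnames(ph)
      score <- rowMeans(ph[, traits, drop = FALSE])
      affected <- !is.na(score) & score > threshold
      cand <- affected & (runif(length(score)) < probandProbability)
      if (!any(cand)) next
      p@members$proband <- FALSE
      p@members$proband[which(cand)[1]] <- TRUE
      out[[length(out) + 1]] <- p
    }
  })
  PedigreeSet(out)
}
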