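## Stage 1: saturated variance-component maximum likelihood.
##
## For every observed trait a univariate model
##   y_v = X beta_v + sum_c u_{c,v},   u_{c,v} ~ MVN(0, sigma2_{c,v} R_c)
## is fitted by ML over the pedigrees (variances unconstrained in sign),
## then for every trait pair the per-component cross-covariances are
## fitted holding the univariate estimates fixed.  Per-pedigree scores
## feed the robust sandwich covariance of the stacked moment vector.

#' Multivariate-normal pedigree log likelihood
#'
#' Log density of one pedigree's stacked trait vector under mean
#' \code{mu} and covariance \code{Sigma}; entries with missing values
#' are dropped (the corresponding rows and columns of \code{Sigma} are
#' deleted).  Returns \code{-Inf} when \code{Sigma} is not positive
#' definite on the observed entries, and 0 when everything is missing.
#'
#' @param y stacked trait values (individual-major), may contain NA.
#' @param mu implied means, same length.
#' @param Sigma assembled covariance matrix.
#' @param probandEntries optional integer positions (in the full
#'   stacking) of a proband's entries: when given, the marginal log
#'   density of the proband's observed entries is subtracted
#'   (single-ascertainment conditioning).
#' @return scalar log likelihood.
#' @export
pedigreeLogLik <- function(y, mu, Sigma, probandEntries = NULL) {
  obs <- which(!is.na(y))
  if (!length(obs)) return(0)
  r <- y[obs] - mu[obs]
  S <- Sigma[obs, obs, drop = FALSE]
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, r, transpose = TRUE)
  ll <- -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  if (!is.null(probandEntries) && length(probandEntries)) {
    pobs <- intersect(probandEntries, obs)
    if (length(pobs))
      ll <- ll - pedigreeLogLik(y[pobs], mu[pobs],
                                Sigma[pobs, pobs, drop = FALSE])
  }
  ll
}

## Relationship matrices for every pedigree and component label.
.relMatsFor <- function(peds, components, ibd = NULL) {
  lapply(peds, function(p) {
    out <- lapply(components, function(c.) .componentMatrix(p, c., ibd))
    names(out) <- components
    out
  })
}

## Locate a covariate column in the covariate or genotype matrices.
.covColumn <- function(ped, name) {
  if (name %in% colnames(ped@covariates)) return(ped@covariates[, name])
  if (name %in% colnames(ped@genotypes)) return(ped@genotypes[, name])
  stop("covariate '", name, "' not found in pedigree ", ped@familyId)
}

## Per-pedigree context shared by every stage-1 fit on the same data:
## covariate values, design-matrix templates for one- and two-trait
## stacks, proband row and covariate completeness.  Building this once
## per saturated run (instead of once per pair fit) matters for models
## with many trait pairs.
.fitContext <- function(peds, covariates) {
  q <- length(covariates)
  lapply(peds, function(p) {
    n <- pedSize(p)
    Xc <- if (q) vapply(covariates, function(nm) .covColumn(p, nm),
                        numeric(n)) else matrix(0, n, 0)
    if (q == 1) Xc <- matrix(Xc, ncol = 1)
    xf <- function(t) {
      Xfull <- matrix(0, n * t, t * (1 + q))
      for (v in seq_len(t)) {
        rows <- seq(v, n * t, by = t)
        cols <- (v - 1) * (1 + q) + 1
        Xfull[rows, cols] <- 1
        if (q) Xfull[rows, cols + seq_len(q)] <- Xc
      }
      Xfull
    }
    list(n = n, pheno = p@phenotypes, famId = p@familyId,
         ip = which(p@members$proband),
         xok = if (q) complete.cases(Xc) else rep(TRUE, n),
         Xfull1 = xf(1), Xfull2 = xf(2))
  })
}

## Pack one fit's data (vars of length 1 or 2) for the C++ likelihood.
.packFit <- function(peds, vars, covariates, components, relmats,
                     ctx = NULL) {
  t <- length(vars)
  q <- length(covariates)
  if (is.null(ctx)) ctx <- .fitContext(peds, covariates)
  packed <- vector("list", length(peds))
  keep <- logical(length(peds))
  probandMissing <- FALSE
  for (k in seq_along(ctx)) {
    cx <- ctx[[k]]
    n <- cx$n
    if (!all(vars %in% colnames(cx$pheno)))
      stop("phenotype '", setdiff(vars, colnames(cx$pheno))[1],
           "' not found in pedigree ", cx$famId)
    yfull <- as.vector(t(cx$pheno[, vars, drop = FALSE]))  # individual-major
    ## individuals with a missing covariate cannot enter the mean model
    if (q && any(!cx$xok)) yfull[rep(!cx$xok, each = t)] <- NA
    idx <- which(!is.na(yfull))
    if (!length(idx)) { keep[k] <- FALSE; next }
    Xfull <- if (t == 1) cx$Xfull1 else cx$Xfull2
    pentries <- if (length(cx$ip)) (cx$ip[1] - 1) * t + seq_len(t)
                else integer(0)
    pidx <- which(idx %in% pentries)
    if (length(cx$ip) && !length(pidx)) probandMissing <- TRUE
    packed[[k]] <- list(
      y = yfull[idx],
      X = if (length(idx) == n * t) Xfull else Xfull[idx, , drop = FALSE],
      R = unname(relmats[[k]]),
      idx = as.integer(idx), pidx = as.integer(pidx))
    keep[k] <- TRUE
  }
  list(peds = packed[keep], ptr = .cpp_pack(packed[keep]), keep = keep,
       t = t, q = q, nbeta = t * (1 + q), C = length(components),
       probandMissing = probandMissing)
}

.vcube <- function(sigma, t, C) {
  ## sigma: list per component of t x t matrices -> array t x t x C
  array(unlist(sigma), dim = c(t, t, C))
}

.negllUni <- function(par, pack, ascertained) {
  nb <- pack$nbeta
  V <- array(par[nb + seq_len(pack$C)], dim = c(1, 1, pack$C))
  -.cpp_vc_loglik(par[seq_len(nb)], V, pack$ptr, ascertained, FALSE)[1]
}

.gradUni <- function(par, pack, ascertained) {
  nb <- pack$nbeta
  V <- array(par[nb + seq_len(pack$C)], dim = c(1, 1, pack$C))
  sc <- tryCatch(.cpp_vc_scores(par[seq_len(nb)], V, pack$ptr, ascertained),
                 error = function(e) NULL)
  if (is.null(sc)) return(rep(0, length(par)))
  -colSums(sc)
}

#' Univariate variance-component fit
#'
#' ML fit of one trait's mean coefficients and per-component variances
#' over all pedigrees.  Variances are \emph{not} constrained to be
#' positive (constraining them would distort the asymptotic
#' distributions used downstream); the covariance must merely stay
#' positive definite at the optimum.
#'
#' @param trait phenotype name.
#' @param peds a \linkS4class{PedigreeSet}.
#' @param components character vector of component labels
#'   (\code{"p"}, \code{"e"}, \code{"c"}, \code{"a(marker)"}).
#' @param covariates covariate/SNP column names entering the mean.
#' @param ibd \linkS4class{IBDData} when a linkage component is present.
#' @param ascertained condition each pedigree's likelihood on the first
#'   proband's observed value of this trait.
#' @param relmats optional precomputed relationship matrices (from
#'   internal callers).
#' @return list with elements \code{beta}, \code{sigma2}, \code{pack},
#'   \code{converged}, \code{logLik}.
#' @export
fitUnivariateVC <- function(trait, peds, components, covariates = character(0),
                            ibd = NULL, ascertained = FALSE, relmats = NULL,
                            ctx = NULL) {
  if (length(peds) < 2) stop("need at least 2 pedigrees to fit '", trait, "'")
  if (is.null(relmats)) relmats <- .relMatsFor(peds, components, ibd)
  pack <- .packFit(peds, trait, covariates, components, relmats, ctx)
  if (ascertained && pack$probandMissing)
    warning("proband with all values of '", trait,
            "' missing: pedigree contributes unconditionally")
  ## OLS start
  ys <- unlist(lapply(pack$peds, `[[`, "y"))
  Xs <- do.call(rbind, lapply(pack$peds, `[[`, "X"))
  b0 <- tryCatch(drop(solve(crossprod(Xs), crossprod(Xs, ys))),
                 error = function(e) c(mean(ys), rep(0, ncol(Xs) - 1)))
  s2 <- var(ys - drop(Xs %*% b0))
  start <- c(b0, rep(s2 / pack$C, pack$C))
  fit <- NULL
  for (attempt in 0:3) {
    st <- if (attempt == 0) start else
      start * (1 + 0.3 * rnorm(length(start))) + 0.01 * attempt
    o <- tryCatch(nlminb(st, .negllUni, gradient = .gradUni, pack = pack,
                         ascertained = ascertained,
                         control = list(iter.max = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && is.finite(o$objective) && o$objective < 1e9) {
      fit <- o
      break
    }
  }
  if (is.null(fit))
    stop("univariate variance-component fit failed for trait '", trait, "'")
  nb <- pack$nbeta
  beta <- setNames(fit$par[seq_len(nb)], c("(Intercept)", covariates))
  sigma2 <- setNames(fit$par[nb + seq_len(pack$C)], components)
  list(trait = trait, beta = beta, sigma2 = sigma2, pack = pack,
       converged = fit$convergence == 0, logLik = -fit$objective,
       ascertained = ascertained, components = components,
       covariates = covariates)
}

.bivCube <- function(cross, d1, d2, C) {
  V <- array(0, dim = c(2, 2, C))
  for (c. in seq_len(C)) {
    V[1, 1, c.] <- d1[c.]; V[2, 2, c.] <- d2[c.]
    V[1, 2, c.] <- V[2, 1, c.] <- cross[c.]
  }
  V
}

#' Bivariate variance-component fit
#'
#' Holding each trait's mean coefficients and own variances fixed at the
#' univariate estimates, fits the per-component cross-covariances of a
#' trait pair by ML (profile two-step).
#'
#' @param pair character vector of two phenotype names.
#' @param uni1,uni2 the univariate fits of the two traits.
#' @inheritParams fitUnivariateVC
#' @return list with \code{cross} (named per component), \code{pack},
#'   \code{converged}.
#' @export
fitBivariateVC <- function(pair, peds, components, covariates = character(0),
                           ibd = NULL, ascertained = FALSE,
                           uni1, uni2, relmats = NULL, ctx = NULL) {
  if (is.null(relmats)) relmats <- .relMatsFor(peds, components, ibd)
  pack <- .packFit(peds, pair, covariates, components, relmats, ctx)
  beta <- c(uni1$beta, uni2$beta)
  d1 <- uni1$sigma2; d2 <- uni2$sigma2
  C <- pack$C
  negll <- function(cc)
    -.cpp_vc_loglik(beta, .bivCube(cc, d1, d2, C), pack$ptr,
                    ascertained, FALSE)[1]
  grad <- function(cc) {
    sc <- tryCatch(.cpp_vc_scores(beta, .bivCube(cc, d1, d2, C), pack$ptr,
                                  ascertained, crossOnly = TRUE),
                   error = function(e) NULL)
    if (is.null(sc)) return(rep(0, C))
    ## free slots: the (2,1) vech entry of each component
    -colSums(sc)[pack$nbeta + (seq_len(C) - 1) * 3 + 2]
  }
  ## start from the raw residual cross-covariance, split evenly
  rc <- .rawResidCross(pack, beta)
  start <- rep(rc / C, C)
  ## shrink the start until the implied covariance is PD
  for (i in 0:20) {
    if (is.finite(negll(start)) && negll(start) < 1e9) break
    start <- start * 0.5
  }
  fit <- NULL
  for (attempt in 0:3) {
    st <- if (attempt == 0) start else start * 0.5^attempt
    o <- tryCatch(nlminb(st, negll, gradient = grad,
                         control = list(iter.max = 300)),
                  error = function(e) NULL)
    if (!is.null(o) && is.finite(o$objective) && o$objective < 1e9) {
      fit <- o; break
    }
  }
  if (is.null(fit))
    stop("bivariate fit failed for pair (", pair[1], ", ", pair[2], ")")
  list(pair = pair, cross = setNames(fit$par, components), pack = pack,
       beta = beta, diag1 = d1, diag2 = d2,
       converged = fit$convergence == 0, logLik = -fit$objective)
}

## empirical cross-covariance of the two traits' residuals
.rawResidCross <- function(pack, beta) {
  s <- 0; n <- 0
  for (pk in pack$peds) {
    r <- pk$y - drop(pk$X %*% beta)
    i1 <- which(pk$idx %% 2 == 1)       # trait 1 entries
    for (i in i1) {
      j <- which(pk$idx == pk$idx[i] + 1)
      if (length(j)) { s <- s + r[i] * r[j]; n <- n + 1 }
    }
  }
  if (n) s / n else 0
}
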