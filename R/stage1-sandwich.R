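## Assembly of the stage-1 moment vector and its robust sandwich
## covariance from the stacked per-pedigree estimating equations.

#' Saturated stage-1 estimates with robust covariance
#'
#' Runs every univariate and bivariate variance-component fit implied by
#' the model's observed variables, covariates and component labels, and
#' assembles the moment vector \eqn{s} (in \code{\link{momentNames}}
#' order) together with its sandwich covariance
#' \deqn{\hat\Gamma = A^{-1} B A^{-T} / N}
#' where \eqn{A} is the average Jacobian of the stacked per-pedigree
#' estimating equations (numerically differentiated analytic scores;
#' block lower-triangular because the bivariate fits hold univariate
#' estimates fixed) and \eqn{B} the empirical covariance of the stacked
#' per-pedigree scores.  Cross-fit blocks of \eqn{B} come from
#' cross-products of scores of different fits on the same pedigree, so
#' \eqn{\hat\Gamma} estimates \eqn{var(s)} directly, including the
#' \eqn{1/N}.
#'
#' @param peds a \linkS4class{PedigreeSet}.
#' @param mm a \linkS4class{ModelMatrices} (defines variables, covariates
#'   and components).
#' @param ibd \linkS4class{IBDData}, needed for linkage components.
#' @param ascertained condition all stage-1 likelihoods on the first
#'   proband's observed values of each fit's variables.
#' @return A \linkS4class{SaturatedEstimates}.
#' @export
saturatedEstimates <- function(peds, mm, ibd = NULL, ascertained = FALSE) {
  comps <- mm@components
  obs <- mm@observed
  covs <- mm@covariates
  N <- length(peds)
  relmats <- .relMatsFor(peds, comps, ibd)
  ctx <- .fitContext(peds, covs)

  unis <- lapply(obs, function(v)
    fitUnivariateVC(v, peds, comps, covs, ibd = ibd,
                    ascertained = ascertained, relmats = relmats,
                    ctx = ctx))
  names(unis) <- obs
  t <- length(obs)
  pairs <- list()
  if (t > 1)
    for (i in seq_len(t - 1)) for (j in (i + 1):t)
      pairs[[length(pairs) + 1]] <- c(i, j)
  bivs <- lapply(pairs, function(ij)
    fitBivariateVC(obs[ij], peds, comps, covs, ibd = ibd,
                   ascertained = ascertained,
                   uni1 = unis[[ij[1]]], uni2 = unis[[ij[2]]],
                   relmats = relmats, ctx = ctx))

  ## ---- stacked estimating-equation parameter vector tau ----
  C <- length(comps)
  q <- length(covs)
  bslot <- 1 + q                       # beta entries per trait
  uSize <- bslot + C                   # per univariate fit
  tauNames <- character(0)
  tau <- numeric(0)
  uniOff <- integer(t)
  for (i in seq_len(t)) {
    v <- obs[i]
    uniOff[i] <- length(tau)
    tauNames <- c(tauNames, paste0(v, "~1"),
                  if (q) paste0(v, "~", covs),
                  paste0("var(", v, ",", comps, ")"))
    tau <- c(tau, unis[[i]]$beta, unis[[i]]$sigma2)
  }
  pairOff <- integer(length(pairs))
  for (k in seq_along(pairs)) {
    ij <- pairs[[k]]
    pairOff[k] <- length(tau)
    tauNames <- c(tauNames,
                  paste0("cov(", obs[ij[1]], ",", obs[ij[2]], ",", comps, ")"))
    tau <- c(tau, bivs[[k]]$cross)
  }
  names(tau) <- tauNames
  P <- length(tau)

  ## ---- per-fit score evaluation at arbitrary tau ----
  nFits <- t + length(pairs)
  fitCols <- vector("list", nFits)     # tau columns owned by each fit
  for (i in seq_len(t)) fitCols[[i]] <- uniOff[i] + seq_len(uSize)
  for (k in seq_along(pairs)) fitCols[[t + k]] <- pairOff[k] + seq_len(C)

  scoreFit <- function(f, tauv) {
    ## returns N x length(fitCols[[f]]) matrix (zero rows for pedigrees
    ## with no observed data in that fit)
    if (f <= t) {
      u <- unis[[f]]
      par <- tauv[uniOff[f] + seq_len(uSize)]
      V <- array(par[bslot + seq_len(C)], dim = c(1, 1, C))
      sc <- .cpp_vc_scores(par[seq_len(bslot)], V, u$pack$ptr, ascertained)
    } else {
      k <- f - t
      b <- bivs[[k]]
      ij <- pairs[[k]]
      beta <- c(tauv[uniOff[ij[1]] + seq_len(bslot)],
                tauv[uniOff[ij[2]] + seq_len(bslot)])
      d1 <- tauv[uniOff[ij[1]] + bslot + seq_len(C)]
      d2 <- tauv[uniOff[ij[2]] + bslot + seq_len(C)]
      cc <- tauv[pairOff[k] + seq_len(C)]
      sc <- .cpp_vc_scores(beta, .bivCube(cc, d1, d2, C), b$pack$ptr,
                           ascertained, crossOnly = TRUE)
      sc <- sc[, 2 * bslot + (seq_len(C) - 1) * 3 + 2, drop = FALSE]
    }
    keep <- if (f <= t) unis[[f]]$pack$keep else bivs[[f - t]]$pack$keep
    out <- matrix(0, N, ncol(sc))
    out[keep, ] <- sc
    out
  }

  G <- matrix(0, N, P)
  for (f in seq_len(nFits)) G[, fitCols[[f]]] <- scoreFit(f, tau)

  ## ---- A: numeric Jacobian of the average estimating equation ----
  ## tau_j from a univariate fit enters its own fit and every pair fit
  ## containing that trait; pair parameters enter only their own fit.
  dependents <- vector("list", P)
  for (i in seq_len(t)) {
    dep <- c(i, t + which(vapply(pairs, function(ij) i %in% ij, TRUE)))
    for (j in fitCols[[i]]) dependents[[j]] <- dep
  }
  for (k in seq_along(pairs))
    for (j in fitCols[[t + k]]) dependents[[j]] <- t + k

  A <- matrix(0, P, P)
  for (j in seq_len(P)) {
    h <- 1e-5 * max(1, abs(tau[j]))
    tp <- tm <- tau
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    for (f in dependents[[j]]) {
      cols <- fitCols[[f]]
      gp <- colSums(scoreFit(f, tp)) / N
      gm <- colSums(scoreFit(f, tm)) / N
      A[cols, j] <- (gp - gm) / (2 * h)
    }
  }
  B <- crossprod(G) / N
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular estimating-equation Jacobian; ",
         "consider simplifying the model"))
  Gamma <- (Ainv %*% B %*% t(Ainv)) / N
  Gamma <- (Gamma + t(Gamma)) / 2
  ## PSD floor
  ee <- eigen(Gamma, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  Gamma <- ee$vectors %*% (ev * t(ee$vectors))
  Gamma <- (Gamma + t(Gamma)) / 2
  dimnames(Gamma) <- list(tauNames, tauNames)

  ## ---- reorder tau -> moment order ----
  mn <- momentNames(mm)
  perm <- match(mn, tauNames)
  if (anyNA(perm)) stop("internal error: moment/tau name mismatch")
  s <- tau[perm]
  Gamma <- Gamma[perm, perm]
  ## influence-style per-pedigree contributions, moment order
  infl <- -t(Ainv %*% t(G))[, perm, drop = FALSE] / N
  conv <- all(vapply(unis, `[[`, TRUE, "converged")) &&
          all(vapply(bivs, `[[`, TRUE, "converged"))
  new("SaturatedEstimates", s = s, Gamma = Gamma, scores = infl,
      N = N, converged = conv,
      details = list(univariate = unis, bivariate = bivs,
                     ascertained = ascertained))
}

setMethod("show", "SaturatedEstimates", function(object) {
  cat("SaturatedEstimates:", length(object@s), "moments from",
      object@N, "pedigrees; converged:", object@converged, "\n")
})
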