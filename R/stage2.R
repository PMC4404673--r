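## Stage 2: minimum-distance (ADF) fit of the structural model to the
## stage-1 moments, with an evolutionary multi-start and sandwich
## parameter covariance.

## heuristic starting point: loadings 1, structural paths 0.3,
## intercepts at their stage-1 values, covariate coefficients at the
## average stage-1 slope, variance components at equal splits of the
## stage-1 variances between the latent and residual layers
.stage2Center <- function(mm, s) {
  par <- mm@par
  th <- numeric(nrow(par))
  hasLatent <- length(mm@latent) > 0
  indicatorsOf <- function(l) {
    m <- mm@spec@measurement
    m$indicator[m$latent == l & m$indicator %in% mm@observed]
  }
  for (j in seq_len(nrow(par))) {
    nm <- par$name[j]
    if (par$role[j] == "IN") {
      th[j] <- if (nm %in% names(s)) s[[nm]] else 0
    } else if (par$role[j] == "CO") {
      pp <- strsplit(sub("=~", "~", nm), "~", fixed = TRUE)[[1]]
      lhs <- pp[1]; rhs <- pp[2]
      if (rhs %in% mm@covariates) {
        slopes <- s[paste0(mm@observed, "~", rhs)]
        th[j] <- mean(slopes, na.rm = TRUE)
      } else if (lhs %in% mm@latent && rhs %in% mm@latent) {
        th[j] <- 0.3
      } else th[j] <- 1
    } else {                            # VC
      m <- regmatches(nm, regexec("^var\\(([^,]+),(.+)\\)$", nm))[[1]]
      if (length(m) == 3) {
        v <- m[2]; c. <- m[3]
        if (v %in% mm@observed) {
          th[j] <- s[[paste0("var(", v, ",", c., ")")]] *
            (if (hasLatent) 0.5 else 1)
        } else {
          inds <- indicatorsOf(v)
          if (!length(inds)) inds <- mm@observed
          th[j] <- mean(s[paste0("var(", inds, ",", c., ")")], na.rm = TRUE) * 0.5
        }
      } else {                          # free covariance slot
        th[j] <- if (nm %in% names(s)) s[[nm]] * 0.5 else 0
      }
    }
  }
  if (anyNA(th)) th[is.na(th)] <- 0.5
  names(th) <- par$name
  th
}

.makeQ <- function(mm, s, W, sigmaFn = .makeSigma(mm)) {
  force(s); force(W); force(sigmaFn)
  s <- unname(s)
  function(theta) {
    sig <- tryCatch(sigmaFn(theta), error = function(e) NULL)
    if (is.null(sig) || !all(is.finite(sig))) return(1e12)
    r <- s - sig
    drop(crossprod(r, W %*% r))
  }
}

.sigmaJacobian <- function(sigmaFn, theta, nMom) {
  p <- length(theta)
  J <- matrix(0, nMom, p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (sigmaFn(tp) - sigmaFn(tm)) / (2 * h)
  }
  J
}

#' Evolutionary starting values for the stage-2 fit
#'
#' Seed-deterministic heuristic genetic algorithm over the distance
#' \eqn{Q(\theta)}: a population initialised around the heuristic center
#' (loadings 1, intercepts at stage-1 values, variances at equal splits
#' of the stage-1 variances) evolves by tournament selection (size 3),
#' blend crossover (\eqn{\alpha = 0.5}) and Gaussian mutation (rate 0.2,
#' sd 0.1 x scale) with elitism.  Returns the distinct top candidates
#' plus the heuristic center, each to be polished by quasi-Newton
#' iteration.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param s stage-1 moment vector.
#' @param W weight matrix of the distance.
#' @param seed RNG seed (results are identical for identical seeds).
#' @param popSize,generations population size and generation count.
#' @param nKeep number of distinct top candidates returned.
#' @return list of parameter vectors; the heuristic center is always the
#'   last element.
#' @export
generateStartingValues <- function(mm, s, W, seed = 1, popSize = 20,
                                   generations = 10, nKeep = 5) {
  Q <- .makeQ(mm, s, W)
  center <- .stage2Center(mm, s)
  p <- length(center)
  scale <- pmax(0.5, abs(center))
  .withSeed(seed, {
    pop <- lapply(seq_len(popSize), function(i) {
      if (i == 1) center else center + rnorm(p, 0, scale)
    })
    fit <- vapply(pop, Q, 1)
    for (g in seq_len(generations)) {
      ord <- order(fit)
      newPop <- pop[ord[1]]             # elitism
      newFit <- fit[ord[1]]
      while (length(newPop) < popSize) {
        pick <- function() {
          cand <- sample.int(popSize, 3)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        d <- hi - lo
        child <- runif(p, lo - 0.5 * d, hi + 0.5 * d)
        mut <- runif(p) < 0.2
        child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.1 * scale[mut])
        newPop[[length(newPop) + 1]] <- child
        newFit <- c(newFit, Q(child))
      }
      pop <- newPop; fit <- newFit
    }
    ord <- order(fit)
    out <- list(); seen <- character(0)
    for (i in ord) {
      key <- paste(signif(pop[[i]], 8), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- pop[[i]]
      if (length(out) >= nKeep) break
    }
    c(out, list(center))
  })
}

#' Minimum-distance fit of the structural model
#'
#' Finds \eqn{\hat\theta = \arg\min_\theta (s - \sigma(\theta))^T W
#' (s - \sigma(\theta))} by quasi-Newton polish from each evolutionary
#' starting value, and computes the sandwich parameter covariance
#' \deqn{(\Delta^T W \Delta)^{-1} \Delta^T W \hat\Gamma W \Delta
#'       (\Delta^T W \Delta)^{-1}}
#' at the optimum, with Wald z statistics and two-sided normal p-values.
#' Because \eqn{\hat\Gamma} carries the \eqn{1/N}, \eqn{Q_{min}} is
#' already on the chi-square scale.
#'
#' @param sat a \linkS4class{SaturatedEstimates}.
#' @param mm a \linkS4class{ModelMatrices}.
#' @param weight \code{"diagonal"} (default, \eqn{W =
#'   diag(\hat\Gamma)^{-1}}; numerically robust with many moments) or
#'   \code{"full"} (\eqn{W = \hat\Gamma^{-}}, the asymptotically optimal
#'   ADF weight).
#' @param seed RNG seed for the evolutionary starts.
#' @param starts optional list of starting vectors (overrides the
#'   evolutionary search).
#' @return A \linkS4class{PedSEMFit} (fit indices not yet attached; see
#'   \code{\link{fitPedSEM}}).
#' @export
minimumDistanceFit <- function(sat, mm, weight = c("diagonal", "full"),
                               seed = 1, starts = NULL) {
  weight <- match.arg(weight)
  s <- sat@s
  Gamma <- sat@Gamma
  W <- switch(weight,
              diagonal = diag(1 / pmax(diag(Gamma), 1e-12)),
              full = .pinvSym(Gamma))
  dimnames(W) <- dimnames(Gamma)
  sigmaFn <- .makeSigma(mm)
  Q <- .makeQ(mm, s, W, sigmaFn)
  sU <- unname(s)
  nMom <- length(s)
  grad <- function(theta) {
    out <- tryCatch({
      sig <- sigmaFn(theta)
      J <- .sigmaJacobian(sigmaFn, theta, nMom)
      drop(-2 * crossprod(J, W %*% (sU - sig)))
    }, error = function(e) NULL)
    if (is.null(out) || !all(is.finite(out))) rep(0, length(theta)) else out
  }
  if (is.null(starts)) starts <- generateStartingValues(mm, s, W, seed = seed)
  best <- NULL
  for (st in starts) {
    o <- tryCatch(nlminb(st, Q, gradient = grad,
                         control = list(iter.max = 500, rel.tol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best))
    stop("all stage-2 starts failed to converge")
  theta <- setNames(best$par, mm@par$name)
  Qmin <- max(best$objective, 0)
  Delta <- momentJacobian(mm, theta)
  DWD <- crossprod(Delta, W %*% Delta)
  DWDi <- tryCatch(solve(DWD), error = function(e) .pinvSym(DWD))
  Vc <- DWDi %*% crossprod(Delta, W %*% Gamma %*% W %*% Delta) %*% t(DWDi)
  Vc <- (Vc + t(Vc)) / 2
  dimnames(Vc) <- list(mm@par$name, mm@par$name)
  se <- sqrt(pmax(diag(Vc), 0))
  z <- theta / ifelse(se > 0, se, NA)
  pval <- 2 * pnorm(-abs(z))
  par <- data.frame(name = mm@par$name, role = mm@par$role,
                    estimate = theta, se = se, z = z, p = pval,
                    row.names = NULL, stringsAsFactors = FALSE)
  new("PedSEMFit", theta = theta, vcov = Vc, par = par, Qmin = Qmin,
      df = length(s) - length(theta), weightType = weight, W = W,
      mm = mm, sat = sat, fitIndices = list(),
      converged = best$convergence == 0, nStarts = length(starts),
      seed = seed)
}

#' Fit a pedigree SEM (two-stage pipeline)
#'
#' Convenience front end: parses the model if given as text, compiles
#' the model matrices, checks identification, runs the stage-1 saturated
#' fits (optionally with single-ascertainment conditioning), performs
#' the stage-2 minimum-distance fit, and attaches the four chi-square
#' fit indices and CFI.
#'
#' @param peds a \linkS4class{PedigreeSet}.
#' @param model model description text, \linkS4class{ModelSpec} or
#'   \linkS4class{ModelMatrices}.
#' @param ibd optional \linkS4class{IBDData} for linkage components.
#' @param ascertained logical; condition stage-1 likelihoods on the
#'   first proband (single ascertainment correction).
#' @param weight stage-2 weight matrix choice, see
#'   \code{\link{minimumDistanceFit}}.
#' @param seed seed governing the evolutionary starts and the
#'   Monte-Carlo tail of the theoretically corrected fit test.
#' @param mcReps Monte-Carlo replicates for the theoretical fit test.
#' @return A \linkS4class{PedSEMFit}.
#' @export
fitPedSEM <- function(peds, model, ibd = NULL, ascertained = FALSE,
                      weight = c("diagonal", "full"), seed = 1,
                      mcReps = 1e5) {
  weight <- match.arg(weight)
  mm <- if (is(model, "ModelMatrices")) model
        else if (is(model, "ModelSpec")) buildModelMatrices(model)
        else buildModelMatrices(parseModel(model))
  idc <- checkIdentification(mm)
  if (!idc$identified)
    warning("model appears under-identified (rank-deficient moment Jacobian)")
  seeds <- .subSeeds(seed, 2)
  sat <- saturatedEstimates(peds, mm, ibd = ibd, ascertained = ascertained)
  fit <- minimumDistanceFit(sat, mm, weight = weight, seed = seeds[1])
  fit@fitIndices <- computeFitIndices(fit, mcReps = mcReps, seed = seeds[2])
  fit@seed <- seed                     # report the user-level seed
  fit
}

setMethod("show", "PedSEMFit", function(object) {
  cat("PedSEMFit:", length(object@theta), "parameters, df =", object@df,
      ", Qmin =", format(object@Qmin, digits = 4),
      ", weight =", object@weightType, "\n")
  print(object@par, digits = 4)
  fi <- object@fitIndices
  if (length(fi)) {
    cat("\nFit indices:\n")
    print(fi$table, digits = 4)
    cat("CFI:", format(fi$cfi, digits = 4), "\n")
  }
})
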