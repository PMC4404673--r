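## Chi-square tests of overall model fit and CFI.
##
## With a non-optimal weight W the minimized distance Q is
## asymptotically a weighted sum of independent 1-df chi-squares whose
## weights are the eigenvalues of U Gamma, with U the residual weight
## projection.  The four reported tests are: unadjusted (Q against
## chi-square(df)), mean adjusted (first-moment Satorra-Bentler-style
## scaling), mean and variance adjusted (two-moment matching with
## fractional df), and the theoretically corrected test (Monte-Carlo
## tail of the exact mixture, back-calculated to a chi-square scale).

#' Mixture weights of the fit-statistic distribution
#'
#' Eigenvalues of \eqn{U \hat\Gamma} with
#' \eqn{U = W - W\Delta(\Delta^TW\Delta)^{-1}\Delta^TW}.  When
#' \eqn{W = \hat\Gamma^{-1}} exactly df weights equal 1 and the rest 0.
#' Small negative eigenvalues (sampling noise in \eqn{\hat\Gamma}) are
#' floored at zero; values below \code{-1e-8} relative to the largest
#' trigger a warning first.
#'
#' @param W weight matrix used in the distance.
#' @param Gamma covariance of the stage-1 moment vector.
#' @param Delta moment Jacobian at the optimum (may have zero columns
#'   for a model without free parameters).
#' @return numeric vector of nonnegative weights, decreasing.
#' @export
mixtureWeights <- function(W, Gamma, Delta) {
  if (is.null(Delta) || ncol(Delta) == 0) {
    U <- W
  } else {
    DWD <- crossprod(Delta, W %*% Delta)
    DWDi <- tryCatch(solve(DWD), error = function(e)
      stop("singular Delta' W Delta in mixture weights"))
    U <- W - W %*% Delta %*% DWDi %*% crossprod(Delta, W)
  }
  ev <- Re(eigen(U %*% Gamma, only.values = TRUE)$values)
  mx <- max(abs(ev), 1e-300)
  if (any(ev < -1e-8 * mx))
    warning("negative mixture weights floored at zero (",
            sum(ev < -1e-8 * mx), " below tolerance)")
  ev <- pmax(ev, 0)
  ev[ev < 1e-10 * mx] <- 0
  sort(ev, decreasing = TRUE)
}

#' Chi-square tests of model fit
#'
#' @param Qmin minimized stage-2 distance (chi-square scale).
#' @param df model degrees of freedom (moments minus free parameters).
#' @return list(stat, df, p).
#' @export
chisqUnadjusted <- function(Qmin, df) {
  if (df < 1) return(list(stat = NA_real_, df = df, p = NA_real_))
  list(stat = Qmin, df = df, p = pchisq(Qmin, df, lower.tail = FALSE))
}

#' @rdname chisqUnadjusted
#' @param weights mixture weights from \code{\link{mixtureWeights}}.
#' @export
chisqMeanAdjusted <- function(Qmin, weights, df) {
  if (df < 1) return(list(stat = NA_real_, df = df, p = NA_real_))
  sw <- sum(weights)
  if (sw <= 0) stop("sum of mixture weights is not positive")
  scale <- sw / df
  stat <- Qmin / scale
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' @rdname chisqUnadjusted
#' @export
chisqMeanVarianceAdjusted <- function(Qmin, weights, df) {
  if (df < 1) return(list(stat = NA_real_, df = df, p = NA_real_))
  sw <- sum(weights); sw2 <- sum(weights^2)
  if (sw2 <= 0) stop("sum of squared mixture weights is not positive")
  dfStar <- sw^2 / sw2
  stat <- Qmin * dfStar / sw
  list(stat = stat, df = dfStar, p = pchisq(stat, dfStar, lower.tail = FALSE))
}

#' @rdname chisqUnadjusted
#' @param mcReps Monte-Carlo draws from the weighted mixture
#'   (at least 1e4; default 1e5).
#' @param seed RNG seed (the p-value is seed-deterministic).
#' @details The theoretically corrected test simulates
#'   \eqn{\sum_j w_j z_j^2} from the estimated asymptotic mixture,
#'   computes the add-one-smoothed tail probability
#'   \eqn{p = (1 + \#\{draw \ge Q\})/(R + 1)} (never exactly zero), and
#'   back-calculates the chi-square(df) statistic that would have
#'   produced that p-value.
#' @export
chisqTheoretical <- function(Qmin, weights, df, mcReps = 1e5, seed = 1) {
  if (df < 1) return(list(stat = NA_real_, df = df, p = NA_real_))
  w <- weights[weights > 0]
  if (!length(w)) stop("no positive mixture weights")
  p <- .withSeed(seed, {
    exceed <- 0L
    block <- 5e4
    done <- 0
    while (done < mcReps) {
      b <- min(block, mcReps - done)
      draws <- as.vector(matrix(rchisq(b * length(w), df = 1),
                                nrow = b) %*% w)
      exceed <- exceed + sum(draws >= Qmin)
      done <- done + b
    }
    (1 + exceed) / (mcReps + 1)
  })
  list(stat = qchisq(p, df, lower.tail = FALSE), df = df, p = p)
}

#' Comparative fit index
#'
#' \deqn{CFI = 1 - \frac{\max(T_m - df_m, 0)}
#'   {\max(T_b - df_b,\; T_m - df_m,\; 0)}}
#' computed from the theoretically corrected statistics of the fitted
#' model and of the independence baseline (all covariances and
#' cross-loadings zero; means and per-variable variances free), clamped
#' to [0, 1]; NA when the denominator is zero.
#'
#' @param statModel,dfModel,statBaseline,dfBaseline statistics and
#'   degrees of freedom of the fitted and baseline models.
#' @return scalar CFI.
#' @export
cfi <- function(statModel, dfModel, statBaseline, dfBaseline) {
  num <- max(statModel - dfModel, 0)
  den <- max(statBaseline - dfBaseline, statModel - dfModel, 0)
  if (den == 0) return(NA_real_)
  min(max(1 - num / den, 0), 1)
}

## Independence baseline: free parameters are exactly the mean and
## variance moments; all covariance moments are fixed at zero.  The
## moment map is linear (sigma = D theta with indicator columns), so the
## GLS solution and residual are closed-form.
.baselineFit <- function(s, W, Gamma, momNames) {
  isCov <- grepl("^cov\\(", momNames)
  D <- diag(length(s))[, !isCov, drop = FALSE]
  DWD <- crossprod(D, W %*% D)
  thetaB <- solve(DWD, crossprod(D, W %*% s))
  r <- s - drop(D %*% thetaB)
  Qb <- drop(crossprod(r, W %*% r))
  list(Q = Qb, Delta = D, df = sum(isCov))
}

#' Compute the fit-index bundle for a fitted model
#'
#' Assembles the four chi-square tests and CFI for a
#' \linkS4class{PedSEMFit}.
#'
#' @param fit a \linkS4class{PedSEMFit}.
#' @param mcReps Monte-Carlo draws for the theoretical test.
#' @param seed RNG seed.
#' @return list with \code{table} (data.frame: index, stat, df, p),
#'   \code{cfi}, \code{weights}, \code{mcReps}, \code{seed}.
#' @export
computeFitIndices <- function(fit, mcReps = 1e5, seed = 1) {
  s <- fit@sat@s; Gamma <- fit@sat@Gamma; W <- fit@W
  df <- fit@df
  if (df < 1) {
    tab <- data.frame(
      index = c("unadjusted", "mean_adjusted", "mean_variance_adjusted",
                "theoretical"),
      stat = NA_real_, df = ifelse(df == 0, 0, df), p = NA_real_,
      stringsAsFactors = FALSE)
    return(list(table = tab, cfi = NA_real_, weights = numeric(0),
                mcReps = mcReps, seed = seed))
  }
  Delta <- momentJacobian(fit@mm, fit@theta)
  w <- mixtureWeights(W, Gamma, Delta)
  u  <- chisqUnadjusted(fit@Qmin, df)
  ma <- chisqMeanAdjusted(fit@Qmin, w, df)
  mv <- chisqMeanVarianceAdjusted(fit@Qmin, w, df)
  seeds <- .subSeeds(seed, 2)
  th <- chisqTheoretical(fit@Qmin, w, df, mcReps = mcReps, seed = seeds[1])
  ## baseline for CFI, same theoretical correction
  base <- .baselineFit(s, W, Gamma, names(s))
  wB <- mixtureWeights(W, Gamma, base$Delta)
  thB <- chisqTheoretical(base$Q, wB, base$df, mcReps = mcReps,
                          seed = seeds[2])
  tab <- data.frame(
    index = c("unadjusted", "mean_adjusted", "mean_variance_adjusted",
              "theoretical"),
    stat = c(u$stat, ma$stat, mv$stat, th$stat),
    df = c(u$df, ma$df, mv$df, th$df),
    p = c(u$p, ma$p, mv$p, th$p),
    stringsAsFactors = FALSE)
  list(table = tab,
       cfi = cfi(th$stat, th$df, thB$stat, thB$df),
       weights = w, mcReps = mcReps, seed = seed,
       baseline = list(stat = thB$stat, df = thB$df, p = thB$p))
}
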