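## Model-implied moments: per-component trait covariances, implied
## means, the Kronecker pedigree covariance, the moment map and its
## Jacobian.

#' Model-implied per-component trait covariance
#'
#' Computes \eqn{V_c(\theta) = \Lambda (I-B)^{-1} \Psi_c (I-B)^{-T}
#' \Lambda^T + \Theta_c}, the \eqn{t \times t} covariance among the
#' observed traits contributed by variance component \eqn{c}.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta free-parameter vector.
#' @param component component label (\code{"p"}, \code{"e"}, \code{"c"}
#'   or \code{"a(marker)"}).
#' @return symmetric matrix with the observed variables as dimnames.
#' @export
impliedComponentCovariance <- function(mm, theta, component) {
  ev <- mmEval(mm, theta)
  .impliedVc(ev, mm, component)
}

.ibInv <- function(ev) {
  L <- nrow(ev$B)
  if (!L) return(matrix(0, 0, 0))
  IB <- diag(L) - ev$B
  d <- det(IB)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("(I - B) is singular at the supplied parameter values")
  solve(IB)
}

.impliedVc <- function(ev, mm, component, ibi = NULL) {
  if (!(component %in% mm@components))
    stop("unknown component: ", component)
  if (is.null(ibi)) ibi <- .ibInv(ev)
  if (length(mm@latent)) {
    A <- ev$Lambda %*% ibi
    V <- A %*% ev$Psi[[component]] %*% t(A) + ev$Theta[[component]]
  } else V <- ev$Theta[[component]]
  (V + t(V)) / 2
}

#' Model-implied mean
#'
#' \eqn{\mu(x) = \nu + \Lambda (I-B)^{-1} (\alpha + \Gamma_\eta x) +
#' \Gamma_y x} for one individual's covariate vector \eqn{x}.  The
#' moment-vector entries (implied intercepts and per-covariate implied
#' slopes) are this function at \eqn{x = 0} and at unit vectors.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta free-parameter vector.
#' @param x covariate values (length = number of covariates, no missing
#'   values).
#' @return named numeric vector over the observed variables.
#' @export
impliedMean <- function(mm, theta, x = numeric(length(mm@covariates))) {
  if (anyNA(x)) stop("missing covariate values are not allowed in the mean model")
  ev <- mmEval(mm, theta)
  ibi <- .ibInv(ev)
  mu <- ev$nu
  if (length(mm@latent))
    mu <- mu + drop(ev$Lambda %*% ibi %*% (ev$alpha + ev$Ge %*% x))
  if (length(mm@covariates))
    mu <- mu + drop(ev$Gy %*% x)
  setNames(mu, mm@observed)
}

#' Assemble the per-pedigree Kronecker covariance
#'
#' \eqn{\Sigma_k = \sum_c R_{c,k} \otimes V_c(\theta)} with
#' individual-major ordering: entries are blocks of the \eqn{t} traits
#' per individual, individuals in pedigree order.
#'
#' @param V named list of \eqn{t \times t} component covariance matrices.
#' @param R named list (same names) of pedigree relationship matrices.
#' @return symmetric matrix of dimension \code{n * t}.
#' @export
assemblePedigreeCovariance <- function(V, R) {
  if (!length(V)) stop("no components supplied")
  if (!setequal(names(V), names(R)))
    stop("component names of V and R differ")
  t <- nrow(V[[1]]); n <- nrow(R[[1]])
  out <- matrix(0, n * t, n * t)
  for (c. in names(V)) {
    if (nrow(V[[c.]]) != t || nrow(R[[c.]]) != n)
      stop("dimension mismatch in component ", c.)
    out <- out + kronecker(R[[c.]], V[[c.]])
  }
  (out + t(out)) / 2
}

#' Moment names
#'
#' Deterministic ordering of the stage-1 moment vector: per observed
#' variable (model order) the intercept and one slope per covariate;
#' then per variable and component (canonical order p, e, c, a(...)) the
#' variance; then per pair (i < j in model order) and component the
#' covariance.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @return character vector of moment labels.
#' @export
momentNames <- function(mm) {
  obs <- mm@observed; comps <- mm@components; cov <- mm@covariates
  mean_ <- unlist(lapply(obs, function(v) c(paste0(v, "~1"),
                                            if (length(cov)) paste0(v, "~", cov))))
  var_ <- unlist(lapply(obs, function(v) paste0("var(", v, ",", comps, ")")))
  t <- length(obs)
  cov_ <- character(0)
  if (t > 1) {
    for (i in seq_len(t - 1)) for (j in (i + 1):t)
      cov_ <- c(cov_, paste0("cov(", obs[i], ",", obs[j], ",", comps, ")"))
  }
  c(mean_, var_, cov_)
}

#' The moment map
#'
#' Evaluates \eqn{\sigma(\theta)}: implied intercepts and covariate
#' slopes from the mean structure, and the entries of each
#' \eqn{V_c(\theta)} for variances and pairwise covariances, stacked in
#' \code{\link{momentNames}} order.  The map depends only on
#' \eqn{\theta}, never on data.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta free-parameter vector.
#' @param useNames attach moment labels (skipped in hot loops).
#' @return named numeric vector.
#' @export
momentMap <- function(mm, theta, useNames = TRUE) {
  ev <- mmEval(mm, theta)
  ibi <- .ibInv(ev)
  obs <- mm@observed; comps <- mm@components
  t <- length(obs); q <- length(mm@covariates); C <- length(comps)
  if (length(mm@latent)) {
    A <- ev$Lambda %*% ibi
    mu0 <- ev$nu + drop(A %*% ev$alpha)
    slopes <- if (q) A %*% ev$Ge + ev$Gy else ev$Gy
  } else {
    mu0 <- ev$nu
    slopes <- ev$Gy
  }
  mean_ <- if (q) as.vector(rbind(mu0, t(slopes))) else as.vector(mu0)
  Vc <- lapply(comps, function(c.) .impliedVc(ev, mm, c., ibi))
  varMat <- vapply(seq_len(t), function(i)
    vapply(Vc, function(V) V[i, i], 1), numeric(C))
  var_ <- as.vector(varMat)              # per variable, components within
  cov_ <- numeric(0)
  if (t > 1) {
    ut <- which(upper.tri(Vc[[1]]))
    ## reorder column-major upper triangle to row-wise pair order
    ri <- row(Vc[[1]])[ut]; ci <- col(Vc[[1]])[ut]
    ord <- order(ri, ci)
    covMat <- vapply(Vc, function(V) V[ut][ord], numeric(length(ut)))
    cov_ <- as.vector(t(covMat))         # per pair, components within
  }
  out <- c(mean_, var_, cov_)
  if (useNames) names(out) <- momentNames(mm)
  out
}

## Closure factory: packs the model's slot layout once for the C++
## moment-map evaluator used by the stage-2 hot loops.  Numerically
## identical to momentMap(..., useNames = FALSE); the R implementation
## above serves as its independent reference in the tests.
.makeSigma <- function(mm) {
  obs <- mm@observed; comps <- mm@components
  t <- length(obs)
  slot <- function(v, i) {
    v <- as.matrix(v); i <- as.matrix(i)
    at <- which(i > 0)
    list(v = v, at = at - 1L, par = as.integer(i[at]) - 1L)
  }
  ut <- integer(0)
  if (t > 1) {
    tmp <- matrix(0, t, t)
    u0 <- which(upper.tri(tmp))
    ut <- u0[order(row(tmp)[u0], col(tmp)[u0])] - 1L
  }
  ctx <- list(
    t = t, q = length(mm@covariates), L = length(mm@latent),
    C = length(comps),
    Lam = slot(mm@Lambda_v, mm@Lambda_i), B = slot(mm@B_v, mm@B_i),
    Ge = slot(mm@Ge_v, mm@Ge_i), Gy = slot(mm@Gy_v, mm@Gy_i),
    nu = slot(mm@nu_v, mm@nu_i), alpha = slot(mm@alpha_v, mm@alpha_i),
    Psi = lapply(comps, function(c.) slot(mm@Psi_v[[c.]], mm@Psi_i[[c.]])),
    Theta = lapply(comps, function(c.) slot(mm@Theta_v[[c.]], mm@Theta_i[[c.]])),
    ut = ut)
  ptr <- .cpp_sigma_pack(ctx)
  function(theta) drop(.cpp_sigma(ptr, theta))
}

#' Jacobian of the moment map
#'
#' Central finite differences with per-coordinate step
#' \eqn{h_j = \max(10^{-6}, 10^{-6} |\theta_j|)}.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta free-parameter vector.
#' @return matrix of dimension (number of moments) x (number of free
#'   parameters).
#' @export
momentJacobian <- function(mm, theta) {
  p <- length(theta)
  s0 <- momentMap(mm, theta, useNames = FALSE)
  J <- matrix(0, length(s0), p, dimnames = list(momentNames(mm), mm@par$name))
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (momentMap(mm, tp, useNames = FALSE) -
               momentMap(mm, tm, useNames = FALSE)) / (2 * h)
  }
  if (!all(is.finite(J))) stop("non-finite entries in moment Jacobian")
  J
}
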