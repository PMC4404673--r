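## Compile a ModelSpec into parameterized LISREL-with-covariates
## matrices with free/fixed bookkeeping, plus identification checks.

#' Compile model matrices
#'
#' Places every edge, intercept and variance-component of a parsed model
#' into the system
#' \deqn{\eta = \alpha + B\eta + \Gamma_\eta x + \textstyle\sum_c \zeta_c,
#'   \qquad y = \nu + \Lambda\eta + \Gamma_y x + \textstyle\sum_c \epsilon_c,}
#' with \eqn{\zeta_c \sim (0, \Psi_c)} and \eqn{\epsilon_c \sim (0,
#' \Theta_c)} per variance component \eqn{c}.  Latent intercepts
#' \eqn{\alpha} are fixed at 0; observed intercepts \eqn{\nu} are free.
#' The scale of each latent with indicators is anchored by fixing its
#' first loading to 1 unless the user fixed one of its loadings
#' explicitly (a fixed variance does not release the anchor); a latent
#' without indicators is anchored by a fixed path to an anchored
#' variable or by fixing all of its variance components.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return A \linkS4class{ModelMatrices}.
#' @export
buildModelMatrices <- function(spec) {
  obs <- spec@observed; lat <- spec@latent; cov <- spec@covariates
  comps <- spec@components
  t <- length(obs); L <- length(lat); q <- length(cov)

  Lambda_v <- matrix(0, t, L, dimnames = list(obs, lat))
  B_v  <- matrix(0, L, L, dimnames = list(lat, lat))
  Ge_v <- matrix(0, L, q, dimnames = list(lat, cov))
  Gy_v <- matrix(0, t, q, dimnames = list(obs, cov))
  Lambda_i <- Lambda_v; B_i <- B_v; Ge_i <- Ge_v; Gy_i <- Gy_v
  nu_v <- setNames(numeric(t), obs); nu_i <- setNames(integer(t), obs)
  alpha_v <- setNames(numeric(L), lat); alpha_i <- setNames(integer(L), lat)
  Psi_v <- Psi_i <- lapply(comps, function(c.) matrix(0, L, L, dimnames = list(lat, lat)))
  Theta_v <- Theta_i <- lapply(comps, function(c.) matrix(0, t, t, dimnames = list(obs, obs)))
  names(Psi_v) <- names(Psi_i) <- names(Theta_v) <- names(Theta_i) <- comps

  cs <- spec@constraints
  fixedCoef <- function(src, dst) {
    hit <- which(cs$kind == "coef" & cs$var1 == src & cs$var2 == dst)
    if (length(hit)) cs$value[hit[1]] else NA_real_
  }
  fixedVar <- function(v, comp) {
    hit <- which(cs$kind == "var" & cs$var1 == v & cs$comp == comp)
    if (length(hit)) cs$value[hit[1]] else NA_real_
  }

  parName <- character(0); parRole <- character(0)
  nextIdx <- 0L
  addPar <- function(name, role) {
    nextIdx <<- nextIdx + 1L
    parName <<- c(parName, name); parRole <<- c(parRole, role)
    nextIdx
  }

  ## ---- anchoring: decide which loadings get the default fix of 1 ----
  meas <- spec@measurement
  userFixedLoad <- !is.na(mapply(fixedCoef, meas$latent, meas$indicator))
  strt <- spec@structural
  latStruct <- strt[strt$rhsType == "latent", , drop = FALSE]
  userFixedPath <- !is.na(mapply(fixedCoef, latStruct$rhs, latStruct$lhs))

  ## every latent with indicators gets its first loading fixed to 1
  ## unless the user fixed one of its loadings explicitly (fixing a
  ## variance does NOT release the anchor: a latent may be doubly
  ## pinned, which keeps its scale strongly identified)
  anchored <- setNames(rep(FALSE, L), lat)
  allVarFixed <- vapply(lat, function(l)
    length(spec@vc[[l]]) > 0 &&
      all(!is.na(vapply(spec@vc[[l]], function(c.) fixedVar(l, c.), 1))), TRUE)
  autoAnchor <- setNames(rep(NA_integer_, L), lat)  # row of meas to auto-fix
  for (l in lat) {
    mi <- which(meas$latent == l)
    if (length(mi)) {
      if (!any(userFixedLoad[mi])) autoAnchor[[l]] <- mi[1]
      anchored[[l]] <- TRUE
    } else if (allVarFixed[[l]]) {
      anchored[[l]] <- TRUE
    }
  }
  ## indicator-less latents can still be anchored by a fixed path to an
  ## already-anchored variable (resolved to a fixpoint)
  repeat {
    changed <- FALSE
    for (l in lat) {
      if (anchored[[l]]) next
      si <- which(latStruct$rhs == l)
      ok <- si[userFixedPath[si] &
               (latStruct$lhs[si] %in% obs | anchored[latStruct$lhs[si]])]
      if (length(ok)) { anchored[[l]] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  if (!all(anchored))
    stop("cannot set the scale of latent variable(s): ",
         paste(lat[!anchored], collapse = ", "),
         " (no free anchor loading, fixed path or fixed variance)")

  ## ---- loadings ----
  for (i in seq_len(nrow(meas))) {
    l <- meas$latent[i]; ind <- meas$indicator[i]
    fv <- fixedCoef(l, ind)
    if (!is.na(fv)) {
      Lambda_v[ind, l] <- fv
    } else if (!is.na(autoAnchor[[l]]) && autoAnchor[[l]] == i) {
      Lambda_v[ind, l] <- 1
    } else {
      Lambda_i[ind, l] <- addPar(paste0(l, "=~", ind), "CO")
    }
  }
  ## ---- structural paths and covariate coefficients ----
  for (i in seq_len(nrow(strt))) {
    lhs <- strt$lhs[i]; rhs <- strt$rhs[i]; type <- strt$rhsType[i]
    if (type == "latent") {
      fv <- fixedCoef(rhs, lhs)
      if (!is.na(fv)) B_v[lhs, rhs] <- fv
      else B_i[lhs, rhs] <- addPar(paste0(lhs, "~", rhs), "CO")
    } else {                                   # covariate
      fv <- fixedCoef(rhs, lhs)
      if (lhs %in% lat) {
        if (!is.na(fv)) Ge_v[lhs, rhs] <- fv
        else Ge_i[lhs, rhs] <- addPar(paste0(lhs, "~", rhs), "CO")
      } else {
        if (!is.na(fv)) Gy_v[lhs, rhs] <- fv
        else Gy_i[lhs, rhs] <- addPar(paste0(lhs, "~", rhs), "CO")
      }
    }
  }
  ## ---- intercepts (latent alpha fixed at 0) ----
  for (v in obs) nu_i[v] <- addPar(paste0(v, "~1"), "IN")
  ## ---- variance components ----
  for (c. in comps) {
    for (v in c(obs, lat)) {
      if (!(c. %in% spec@vc[[v]])) next
      fv <- fixedVar(v, c.)
      if (v %in% lat) {
        if (!is.na(fv)) Psi_v[[c.]][v, v] <- fv
        else Psi_i[[c.]][v, v] <- addPar(paste0("var(", v, ",", c., ")"), "VC")
      } else {
        if (!is.na(fv)) Theta_v[[c.]][v, v] <- fv
        else Theta_i[[c.]][v, v] <- addPar(paste0("var(", v, ",", c., ")"), "VC")
      }
    }
    covRows <- which(cs$kind == "cov" & cs$comp == c.)
    for (i in covRows) {
      v1 <- cs$var1[i]; v2 <- cs$var2[i]; val <- cs$value[i]
      if (v1 %in% lat) {
        if (is.na(val))
          Psi_i[[c.]][v1, v2] <- Psi_i[[c.]][v2, v1] <-
            addPar(paste0("cov(", v1, ",", v2, ",", c., ")"), "VC")
        else Psi_v[[c.]][v1, v2] <- Psi_v[[c.]][v2, v1] <- val
      } else {
        if (is.na(val))
          Theta_i[[c.]][v1, v2] <- Theta_i[[c.]][v2, v1] <-
            addPar(paste0("cov(", v1, ",", v2, ",", c., ")"), "VC")
        else Theta_v[[c.]][v1, v2] <- Theta_v[[c.]][v2, v1] <- val
      }
    }
  }

  par <- data.frame(name = parName, role = parRole, stringsAsFactors = FALSE)
  if (anyDuplicated(par$name)) stop("duplicate parameter slot: ",
                                    par$name[duplicated(par$name)][1])
  storage.mode(Lambda_i) <- storage.mode(B_i) <- "double"
  storage.mode(Ge_i) <- storage.mode(Gy_i) <- "double"
  mm <- new("ModelMatrices", spec = spec, observed = obs, latent = lat,
            covariates = cov, components = comps,
            Lambda_v = Lambda_v, Lambda_i = Lambda_i,
            B_v = B_v, B_i = B_i, Ge_v = Ge_v, Ge_i = Ge_i,
            Gy_v = Gy_v, Gy_i = Gy_i,
            nu_v = nu_v, nu_i = as.integer(nu_i),
            alpha_v = alpha_v, alpha_i = as.integer(alpha_i),
            Psi_v = Psi_v, Psi_i = Psi_i,
            Theta_v = Theta_v, Theta_i = Theta_i, par = par)
  ## (I - B) must be invertible at default starting values
  ev <- mmEval(mm, rep(0.5, nrow(par)))
  d <- det(diag(length(lat)) - ev$B)
  if (length(lat) && abs(d) < 1e-12)
    stop("(I - B) singular at default starting values; check structural loops")
  mm
}

#' Evaluate model matrices at a parameter vector
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param theta numeric vector of free parameters (order of
#'   \code{parameterTable(mm)}).
#' @return list with numeric \code{Lambda}, \code{B}, \code{Ge},
#'   \code{Gy}, \code{nu}, \code{alpha}, and per-component lists
#'   \code{Psi}, \code{Theta}.
#' @export
mmEval <- function(mm, theta) {
  stopifnot(length(theta) == nrow(mm@par))
  fill <- function(v, i) {
    sel <- i > 0
    v[sel] <- theta[i[sel]]
    v
  }
  list(Lambda = fill(mm@Lambda_v, mm@Lambda_i),
       B = fill(mm@B_v, mm@B_i),
       Ge = fill(mm@Ge_v, mm@Ge_i),
       Gy = fill(mm@Gy_v, mm@Gy_i),
       nu = fill(mm@nu_v, mm@nu_i),
       alpha = fill(mm@alpha_v, mm@alpha_i),
       Psi = mapply(fill, mm@Psi_v, mm@Psi_i, SIMPLIFY = FALSE),
       Theta = mapply(fill, mm@Theta_v, mm@Theta_i, SIMPLIFY = FALSE))
}

#' Free-parameter table
#'
#' Lists every free parameter with its role: CO (coefficients:
#' loadings, structural paths, covariate effects), IN (intercepts) or
#' VC (variance components).
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @return data.frame(name, role).
#' @export
parameterTable <- function(mm) mm@par

#' Count of free parameters
#' @param mm a \linkS4class{ModelMatrices}.
#' @export
nFreeParameters <- function(mm) nrow(mm@par)

#' Identification check
#'
#' Degrees of freedom are the number of stage-1 moments (per-trait
#' intercept and covariate coefficients, per-trait per-component
#' variances, per-pair per-component covariances) minus the number of
#' free parameters.  The model counts as identified when the numerical
#' rank of the moment-map Jacobian equals the free-parameter count at
#' each of \code{nDraws} random parameter points (singular values below
#' \code{1e-8} of the largest treated as zero).
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @param nDraws number of random parameter draws.
#' @param seed RNG seed for the draws.
#' @return list(df, identified, nMoments, nFree).
#' @export
checkIdentification <- function(mm, nDraws = 5, seed = 1) {
  nm <- length(momentNames(mm))
  np <- nFreeParameters(mm)
  df <- nm - np
  if (df < 0)
    stop("model under-identified: ", np, " free parameters for only ",
         nm, " moments")
  ok <- TRUE
  sigmaFn <- .makeSigma(mm)
  .withSeed(seed, {
    for (i in seq_len(nDraws)) {
      th <- .heuristicThetaCenter(mm) + rnorm(np, 0, 0.2)
      J <- try(.sigmaJacobian(sigmaFn, th, nm), silent = TRUE)
      if (inherits(J, "try-error") || !all(is.finite(J))) next
      sv <- svd(J, nu = 0, nv = 0)$d
      if (sum(sv > 1e-8 * max(sv)) < np) ok <- FALSE
    }
  })
  list(df = df, identified = ok, nMoments = nm, nFree = np)
}

## neutral parameter point: coefficients 1 (structural paths 0.3 to keep
## I - B well inside invertibility), intercepts 0, variances 1
.heuristicThetaCenter <- function(mm) {
  th <- rep(1, nFreeParameters(mm))
  th[mm@par$role == "IN"] <- 0
  th[mm@par$name %in% paste0(rep(mm@latent, each = length(mm@latent)), "~",
                             rep(mm@latent, length(mm@latent)))] <- 0.3
  covSlots <- grepl("^cov\\(", mm@par$name)
  th[covSlots] <- 0.1
  th
}

setMethod("show", "ModelMatrices", function(object) {
  cat("ModelMatrices:", length(object@observed), "observed,",
      length(object@latent), "latent,", length(object@covariates),
      "covariates;", nrow(object@par), "free parameters (",
      sum(object@par$role == "CO"), "CO,",
      sum(object@par$role == "IN"), "IN,",
      sum(object@par$role == "VC"), "VC )\n")
})
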