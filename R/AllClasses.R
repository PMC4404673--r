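#' @import methods
#' @importFrom stats pchisq qchisq pnorm qnorm rbinom rnorm runif sd var
#'   quantile optim nlminb coef lm ks.test setNames rchisq complete.cases
#' @importFrom utils read.csv write.csv head modifyList capture.output
#' @useDynLib pedsem, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Pedigree: one family with optional trait, covariate and genotype data
#'
#' A \code{Pedigree} holds the members of a single family in topological
#' order (every parent precedes its offspring), together with numeric
#' phenotype, covariate and genotype matrices whose rows parallel the
#' member table.  Founders have both parent identifiers missing; loops
#' through marriage (e.g. cousin matings) are permitted, cycles through
#' descent are not.
#'
#' @slot familyId single character family identifier.
#' @slot members data.frame with columns \code{id}, \code{father},
#'   \code{mother} (character, \code{NA} for founders), \code{sex}
#'   (\code{"male"}, \code{"female"} or \code{"unknown"}), \code{proband}
#'   (logical) and \code{household} (character or \code{NA}).
#' @slot phenotypes,covariates,genotypes numeric matrices with one row per
#'   member (possibly zero columns); genotype entries are counts of the
#'   coded allele in \{0, 1, 2\} or \code{NA}.
#' @export
setClass("Pedigree",
  representation(
    familyId   = "character",
    members    = "data.frame",
    phenotypes = "matrix",
    covariates = "matrix",
    genotypes  = "matrix"
  )
)

setValidity("Pedigree", function(object) {
  msgs <- character(0)
  m <- object@members
  need <- c("id", "father", "mother", "sex", "proband", "household")
  if (!all(need %in% names(m)))
    return(paste("members table lacks columns:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (anyDuplicated(m$id))
    msgs <- c(msgs, "duplicated member ids")
  bad <- xor(is.na(m$father), is.na(m$mother))
  if (any(bad))
    msgs <- c(msgs, paste("members with exactly one parent:",
                          paste(m$id[bad], collapse = ", ")))
  ref <- c(m$father, m$mother)
  miss <- setdiff(ref[!is.na(ref)], m$id)
  if (length(miss))
    msgs <- c(msgs, paste("parents not found in family:",
                          paste(miss, collapse = ", ")))
  ## topological order: parents listed before offspring
  pos <- seq_len(nrow(m))
  names(pos) <- m$id
  for (i in pos) {
    f <- m$father[i]
    if (!is.na(f) && f %in% m$id && pos[f] >= i)
      msgs <- c(msgs, "members not in topological order (or cycle)")
  }
  for (mat in list(object@phenotypes, object@covariates, object@genotypes))
    if (nrow(mat) != nrow(m))
      msgs <- c(msgs, "data matrix row count differs from member count")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' A collection of pedigrees
#'
#' Plain list subclass whose elements are \linkS4class{Pedigree} objects;
#' this is the unit of data passed to the fitting and simulation
#' functions.
#' @export
setClass("PedigreeSet", contains = "list")

setValidity("PedigreeSet", function(object) {
  if (!all(vapply(object@.Data, is, TRUE, class2 = "Pedigree")))
    "all elements must be Pedigree objects" else TRUE
})

#' Identity-by-descent sharing data
#'
#' Long-format store of pairwise expected IBD allele-sharing proportions
#' \eqn{\hat\pi_{ij}} per family and marker, as consumed by the linkage
#' variance component.  Pairs are stored unordered; the diagonal is
#' implicit (1).
#'
#' @slot table data.frame with columns \code{family}, \code{marker},
#'   \code{id1}, \code{id2}, \code{pi}.
#' @export
setClass("IBDData", representation(table = "data.frame"))

setValidity("IBDData", function(object) {
  tb <- object@table
  need <- c("family", "marker", "id1", "id2", "pi")
  if (!all(need %in% names(tb)))
    return("IBD table needs columns family, marker, id1, id2, pi")
  if (nrow(tb) && (any(tb$pi < 0) || any(tb$pi > 1)))
    return("pi values outside [0, 1]")
  TRUE
})

#' Parsed model description
#'
#' Result of \code{\link{parseModel}}: the measurement equations
#' (latent \code{=~} indicators), structural equations (\code{~}),
#' variance-component declarations (\code{<p,e,c,a(marker)>}) and
#' equality constraints of a pedigree SEM.
#'
#' @slot observed,latent,covariates ordered variable names.
#' @slot components variance-component labels in canonical order
#'   (p, e, c, then a(marker) labels).
#' @slot measurement data.frame(latent, indicator, fixed, value).
#' @slot structural data.frame(lhs, rhs, rhsType, fixed, value) where
#'   \code{rhsType} is \code{"latent"}, \code{"observed"} or
#'   \code{"covariate"}.
#' @slot vc named list: variable -> character vector of component labels.
#' @slot constraints data.frame(kind, var1, var2, comp, value).
#' @slot text the original model description.
#' @export
setClass("ModelSpec",
  representation(
    observed    = "character",
    latent      = "character",
    covariates  = "character",
    components  = "character",
    measurement = "data.frame",
    structural  = "data.frame",
    vc          = "list",
    constraints = "data.frame",
    text        = "character"
  )
)

#' Parameterized SEM matrices
#'
#' Compiled form of a \linkS4class{ModelSpec}: every coefficient,
#' intercept and variance-component slot of the LISREL-with-covariates
#' system
#' \deqn{\eta = \alpha + B\eta + \Gamma_\eta x + \textstyle\sum_c \zeta_c,
#'   \qquad y = \nu + \Lambda\eta + \Gamma_y x + \textstyle\sum_c \epsilon_c}
#' is stored as a pair of matrices: fixed values and free-parameter
#' indices (0 = structurally fixed).  \code{par} lists the free
#' parameters with their role (CO = coefficient, IN = intercept,
#' VC = variance component).
#' @export
setClass("ModelMatrices",
  representation(
    spec       = "ModelSpec",
    observed   = "character",
    latent     = "character",
    covariates = "character",
    components = "character",
    Lambda_v = "matrix", Lambda_i = "matrix",
    B_v      = "matrix", B_i      = "matrix",
    Ge_v     = "matrix", Ge_i     = "matrix",
    Gy_v     = "matrix", Gy_i     = "matrix",
    nu_v     = "numeric", nu_i    = "integer",
    alpha_v  = "numeric", alpha_i = "integer",
    Psi_v    = "list", Psi_i = "list",
    Theta_v  = "list", Theta_i = "list",
    par      = "data.frame"
  )
)

#' Stage-1 saturated estimates
#'
#' The stacked moment vector \eqn{s} (per-trait intercepts and covariate
#' coefficients, per-trait per-component variances, per-pair
#' per-component covariances) with its robust sandwich covariance
#' \eqn{\hat\Gamma} (scaled to estimate \eqn{var(s)} directly, i.e.
#' including the \eqn{1/N}).
#' @export
setClass("SaturatedEstimates",
  representation(
    s         = "numeric",
    Gamma     = "matrix",
    scores    = "matrix",
    N         = "numeric",
    converged = "logical",
    details   = "list"
  )
)

#' Fitted pedigree SEM
#'
#' Result of the stage-2 minimum-distance fit: parameter estimates with
#' sandwich standard errors, the minimized distance, and the fit-index
#' bundle.
#' @export
setClass("PedSEMFit",
  representation(
    theta      = "numeric",
    vcov       = "matrix",
    par        = "data.frame",
    Qmin       = "numeric",
    df         = "numeric",
    weightType = "character",
    W          = "matrix",
    mm         = "ModelMatrices",
    sat        = "SaturatedEstimates",
    fitIndices = "list",
    converged  = "logical",
    nStarts    = "numeric",
    seed       = "numeric"
  )
)

#' Phased founder haplotype panel
#'
#' Reference panel of phased 0/1 haplotypes from which pedigree founders
#' draw their chromosomes during gene dropping (the synthetic stand-in
#' for a phased population panel).  Allele 1 is the coded (minor)
#' allele.
#'
#' @slot markers data.frame(name, pos) with strictly increasing base-pair
#'   positions.
#' @slot haplotypes integer matrix, rows = phased haplotypes,
#'   columns = markers, entries in \{0, 1\}.
#' @export
setClass("HaplotypePanel",
  representation(markers = "data.frame", haplotypes = "matrix")
)

setValidity("HaplotypePanel", function(object) {
  h <- object@haplotypes
  if (nrow(h) < 2) return("panel needs at least 2 haplotypes")
  if (length(h) && !all(h %in% c(0L, 1L))) return("allele codes must be 0/1")
  if (ncol(h) != nrow(object@markers)) return("marker count mismatch")
  if (is.unsorted(object@markers$pos, strictly = TRUE))
    return("marker positions must be strictly increasing")
  TRUE
})
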