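## Kinship and per-component relationship matrices.

#' Kinship coefficient matrix
#'
#' Computes the matrix of kinship coefficients
#' \eqn{\phi_{ij}} = P(a random allele drawn from i is identical by
#' descent to a random allele drawn from j) by the standard recursion in
#' topological order:
#' \deqn{\phi_{ii} = \tfrac12 (1 + \phi_{f_i m_i}), \qquad
#'       \phi_{ij} = \tfrac12 (\phi_{f_i j} + \phi_{m_i j})}
#' with \eqn{\phi} of a missing parent equal to 0.  The recursion handles
#' inbreeding and pedigree loops without special-casing; the diagonal is
#' \eqn{(1 + F_i)/2} where \eqn{F_i} is the inbreeding coefficient.
#'
#' @param ped a \linkS4class{Pedigree} (members already topologically
#'   sorted by construction).
#' @return symmetric matrix with dimnames the member ids.
#' @export
kinshipMatrix <- function(ped) {
  m <- ped@members
  n <- nrow(m)
  phi <- matrix(0, n, n, dimnames = list(m$id, m$id))
  fa <- match(m$father, m$id)
  mo <- match(m$mother, m$id)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {                # founder
      phi[i, i] <- 0.5
    } else {
      if (fa[i] >= i || mo[i] >= i)
        stop("internal error: pedigree not topologically ordered")
      if (i > 1) {
        j <- seq_len(i - 1)
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
      }
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
  }
  phi
}

.componentLabels <- c("polygenic", "environment", "household", "linkage")

#' Per-component relationship matrix
#'
#' Returns the pedigree-level matrix \eqn{R_c} that couples a variance
#' component across family members:
#' \itemize{
#'   \item \code{polygenic}: the numerator relationship matrix
#'     \eqn{2\Phi} (unit diagonal for non-inbred individuals), so a
#'     polygenic variance parameter is the additive genetic variance of
#'     one individual;
#'   \item \code{environment}: the identity;
#'   \item \code{household}: 1 within a household group, 0 between; when
#'     no household codes are present the whole family is one household;
#'   \item \code{linkage}: the marker-specific IBD sharing matrix
#'     \eqn{\hat\pi} with unit diagonal, taken from \code{ibd}.
#' }
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param component one of \code{"polygenic"}, \code{"environment"},
#'   \code{"household"}, \code{"linkage"}.
#' @param ibd an \linkS4class{IBDData}, required for linkage.
#' @param marker marker name, required for linkage.
#' @return symmetric matrix of dimension \code{pedSize(ped)}.
#' @export
relationshipMatrix <- function(ped,
                               component = c("polygenic", "environment",
                                             "household", "linkage"),
                               ibd = NULL, marker = NULL) {
  component <- match.arg(component)
  ids <- ped@members$id
  n <- length(ids)
  switch(component,
    polygenic = 2 * kinshipMatrix(ped),
    environment = {
      out <- diag(1, n, n)
      dimnames(out) <- list(ids, ids)
      out
    },
    household = {
      hh <- ped@members$household
      if (all(is.na(hh))) hh <- rep("1", n)
      out <- outer(hh, hh, function(a, b) as.numeric(!is.na(a) & !is.na(b) & a == b))
      diag(out) <- 1
      dimnames(out) <- list(ids, ids)
      out
    },
    linkage = {
      if (is.null(ibd) || is.null(marker))
        stop("linkage component requires 'ibd' data and a 'marker' name")
      ibdMatrix(ibd, ped@familyId, marker, ids)
    })
}

## Map a model component label ("p", "e", "c", "a(marker)") to R_c for
## one pedigree.
.componentMatrix <- function(ped, label, ibd = NULL) {
  if (label == "p") return(relationshipMatrix(ped, "polygenic"))
  if (label == "e") return(relationshipMatrix(ped, "environment"))
  if (label == "c") return(relationshipMatrix(ped, "household"))
  mk <- .linkageMarker(label)
  if (!is.na(mk))
    return(relationshipMatrix(ped, "linkage", ibd = ibd, marker = mk))
  stop("unknown variance component label: ", label)
}

.linkageMarker <- function(label) {
  m <- regmatches(label, regexec("^a\\(([^)]+)\\)$", label))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}
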