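## Parser for the model-description language.
##
## One statement per line (or `;`-separated), `#` starts a comment:
##   L1 =~ P1 + P2 + P3          measurement equation
##   bp ~ anger + stress         structural equation
##   L1 ~ rs6040343 + <p,e>      covariate regression + variance components
##   P1 ~ <e>                    variance components only
##   latent(g1)                  declare a latent without indicators
##   coef(g1, z1) = 1            fix a coefficient
##   var(stress, p) = 0.1        fix a variance component
##   cov(P1, P2, e) = 0          fix a residual covariance
##   cov(P1, P2, e)              free a residual covariance
## Variables on a `~` right-hand side that are neither latents nor
## observed traits are covariates (fixed regressors, e.g. SNP allele
## counts or age).  Unannotated variables default to a single residual
## environmental component <e>.

.trim <- function(x) gsub("^\\s+|\\s+$", "", x)

.splitStatements <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  st <- unlist(strsplit(lines, ";", fixed = TRUE))
  st <- .trim(st)
  st[nzchar(st)]
}

.canonicalComponents <- function(labels) {
  base <- c("p", "e", "c")
  a <- labels[grepl("^a\\(", labels)]
  c(intersect(base, labels), a[!duplicated(a)])
}

.parseVCList <- function(txt, line) {
  parts <- .trim(unlist(strsplit(txt, ",")))
  ok <- parts == "p" | parts == "e" | parts == "c" | grepl("^a\\([^)]+\\)$", parts)
  if (!all(ok))
    stop("line ", line, ": unknown variance component label '",
         parts[!ok][1], "' (expected p, e, c or a(marker))")
  parts
}

#' Parse a model description
#'
#' Parses the model language (see Details) into a
#' \linkS4class{ModelSpec}: ordered observed, latent and covariate
#' variables, measurement and structural edges, per-variable
#' variance-component declarations and constraints.
#'
#' @details Measurement equations use \code{=~}, structural equations
#' use \code{~}; a trailing \code{<p,e,...>} term on a \code{~}
#' right-hand side declares the left-hand variable's variance
#' components (p = polygenic, e = residual environment, c = shared
#' household, \code{a(marker)} = marker-specific IBD linkage).
#' Constraints use \code{=} with \code{coef()}, \code{var()} or
#' \code{cov()}.  A latent without indicators (e.g. a pleiotropy factor
#' whose scale is set by a fixed path) is declared with
#' \code{latent(name)}; alternatively a higher-order \code{=~} whose
#' indicators are themselves latents places its edges in the structural
#' matrix.
#'
#' @param text model description string (or path to a \code{.model}
#'   file when \code{file = TRUE}).
#' @param file logical; read \code{text} as a file path.
#' @return A \linkS4class{ModelSpec}.
#' @export
parseModel <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text), collapse = "\n")
  if (!nzchar(.trim(paste(text, collapse = "")))) stop("empty model description")
  st <- .splitStatements(paste(text, collapse = "\n"))

  meas <- list()    # latent -> character vector of indicators
  struct <- list()  # list(lhs, rhs vector)
  vc <- list()
  declaredLatent <- character(0)
  constraints <- data.frame(kind = character(0), var1 = character(0),
                            var2 = character(0), comp = character(0),
                            value = numeric(0), stringsAsFactors = FALSE)
  freeCovs <- list()

  for (ln in seq_along(st)) {
    s <- st[ln]
    if (grepl("^latent\\s*\\(", s)) {
      m <- regmatches(s, regexec("^latent\\s*\\(\\s*([^)\\s]+)\\s*\\)$", s))[[1]]
      if (length(m) != 2) stop("line ", ln, ": malformed latent() declaration")
      declaredLatent <- c(declaredLatent, m[2])
    } else if (grepl("=~", s, fixed = TRUE)) {
      pp <- .trim(strsplit(s, "=~", fixed = TRUE)[[1]])
      if (length(pp) != 2 || !nzchar(pp[1]))
        stop("line ", ln, ": malformed measurement equation")
      inds <- .trim(unlist(strsplit(pp[2], "+", fixed = TRUE)))
      if (!all(nzchar(inds))) stop("line ", ln, ": empty indicator")
      meas[[pp[1]]] <- c(meas[[pp[1]]], inds)
    } else if (grepl("^(coef|var|cov)\\s*\\(", s)) {
      m <- regmatches(s, regexec(
        "^(coef|var|cov)\\s*\\(([^)]*)\\)\\s*(=\\s*(-?[0-9.eE+]+))?$", s))[[1]]
      if (!length(m)) stop("line ", ln, ": malformed constraint")
      kind <- m[2]
      args <- .trim(unlist(strsplit(m[3], ",")))
      hasVal <- nzchar(m[4])
      val <- if (hasVal) as.numeric(m[5]) else NA_real_
      if (kind == "coef") {
        if (length(args) != 2 || !hasVal)
          stop("line ", ln, ": coef(a, b) = value expected")
        constraints <- rbind(constraints, data.frame(
          kind = "coef", var1 = args[1], var2 = args[2], comp = NA,
          value = val, stringsAsFactors = FALSE))
      } else if (kind == "var") {
        if (length(args) != 2 || !hasVal)
          stop("line ", ln, ": var(v, comp) = value expected")
        .parseVCList(args[2], ln)
        constraints <- rbind(constraints, data.frame(
          kind = "var", var1 = args[1], var2 = NA, comp = args[2],
          value = val, stringsAsFactors = FALSE))
      } else {
        if (length(args) != 3)
          stop("line ", ln, ": cov(v1, v2, comp) [= value] expected")
        .parseVCList(args[3], ln)
        if (hasVal) {
          constraints <- rbind(constraints, data.frame(
            kind = "cov", var1 = args[1], var2 = args[2], comp = args[3],
            value = val, stringsAsFactors = FALSE))
        } else {
          freeCovs[[length(freeCovs) + 1]] <- args
        }
      }
    } else if (grepl("~", s, fixed = TRUE)) {
      pp <- .trim(strsplit(s, "~", fixed = TRUE)[[1]])
      if (length(pp) != 2 || !nzchar(pp[1]))
        stop("line ", ln, ": malformed structural equation")
      terms <- .trim(unlist(strsplit(pp[2], "+", fixed = TRUE)))
      vcterm <- grepl("^<.*>$", terms)
      for (tt in terms[vcterm]) {
        labels <- .parseVCList(gsub("^<|>$", "", tt), ln)
        vc[[pp[1]]] <- unique(c(vc[[pp[1]]], labels))
      }
      rhs <- terms[!vcterm]
      if (length(rhs))
        struct[[length(struct) + 1]] <- list(lhs = pp[1], rhs = rhs)
      else if (is.null(vc[[pp[1]]]))
        stop("line ", ln, ": empty right-hand side")
      if (!(pp[1] %in% names(vc))) vc[pp[1]] <- list(NULL)
    } else {
      stop("line ", ln, ": cannot parse statement '", s, "'")
    }
  }

  measLHS <- names(meas)
  allInd <- unique(unlist(meas))
  latent <- unique(c(measLHS, declaredLatent))
  structLHS <- vapply(struct, function(x) x$lhs, "")
  modeled <- unique(c(allInd, structLHS, names(vc)))
  observed <- setdiff(modeled, latent)
  rhsVars <- unique(unlist(lapply(struct, function(x) x$rhs)))
  covariates <- as.character(setdiff(rhsVars, c(latent, observed)))
  observed <- unique(c(intersect(allInd, observed),
                       setdiff(observed, allInd)))  # indicator order first

  ## measurement table; higher-order =~ rows (latent indicator) are
  ## moved to the structural set
  mrows <- list(); srows <- list()
  for (l in measLHS) {
    for (ind in meas[[l]]) {
      if (ind %in% latent && ind != l)
        srows[[length(srows) + 1]] <- data.frame(
          lhs = ind, rhs = l, rhsType = "latent",
          fixed = FALSE, value = NA_real_, stringsAsFactors = FALSE)
      else
        mrows[[length(mrows) + 1]] <- data.frame(
          latent = l, indicator = ind, fixed = FALSE, value = NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  for (eq in struct) {
    for (r in eq$rhs) {
      type <- if (r %in% latent) "latent"
              else if (r %in% observed) "observed"
              else "covariate"
      if (type == "latent" && eq$lhs %in% observed) {
        ## observed ~ latent is a measurement edge
        mrows[[length(mrows) + 1]] <- data.frame(
          latent = r, indicator = eq$lhs, fixed = FALSE, value = NA_real_,
          stringsAsFactors = FALSE)
      } else if (type == "observed") {
        stop("paths from observed traits to other variables are not ",
             "supported (", eq$lhs, " ~ ", r, "); use a latent")
      } else {
        srows[[length(srows) + 1]] <- data.frame(
          lhs = eq$lhs, rhs = r, rhsType = type, fixed = FALSE,
          value = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  measurement <- if (length(mrows)) do.call(rbind, mrows) else
    data.frame(latent = character(0), indicator = character(0),
               fixed = logical(0), value = numeric(0))
  structural <- if (length(srows)) do.call(rbind, srows) else
    data.frame(lhs = character(0), rhs = character(0),
               rhsType = character(0), fixed = logical(0),
               value = numeric(0))
  if (anyDuplicated(paste(measurement$latent, measurement$indicator)))
    stop("duplicate measurement edge")

  ## default components
  for (v in c(observed, latent))
    if (is.null(vc[[v]]) || !length(vc[[v]])) vc[[v]] <- "e"
  vc <- vc[c(observed, latent)]

  ## free residual covariances enter as constraints with value = NA
  for (fc in freeCovs)
    constraints <- rbind(constraints, data.frame(
      kind = "cov", var1 = fc[1], var2 = fc[2], comp = fc[3],
      value = NA_real_, stringsAsFactors = FALSE))

  components <- .canonicalComponents(unique(c(unlist(vc),
                                              constraints$comp[!is.na(constraints$comp)])))

  bad <- intersect(observed, latent)
  if (length(bad))
    stop("variable(s) both observed and latent: ", paste(bad, collapse = ", "))
  if (!length(observed)) stop("model has no observed variables")

  spec <- new("ModelSpec", observed = observed, latent = latent,
              covariates = covariates, components = components,
              measurement = measurement, structural = structural,
              vc = vc, constraints = constraints,
              text = paste(text, collapse = "\n"))
  .checkConstraintSlots(spec)
  spec
}

## every constrained slot must exist
.checkConstraintSlots <- function(spec) {
  cs <- spec@constraints
  for (i in seq_len(nrow(cs))) {
    r <- cs[i, ]
    if (r$kind == "coef") {
      hit <- any(spec@measurement$latent == r$var1 &
                 spec@measurement$indicator == r$var2) ||
             any(spec@structural$lhs == r$var2 & spec@structural$rhs == r$var1)
      if (!hit)
        stop("constraint coef(", r$var1, ", ", r$var2,
             ") does not match any model edge")
    } else if (r$kind == "var") {
      if (!(r$var1 %in% names(spec@vc)) || !(r$comp %in% spec@vc[[r$var1]]))
        stop("constraint var(", r$var1, ", ", r$comp,
             ") does not match a declared component")
    } else {
      for (v in c(r$var1, r$var2))
        if (!(v %in% names(spec@vc)))
          stop("constraint cov(", r$var1, ", ", r$var2, ", ", r$comp,
               ") references unknown variable ", v)
      both <- (r$var1 %in% spec@observed) == (r$var2 %in% spec@observed)
      if (!both)
        stop("cov() constraints must pair two observed or two latent variables")
    }
  }
  invisible(TRUE)
}

#' Serialize a ModelSpec back to model-language text
#'
#' Produces a canonical text rendering such that
#' \code{parseModel(serializeModel(spec))} reproduces \code{spec}.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return single character string.
#' @export
serializeModel <- function(spec) {
  out <- character(0)
  for (l in spec@latent) {
    inds <- spec@measurement$indicator[spec@measurement$latent == l]
    if (length(inds))
      out <- c(out, paste(l, "=~", paste(inds, collapse = " + ")))
    else
      out <- c(out, paste0("latent(", l, ")"))
  }
  byLHS <- split(spec@structural, spec@structural$lhs)
  for (v in c(spec@observed, spec@latent)) {
    rhs <- character(0)
    if (v %in% names(byLHS)) rhs <- byLHS[[v]]$rhs
    rhs <- c(rhs, paste0("<", paste(spec@vc[[v]], collapse = ","), ">"))
    out <- c(out, paste(v, "~", paste(rhs, collapse = " + ")))
  }
  cs <- spec@constraints
  for (i in seq_len(nrow(cs))) {
    r <- cs[i, ]
    lhs <- switch(r$kind,
      coef = paste0("coef(", r$var1, ", ", r$var2, ")"),
      var  = paste0("var(", r$var1, ", ", r$comp, ")"),
      cov  = paste0("cov(", r$var1, ", ", r$var2, ", ", r$comp, ")"))
    out <- c(out, if (is.na(r$value)) lhs else paste(lhs, "=", r$value))
  }
  paste(out, collapse = "\n")
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", length(object@observed), "observed,",
      length(object@latent), "latent,",
      length(object@covariates), "covariate(s); components:",
      paste(object@components, collapse = ", "), "\n")
})
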