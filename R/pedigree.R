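## Pedigree construction, CSV input/output and validation.

.sexLevels <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "male")]   <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out
}

.asParent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

## Kahn topological sort of the member table; error on descent cycles.
.topoSortMembers <- function(m, familyId = "?") {
  n <- nrow(m)
  pos <- seq_len(n)
  names(pos) <- m$id
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(m$father[i], m$mother[i])) {
      if (!is.na(p)) {
        j <- pos[[p]]
        indeg[i] <- indeg[i] + 1L
        kids[[j]] <- c(kids[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != n)
    stop("cyclic parentage in family ", familyId)
  order
}

#' Construct a Pedigree
#'
#' Builds a validated \linkS4class{Pedigree} from a member table and
#' optional data matrices.  Members are topologically sorted (parents
#' before offspring); individuals referenced only as parents are
#' auto-created as founders with all data missing, with a warning.
#'
#' @param familyId family identifier.
#' @param members data.frame with at least \code{id}, \code{father},
#'   \code{mother}; optional \code{sex}, \code{proband},
#'   \code{household}.  Missing parents are coded \code{NA}, \code{"0"}
#'   or \code{""}.
#' @param phenotypes,covariates,genotypes numeric matrices or data.frames
#'   with one row per member (in the input member order).
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(familyId, members, phenotypes = NULL,
                     covariates = NULL, genotypes = NULL) {
  m <- as.data.frame(members, stringsAsFactors = FALSE)
  m$id <- as.character(m$id)
  m$father <- .asParent(m$father)
  m$mother <- .asParent(m$mother)
  if (is.null(m$sex)) m$sex <- "unknown" else m$sex <- .sexLevels(m$sex)
  if (is.null(m$proband)) m$proband <- FALSE
  m$proband <- as.logical(m$proband) %in% TRUE
  if (is.null(m$household)) m$household <- NA_character_
  m$household <- as.character(m$household)

  fixmat <- function(x, n) {
    if (is.null(x)) return(matrix(numeric(0), nrow = n, ncol = 0))
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
  n0 <- nrow(m)
  ph <- fixmat(phenotypes, n0); cv <- fixmat(covariates, n0)
  gt <- fixmat(genotypes, n0)

  ## auto-create parents present only as references
  ref <- unique(c(m$father, m$mother))
  ref <- ref[!is.na(ref)]
  extra <- setdiff(ref, m$id)
  if (length(extra)) {
    warning("family ", familyId, ": auto-creating founder(s) ",
            paste(extra, collapse = ", "), " referenced only as parents")
    add <- data.frame(id = extra, father = NA_character_,
                      mother = NA_character_, sex = "unknown",
                      proband = FALSE, household = NA_character_,
                      stringsAsFactors = FALSE)
    m <- rbind(m[, names(add)], add)
    pad <- function(x) rbind(x, matrix(NA_real_, length(extra), ncol(x)))
    ph <- pad(ph); cv <- pad(cv); gt <- pad(gt)
  } else {
    m <- m[, c("id", "father", "mother", "sex", "proband", "household")]
  }
  ord <- .topoSortMembers(m, familyId)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  ph <- ph[ord, , drop = FALSE]; cv <- cv[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(ph) <- rownames(cv) <- rownames(gt) <- m$id
  new("Pedigree", familyId = as.character(familyId), members = m,
      phenotypes = ph, covariates = cv, genotypes = gt)
}

#' @rdname Pedigree
#' @param peds list of \linkS4class{Pedigree} objects.
#' @export
PedigreeSet <- function(peds) new("PedigreeSet", peds)

#' @export
setGeneric("familyId", function(object) standardGeneric("familyId"))
#' @rdname Pedigree
#' @param object a Pedigree.
#' @export
setMethod("familyId", "Pedigree", function(object) object@familyId)

#' @export
setGeneric("pedSize", function(object) standardGeneric("pedSize"))
#' @rdname Pedigree
#' @export
setMethod("pedSize", "Pedigree", function(object) nrow(object@members))

#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname Pedigree
#' @export
setMethod("members", "Pedigree", function(object) object@members)

#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname Pedigree
#' @export
setMethod("phenotypes", "Pedigree", function(object) object@phenotypes)

#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname Pedigree
#' @export
setMethod("covariates", "Pedigree", function(object) object@covariates)

#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname Pedigree
#' @export
setMethod("genotypes", "Pedigree", function(object) object@genotypes)

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree", object@familyId, "with", pedSize(object), "members (",
      sum(is.na(object@members$father)), "founders );",
      ncol(object@phenotypes), "phenotypes,",
      ncol(object@covariates), "covariates,",
      ncol(object@genotypes), "markers\n")
})

setMethod("show", "PedigreeSet", function(object) {
  cat("PedigreeSet:", length(object), "pedigrees,",
      sum(vapply(object, pedSize, 1)), "individuals\n")
})

#' Read pedigrees from CSV
#'
#' Reads a pedigree file with one row per individual and splits it into
#' one \linkS4class{Pedigree} per distinct family identifier.  Mandatory
#' columns (after applying \code{dialect}) are family, id, father and
#' mother; missing parents are coded \code{"0"} or empty.  Remaining
#' columns are assigned to phenotypes, covariates or genotypes via the
#' corresponding arguments; unassigned columns default to phenotypes.
#'
#' @param path CSV file path.
#' @param dialect named list mapping the roles \code{family}, \code{id},
#'   \code{father}, \code{mother}, \code{sex}, \code{proband},
#'   \code{household} to column names in the file.
#' @param phenotypes,covariates,genotypes character vectors of data
#'   column names.
#' @return A \linkS4class{PedigreeSet}.
#' @export
readPedigree <- function(path,
                         dialect = list(),
                         phenotypes = NULL, covariates = NULL,
                         genotypes = NULL) {
  d <- modifyList(list(family = "family", id = "id", father = "father",
                       mother = "mother", sex = "sex", proband = "proband",
                       household = "household"), dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("family", "id", "father", "mother"))
    if (!d[[col]] %in% names(df))
      stop("pedigree file lacks mandatory column '", d[[col]], "' (", col, ")")
  used <- unlist(d[c("family", "id", "father", "mother")])
  for (opt in c("sex", "proband", "household"))
    if (d[[opt]] %in% names(df)) used <- c(used, d[[opt]])
  datacols <- setdiff(names(df), used)
  if (is.null(phenotypes) && is.null(covariates) && is.null(genotypes))
    phenotypes <- datacols
  for (colset in list(phenotypes, covariates, genotypes)) {
    miss <- setdiff(colset, names(df))
    if (length(miss))
      stop("data column(s) not in file: ", paste(miss, collapse = ", "))
  }
  fams <- unique(as.character(df[[d$family]]))
  peds <- lapply(fams, function(f) {
    sub <- df[as.character(df[[d$family]]) == f, , drop = FALSE]
    mem <- data.frame(
      id = as.character(sub[[d$id]]),
      father = as.character(sub[[d$father]]),
      mother = as.character(sub[[d$mother]]),
      stringsAsFactors = FALSE)
    if (d$sex %in% names(sub)) mem$sex <- sub[[d$sex]]
    if (d$proband %in% names(sub)) mem$proband <- sub[[d$proband]] %in% c(1, "1", TRUE, "TRUE", "yes")
    if (d$household %in% names(sub)) mem$household <- as.character(sub[[d$household]])
    pick <- function(cols) if (length(cols)) as.matrix(sub[, cols, drop = FALSE]) else NULL
    Pedigree(f, mem, phenotypes = pick(phenotypes),
             covariates = pick(covariates), genotypes = pick(genotypes))
  })
  PedigreeSet(peds)
}

#' Write pedigrees to CSV
#'
#' Inverse of \code{\link{readPedigree}} (lossless round trip, modulo
#' topological reordering performed at read time).
#'
#' @param peds a \linkS4class{PedigreeSet}.
#' @param path output CSV path.
#' @export
writePedigree <- function(peds, path) {
  rows <- lapply(peds, function(p) {
    m <- p@members
    out <- data.frame(family = p@familyId, id = m$id,
                      father = ifelse(is.na(m$father), "0", m$father),
                      mother = ifelse(is.na(m$mother), "0", m$mother),
                      sex = ifelse(m$sex == "male", 1L,
                            ifelse(m$sex == "female", 2L, 0L)),
                      proband = as.integer(m$proband),
                      stringsAsFactors = FALSE)
    if (any(!is.na(m$household))) out$household <- m$household
    cbind(out, as.data.frame(p@phenotypes), as.data.frame(p@covariates),
          as.data.frame(p@genotypes))
  })
  ## pad to the union of columns so heterogeneous sets still write
  allcols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(allcols, names(r))) r[[cc]] <- NA
    r[, allcols, drop = FALSE]
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Diagnose pedigree structure problems
#'
#' Checks the invariants of a pedigree and returns diagnostics instead of
#' raising: an empty result means the pedigree is valid.  Multiple
#' probands yield a warning-level diagnostic (analysis conditions on the
#' first proband); descent cycles and parent-sex inconsistencies are
#' errors.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return data.frame with columns \code{severity} ("warning"/"error")
#'   and \code{message}; zero rows iff all invariants hold.
#' @export
validatePedigree <- function(ped) {
  out <- data.frame(severity = character(0), message = character(0),
                    stringsAsFactors = FALSE)
  add <- function(sev, msg)
    rbind(out, data.frame(severity = sev, message = msg,
                          stringsAsFactors = FALSE))
  m <- ped@members
  bad <- xor(is.na(m$father), is.na(m$mother))
  if (any(bad))
    out <- add("error", paste("one parent missing for:",
                              paste(m$id[bad], collapse = ", ")))
  ref <- c(m$father, m$mother)
  miss <- setdiff(ref[!is.na(ref)], m$id)
  if (length(miss))
    out <- add("error", paste("unknown parent id:", paste(miss, collapse = ", ")))
  cyc <- tryCatch({.topoSortMembers(m, ped@familyId); FALSE},
                  error = function(e) TRUE)
  if (cyc) out <- add("error", "cyclic parentage (individual is its own ancestor)")
  for (i in seq_len(nrow(m))) {
    f <- m$father[i]; mo <- m$mother[i]
    if (!is.na(f) && f %in% m$id && m$sex[match(f, m$id)] == "female")
      out <- add("error", paste("father", f, "recorded as female"))
    if (!is.na(mo) && mo %in% m$id && m$sex[match(mo, m$id)] == "male")
      out <- add("error", paste("mother", mo, "recorded as male"))
  }
  if (sum(m$proband) > 1)
    out <- add("warning",
               "multiple probands; analysis conditions on the first in file order")
  out
}

#' Read and write IBD sharing files
#'
#' The IBD file dialect is a CSV with columns \code{family},
#' \code{marker}, \code{id1}, \code{id2}, \code{pi}, where \code{pi} is
#' the expected proportion of alleles shared identical by descent by the
#' pair at the marker.  Storage is symmetric in the pair; a pair absent
#' from the store is an error at lookup time (expected sharing is never
#' imputed from the kinship).
#'
#' @param path CSV file path.
#' @return \code{readIBD}: an \linkS4class{IBDData}.
#' @export
readIBD <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("family", "marker", "id1", "id2", "pi")
  if (!all(need %in% names(df)))
    stop("IBD file needs columns ", paste(need, collapse = ", "))
  if (nrow(df) && (any(df$pi < 0 | df$pi > 1)))
    stop("IBD proportion pi outside [0, 1]")
  for (cc in c("family", "marker", "id1", "id2"))
    df[[cc]] <- as.character(df[[cc]])
  new("IBDData", table = df)
}

#' @rdname readIBD
#' @param ibd an \linkS4class{IBDData}.
#' @export
writeIBD <- function(ibd, path) {
  write.csv(ibd@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readIBD
#' @param table data.frame(family, marker, id1, id2, pi).
#' @export
IBDData <- function(table = data.frame(family = character(0),
                                       marker = character(0),
                                       id1 = character(0),
                                       id2 = character(0),
                                       pi = numeric(0))) {
  new("IBDData", table = as.data.frame(table, stringsAsFactors = FALSE))
}

#' @rdname readIBD
#' @param family,marker family and marker identifiers.
#' @param ids member ids defining the matrix order.
#' @return \code{ibdMatrix}: the symmetric matrix of \eqn{\hat\pi}
#'   values with unit diagonal.
#' @export
ibdMatrix <- function(ibd, family, marker, ids) {
  tb <- ibd@table
  tb <- tb[tb$family == family & tb$marker == marker, , drop = FALSE]
  n <- length(ids)
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  if (n < 2) return(out)
  i1 <- match(tb$id1, ids); i2 <- match(tb$id2, ids)
  ok <- !is.na(i1) & !is.na(i2)
  filled <- diag(TRUE, n)
  out[cbind(i1[ok], i2[ok])] <- tb$pi[ok]
  out[cbind(i2[ok], i1[ok])] <- tb$pi[ok]
  filled[cbind(i1[ok], i2[ok])] <- TRUE
  filled[cbind(i2[ok], i1[ok])] <- TRUE
  if (!all(filled)) {
    miss <- which(!filled, arr.ind = TRUE)[1, ]
    stop("no IBD entry for pair (", ids[miss[1]], ", ", ids[miss[2]],
         ") in family ", family, " at marker ", marker)
  }
  out
}
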