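## Path-diagram DOT export and fit reports.

#' Export a model as a Graphviz DOT path diagram
#'
#' Latent variables are drawn as ellipses, observed traits as boxes and
#' covariates as plain nodes; loadings and structural paths are
#' single-headed edges (fixed values printed as edge labels) and every
#' variance component contributes one double-headed self-loop labelled
#' with its component letter.  Node ordering is deterministic.  Rendering
#' to an image is left to external Graphviz tools.
#'
#' @param spec a \linkS4class{ModelSpec} (or model text).
#' @param layout \code{"hierarchical"} (top-down ranks) or
#'   \code{"circular"} (circo engine hint).
#' @return single character string of DOT source.
#' @export
modelToDot <- function(spec, layout = c("hierarchical", "circular")) {
  layout <- match.arg(layout)
  if (is.character(spec)) spec <- parseModel(spec)
  qd <- function(x) paste0("\"", x, "\"")
  out <- c("digraph model {",
           if (layout == "hierarchical") "  rankdir=TB;"
           else "  layout=circo;")
  for (l in spec@latent)
    out <- c(out, paste0("  ", qd(l), " [shape=ellipse];"))
  for (v in spec@observed)
    out <- c(out, paste0("  ", qd(v), " [shape=box];"))
  for (x in spec@covariates)
    out <- c(out, paste0("  ", qd(x), " [shape=plaintext];"))
  cs <- spec@constraints
  fixedOf <- function(src, dst) {
    hit <- which(cs$kind == "coef" & cs$var1 == src & cs$var2 == dst)
    if (length(hit)) cs$value[hit[1]] else NA_real_
  }
  edge <- function(from, to, label = NA) {
    paste0("  ", qd(from), " -> ", qd(to),
           if (!is.na(label)) paste0(" [label=", qd(format(label)), "]"),
           ";")
  }
  m <- spec@measurement
  for (i in seq_len(nrow(m)))
    out <- c(out, edge(m$latent[i], m$indicator[i],
                       fixedOf(m$latent[i], m$indicator[i])))
  st <- spec@structural
  for (i in seq_len(nrow(st)))
    out <- c(out, edge(st$rhs[i], st$lhs[i],
                       fixedOf(st$rhs[i], st$lhs[i])))
  for (v in c(spec@observed, spec@latent))
    for (c. in spec@vc[[v]])
      out <- c(out, paste0("  ", qd(v), " -> ", qd(v),
                           " [dir=both, label=", qd(c.), "];"))
  out <- c(out, "}")
  paste(out, collapse = "\n")
}

#' Fit report
#'
#' Renders a fitted model as plain text or machine-parsable TSV: the
#' parameter table (free parameters with estimate, SE, z, p; fixed slots
#' marked \code{(fixed)} without SE), the four fit indices, the CFI, the
#' seed and the weight choice.
#'
#' @param fit a \linkS4class{PedSEMFit}.
#' @param format \code{"text"} or \code{"tsv"}.
#' @return single character string.
#' @export
fitReport <- function(fit, format = c("text", "tsv")) {
  format <- match.arg(format)
  par <- fit@par
  cs <- fit@mm@spec@constraints
  fixedRows <- NULL
  if (nrow(cs)) {
    fx <- cs[!is.na(cs$value), , drop = FALSE]
    if (nrow(fx)) {
      nm <- vapply(seq_len(nrow(fx)), function(i) {
        r <- fx[i, ]
        switch(r$kind,
               coef = paste0(r$var1, "->", r$var2),
               var = paste0("var(", r$var1, ",", r$comp, ")"),
               cov = paste0("cov(", r$var1, ",", r$var2, ",", r$comp, ")"))
      }, "")
      fixedRows <- data.frame(name = nm, role = "fixed",
                              estimate = fx$value, se = NA_real_,
                              z = NA_real_, p = NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  fi <- fit@fitIndices
  fitTab <- if (length(fi)) fi$table else
    data.frame(index = character(0), stat = numeric(0), df = numeric(0),
               p = numeric(0))
  cfiVal <- if (length(fi)) fi$cfi else NA_real_
  if (format == "tsv") {
    fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 10))
    ln <- c("section\tname\trole\testimate\tse\tz\tp",
            vapply(seq_len(nrow(par)), function(i) paste(
              "parameter", par$name[i], par$role[i], fmt(par$estimate[i]),
              fmt(par$se[i]), fmt(par$z[i]), fmt(par$p[i]), sep = "\t"), ""),
            if (!is.null(fixedRows)) vapply(seq_len(nrow(fixedRows)),
              function(i) paste("fixed", fixedRows$name[i], "fixed",
                                fmt(fixedRows$estimate[i]), "NA", "NA", "NA",
                                sep = "\t"), ""),
            vapply(seq_len(nrow(fitTab)), function(i) paste(
              "fit", fitTab$index[i], "", fmt(fitTab$stat[i]),
              fmt(fitTab$df[i]), "", fmt(fitTab$p[i]), sep = "\t"), ""),
            paste("cfi", "CFI", "", fmt(cfiVal), "", "", "", sep = "\t"),
            paste("meta", "seed", "", fmt(fit@seed), "", "", "", sep = "\t"),
            paste("meta", "weight", fit@weightType, "", "", "", "", sep = "\t"))
    return(paste(ln, collapse = "\n"))
  }
  txt <- c(
    "Pedigree SEM fit",
    sprintf("  weight: %s   seed: %s   Qmin: %.6g   df: %g",
            fit@weightType, format(fit@seed), fit@Qmin, fit@df),
    "", "Parameters:",
    utils::capture.output(print(par, digits = 4, row.names = FALSE)),
    if (!is.null(fixedRows)) c("", "Fixed slots:",
      utils::capture.output(print(fixedRows[, c("name", "estimate")],
                                  digits = 4, row.names = FALSE))),
    "", "Fit indices:",
    utils::capture.output(print(fitTab, digits = 4, row.names = FALSE)),
    sprintf("CFI: %s", format(cfiVal, digits = 4)))
  paste(txt, collapse = "\n")
}

#' Parse a TSV fit report back into tables
#'
#' @param text output of \code{fitReport(fit, "tsv")}.
#' @return list(parameters, fit, cfi, seed, weight).
#' @export
parseFitReport <- function(text) {
  ln <- strsplit(strsplit(text, "\n")[[1]], "\t")
  body <- ln[-1]
  sec <- vapply(body, `[`, "", 1)
  num <- function(x) suppressWarnings(as.numeric(x))
  pr <- body[sec == "parameter"]
  parameters <- data.frame(
    name = vapply(pr, `[`, "", 2), role = vapply(pr, `[`, "", 3),
    estimate = num(vapply(pr, `[`, "", 4)), se = num(vapply(pr, `[`, "", 5)),
    z = num(vapply(pr, `[`, "", 6)), p = num(vapply(pr, `[`, "", 7)),
    stringsAsFactors = FALSE)
  fr <- body[sec == "fit"]
  fitTab <- data.frame(
    index = vapply(fr, `[`, "", 2), stat = num(vapply(fr, `[`, "", 4)),
    df = num(vapply(fr, `[`, "", 5)), p = num(vapply(fr, `[`, "", 7)),
    stringsAsFactors = FALSE)
  list(parameters = parameters, fit = fitTab,
       cfi = num(vapply(body[sec == "cfi"], `[`, "", 4)),
       seed = num(vapply(body[sec == "meta" &
                              vapply(body, `[`, "", 2) == "seed"], `[`, "", 4)),
       weight = vapply(body[sec == "meta" &
                            vapply(body, `[`, "", 2) == "weight"], `[`, "", 3))
}
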