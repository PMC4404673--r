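## Simulation configuration and the end-to-end data generator.

#' Simulation configuration
#'
#' Bundles everything a reproducible pedigree-data simulation needs:
#' base structures, the generating model with true parameter values, a
#' founder haplotype panel, an optional ascertainment scheme, and the
#' master seed.
#'
#' @slot structures base pedigree structures (recycled to
#'   \code{nPedigrees}).
#' @slot nPedigrees number of pedigrees to deliver (after ascertainment,
#'   when an ascertainment scheme is present).
#' @slot model the generating \linkS4class{ModelSpec}.
#' @slot theta named true values for every free parameter.
#' @slot panel founder \linkS4class{HaplotypePanel}; must contain every
#'   SNP covariate and linkage marker of the model.
#' @slot ascertainment empty list, or list(prevalence,
#'   probandProbability, traits = NULL).
#' @slot seed master seed; the simulator is a pure function of
#'   (configuration, seed).
#' @export
setClass("SimulationConfig",
  representation(
    structures = "PedigreeSet",
    nPedigrees = "numeric",
    model = "ModelSpec",
    theta = "numeric",
    panel = "HaplotypePanel",
    ascertainment = "list",
    seed = "numeric"
  )
)

#' @rdname SimulationConfig-class
#' @param structures preset name (\code{"nuclear75"},
#'   \code{"extended5"}) or a \linkS4class{PedigreeSet}.
#' @param nPedigrees pedigree count delivered.
#' @param model model text or \linkS4class{ModelSpec}.
#' @param theta named true parameter vector (or one value recycled to
#'   all free parameters).
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param ascertainment \code{NULL} or list(prevalence,
#'   probandProbability, traits).
#' @param seed master seed.
#' @export
simulationConfig <- function(structures, nPedigrees, model, theta, panel,
                             ascertainment = NULL, seed = 1) {
  if (is.character(structures)) structures <- pedigreePreset(structures)
  spec <- if (is(model, "ModelSpec")) model else parseModel(model)
  mm <- buildModelMatrices(spec)
  theta <- .alignTheta(mm, theta)
  asc <- if (is.null(ascertainment)) list() else ascertainment
  if (length(asc)) {
    stopifnot(asc$prevalence > 0, asc$prevalence < 1,
              asc$probandProbability > 0, asc$probandProbability <= 1)
  }
  need <- unique(c(spec@covariates,
                   stats::na.omit(vapply(spec@components, .linkageMarker, ""))))
  miss <- setdiff(need, panel@markers$name)
  if (length(miss))
    stop("panel lacks model marker(s): ", paste(miss, collapse = ", "))
  new("SimulationConfig", structures = structures,
      nPedigrees = nPedigrees, model = spec, theta = theta,
      panel = panel, ascertainment = asc, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPedigrees, "pedigrees from",
      length(object@structures), "structure(s);",
      if (length(object@ascertainment)) paste0(
        "ascertained (prevalence ", object@ascertainment$prevalence,
        ", proband probability ", object@ascertainment$probandProbability,
        ");") else "unascertained;",
      "seed", object@seed, "\n")
})

## genotype + relationship matrices + phenotypes for a batch of
## structures; returns peds with data, per-ped relmats, labels
.simBatch <- function(structPeds, mm, config, seed) {
  seeds <- .subSeeds(seed, 2)
  drop <- geneDrop(structPeds, config@panel, seed = seeds[1])
  peds <- PedigreeSet(lapply(seq_along(structPeds), function(k) {
    p <- structPeds[[k]]
    p@genotypes <- drop$genotypes[[k]]
    p
  }))
  ## shared components (p, e, c) depend only on the structure: compute
  ## once per structure signature; linkage matrices are per pedigree
  linkMk <- vapply(mm@components, .linkageMarker, "")
  sig <- vapply(peds, .structureSignature, "")
  cache <- new.env(parent = emptyenv())
  relmats <- vector("list", length(peds))
  for (k in seq_along(peds)) {
    base <- cache[[sig[k]]]
    if (is.null(base)) {
      base <- lapply(seq_along(mm@components), function(ci)
        if (is.na(linkMk[ci])) .componentMatrix(peds[[k]], mm@components[ci])
        else NULL)
      cache[[sig[k]]] <- base
    }
    out <- base
    for (ci in seq_along(mm@components))
      if (!is.na(linkMk[ci]))
        out[[ci]] <- trueIBDMatrix(peds[[k]], drop$labels[[k]], linkMk[ci])
    names(out) <- mm@components
    relmats[[k]] <- out
  }
  peds <- simulatePhenotypes(peds, mm, config@theta, relmats, seed = seeds[2])
  list(peds = peds, labels = drop$labels)
}

#' Simulate a complete pedigree data set
#'
#' Pure function of the configuration: recycles the base structures,
#' gene-drops genotypes from the panel, simulates phenotypes under the
#' model at the true parameter values, and (when an ascertainment scheme
#' is configured) repeats batches of families, applies proband-based
#' ascertainment against the empirical affection threshold, and keeps
#' sampling until \code{nPedigrees} families with a proband have been
#' retained.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{peds} (a \linkS4class{PedigreeSet}),
#'   \code{ibd} (an \linkS4class{IBDData} over the model's linkage
#'   markers, empty when the model has none) and \code{threshold} (the
#'   affection threshold used, \code{NA} when unascertained).
#' @export
simulatePedigreeData <- function(config) {
  mm <- buildModelMatrices(config@model)
  linkM <- stats::na.omit(vapply(mm@components, .linkageMarker, ""))
  seeds <- .subSeeds(config@seed, 4)
  if (!length(config@ascertainment)) {
    structs <- .recycleStructures(config@structures, config@nPedigrees)
    sim <- .simBatch(structs, mm, config, seeds[1])
    ibd <- if (length(linkM)) trueIBD(sim$peds, sim$labels, linkM)
           else IBDData()
    return(list(peds = sim$peds, ibd = ibd, threshold = NA_real_))
  }
  asc <- config@ascertainment
  thr <- if (!is.null(asc$threshold)) asc$threshold else
    affectionThreshold(mm, config@theta, config@panel,
                       asc$prevalence, traits = asc$traits,
                       seed = seeds[2])
  kept <- list(); keptLabels <- list()
  total <- 0L
  chunk <- max(500L, config@nPedigrees)
  batchSeeds <- .subSeeds(seeds[3], 1000)
  for (it in seq_len(1000)) {
    structs <- .recycleStructures(config@structures, chunk,
                                  prefix = paste0("F", total + 1, "_"))
    sim <- .simBatch(structs, mm, config, batchSeeds[it])
    ret <- applyAscertainment(sim$peds, asc$prevalence,
                              asc$probandProbability, thr,
                              traits = asc$traits,
                              seed = batchSeeds[it] %% 1000000L + 1L)
    if (length(ret)) {
      retIds <- vapply(ret, familyId, "")
      allIds <- vapply(sim$peds, familyId, "")
      kept <- c(kept, ret@.Data)
      keptLabels <- c(keptLabels, sim$labels[match(retIds, allIds)])
    }
    total <- total + chunk
    if (length(kept) >= config@nPedigrees) break
    ## size the next chunk from the observed retention rate
    rate <- max(length(kept) / total, 1 / total)
    chunk <- min(20000L,
                 max(500L, ceiling(1.5 * (config@nPedigrees - length(kept)) / rate)))
  }
  if (length(kept) < config@nPedigrees)
    stop("ascertainment retained only ", length(kept), " of ",
         config@nPedigrees, " requested pedigrees; supply more input ",
         "pedigrees or relax the scheme")
  kept <- kept[seq_len(config@nPedigrees)]
  keptLabels <- keptLabels[seq_len(config@nPedigrees)]
  peds <- PedigreeSet(kept)
  ibd <- if (length(linkM)) trueIBD(peds, keptLabels, linkM) else IBDData()
  list(peds = peds, ibd = ibd, threshold = thr)
}

#' Read and write simulation configurations as YAML
#'
#' The YAML rendering stores pedigree structures as member tables, the
#' model as its text form, the panel as marker metadata plus 0/1
#' haplotype strings, and the remaining scalars verbatim.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path YAML file path.
#' @export
writeSimulationConfig <- function(config, path) {
  structs <- lapply(config@structures, function(p) {
    m <- p@members
    list(family = p@familyId, id = m$id,
         father = ifelse(is.na(m$father), "0", m$father),
         mother = ifelse(is.na(m$mother), "0", m$mother),
         sex = m$sex)
  })
  obj <- list(
    nPedigrees = config@nPedigrees,
    model = serializeModel(config@model),
    theta = as.list(config@theta),
    panel = list(markers = config@panel@markers$name,
                 pos = config@panel@markers$pos,
                 haplotypes = apply(config@panel@haplotypes, 1,
                                    paste, collapse = "")),
    ascertainment = config@ascertainment,
    seed = config@seed,
    structures = structs)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  structs <- PedigreeSet(lapply(obj$structures, function(s)
    Pedigree(s$family, data.frame(
      id = unlist(s$id), father = unlist(s$father),
      mother = unlist(s$mother), sex = unlist(s$sex),
      stringsAsFactors = FALSE))))
  H <- do.call(rbind, lapply(strsplit(unlist(obj$panel$haplotypes), ""),
                             as.integer))
  colnames(H) <- unlist(obj$panel$markers)
  panel <- new("HaplotypePanel",
               markers = data.frame(name = unlist(obj$panel$markers),
                                    pos = as.numeric(unlist(obj$panel$pos)),
                                    stringsAsFactors = FALSE),
               haplotypes = H)
  simulationConfig(structs, obj$nPedigrees, obj$model,
                   unlist(obj$theta), panel,
                   ascertainment = if (length(obj$ascertainment))
                     obj$ascertainment else NULL,
                   seed = obj$seed)
}
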