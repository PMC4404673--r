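## Replicated simulation experiments: the simulate-and-refit loop behind
## type-1-error, bias, coverage and fit-test-calibration studies.

#' Run a replicated simulate-and-refit experiment
#'
#' Repeatedly simulates a data set under the model at the true parameter
#' values and refits it with the two-stage pipeline, collecting per-
#' parameter estimates, standard errors, Wald p-values and 95% CI
#' coverage indicators, plus the p-values of the four fit tests and the
#' CFI per replicate.  All randomness derives from \code{seed}.
#'
#' @param model model text or \linkS4class{ModelSpec} (both simulation
#'   truth and analysis model).
#' @param structures preset name or \linkS4class{PedigreeSet}.
#' @param nPedigrees pedigrees per replicate.
#' @param theta named true parameter values.
#' @param panel founder \linkS4class{HaplotypePanel}.
#' @param nReps replicate count.
#' @param seed master seed.
#' @param ascertainment \code{NULL} or list(prevalence,
#'   probandProbability, traits) applied when simulating.
#' @param ascertainedFit condition the analysis on probands (defaults to
#'   TRUE whenever an ascertainment scheme is simulated).
#' @param weight stage-2 weight choice.
#' @param mcReps Monte-Carlo draws for the theoretical fit test per
#'   replicate.
#' @return list with data.frames \code{par} (rep, name, role, true,
#'   estimate, se, p, covered), \code{fit} (rep, index, p, cfi) and the
#'   count \code{nFail} of replicates whose fit errored.
#' @export
replicateStudy <- function(model, structures, nPedigrees, theta, panel,
                           nReps, seed = 1, ascertainment = NULL,
                           ascertainedFit = !is.null(ascertainment),
                           weight = c("diagonal", "full"), mcReps = 2e4) {
  weight <- match.arg(weight)
  spec <- if (is(model, "ModelSpec")) model else parseModel(model)
  mm <- buildModelMatrices(spec)
  thetaTrue <- .alignTheta(mm, theta)
  if (is.character(structures)) structures <- pedigreePreset(structures)
  ## the affection threshold depends only on (model, theta, panel,
  ## prevalence): compute it once and reuse across replicates
  if (!is.null(ascertainment) && is.null(ascertainment$threshold)) {
    ascertainment$threshold <- affectionThreshold(
      mm, thetaTrue, panel, ascertainment$prevalence,
      traits = ascertainment$traits, seed = .subSeeds(seed, 1))
  }
  repSeeds <- matrix(.subSeeds(seed, 2 * nReps), ncol = 2)
  parRows <- vector("list", nReps)
  fitRows <- vector("list", nReps)
  nFail <- 0L
  for (r in seq_len(nReps)) {
    cfg <- simulationConfig(structures, nPedigrees, spec, thetaTrue, panel,
                            ascertainment = ascertainment,
                            seed = repSeeds[r, 1])
    dat <- simulatePedigreeData(cfg)
    fit <- tryCatch(
      fitPedSEM(dat$peds, mm, ibd = dat$ibd, ascertained = ascertainedFit,
                weight = weight, seed = repSeeds[r, 2], mcReps = mcReps),
      error = function(e) NULL)
    if (is.null(fit)) { nFail <- nFail + 1L; next }
    pt <- fit@par
    lo <- pt$estimate - 1.959964 * pt$se
    hi <- pt$estimate + 1.959964 * pt$se
    parRows[[r]] <- data.frame(
      rep = r, name = pt$name, role = pt$role,
      true = unname(thetaTrue[pt$name]),
      estimate = pt$estimate, se = pt$se, p = pt$p,
      covered = thetaTrue[pt$name] >= lo & thetaTrue[pt$name] <= hi,
      stringsAsFactors = FALSE)
    fi <- fit@fitIndices
    fitRows[[r]] <- data.frame(
      rep = r, index = fi$table$index, p = fi$table$p, cfi = fi$cfi,
      stringsAsFactors = FALSE)
  }
  list(par = do.call(rbind, parRows), fit = do.call(rbind, fitRows),
       nFail = nFail)
}

#' Two-arm ascertainment experiment
#'
#' Simulates proband-ascertained data sets and analyses each one twice
#' on the same data: once with the single-ascertainment conditional
#' likelihood and once ignoring the sampling scheme, collecting
#' per-parameter coverage in both arms.  This is the simulate-and-refit
#' loop behind coverage-with/without-correction comparisons.
#'
#' @inheritParams replicateStudy
#' @param prevalence,probandProbability the ascertainment scheme.
#' @param traits affection-score traits (default: all observed).
#' @return list of two \code{replicateStudy}-style results,
#'   \code{corrected} and \code{uncorrected}, plus \code{nFail}.
#' @export
ascertainmentStudy <- function(model, structures, nPedigrees, theta, panel,
                               nReps, prevalence, probandProbability,
                               traits = NULL, seed = 1,
                               weight = c("diagonal", "full"),
                               mcReps = 2000) {
  weight <- match.arg(weight)
  spec <- if (is(model, "ModelSpec")) model else parseModel(model)
  mm <- buildModelMatrices(spec)
  thetaTrue <- .alignTheta(mm, theta)
  if (is.character(structures)) structures <- pedigreePreset(structures)
  thr <- affectionThreshold(mm, thetaTrue, panel, prevalence,
                            traits = traits, seed = .subSeeds(seed, 1))
  asc <- list(prevalence = prevalence,
              probandProbability = probandProbability,
              traits = traits, threshold = thr)
  repSeeds <- matrix(.subSeeds(seed, 3 * nReps), ncol = 3)
  arms <- list(corrected = vector("list", nReps),
               uncorrected = vector("list", nReps))
  nFail <- 0L
  for (r in seq_len(nReps)) {
    cfg <- simulationConfig(structures, nPedigrees, spec, thetaTrue, panel,
                            ascertainment = asc, seed = repSeeds[r, 1])
    dat <- simulatePedigreeData(cfg)
    for (arm in c("corrected", "uncorrected")) {
      fit <- tryCatch(
        fitPedSEM(dat$peds, mm, ibd = dat$ibd,
                  ascertained = (arm == "corrected"), weight = weight,
                  seed = repSeeds[r, if (arm == "corrected") 2 else 3],
                  mcReps = mcReps),
        error = function(e) NULL)
      if (is.null(fit)) { nFail <- nFail + 1L; next }
      pt <- fit@par
      lo <- pt$estimate - 1.959964 * pt$se
      hi <- pt$estimate + 1.959964 * pt$se
      arms[[arm]][[r]] <- data.frame(
        rep = r, name = pt$name, role = pt$role,
        true = unname(thetaTrue[pt$name]),
        estimate = pt$estimate, se = pt$se, p = pt$p,
        covered = thetaTrue[pt$name] >= lo & thetaTrue[pt$name] <= hi,
        stringsAsFactors = FALSE)
    }
  }
  list(corrected = list(par = do.call(rbind, arms$corrected), fit = NULL),
       uncorrected = list(par = do.call(rbind, arms$uncorrected), fit = NULL),
       nFail = nFail)
}

#' Summarise a replicate study per parameter
#'
#' @param study result of \code{\link{replicateStudy}}.
#' @return data.frame with per-parameter mean estimate, bias, Monte-Carlo
#'   standard error of the mean, empirical coverage and rejection rate at
#'   the 5\% level.
#' @export
summariseStudy <- function(study) {
  sp <- split(study$par, study$par$name)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    name = d$name[1], role = d$role[1], true = d$true[1],
    nReps = nrow(d),
    mean = mean(d$estimate), bias = mean(d$estimate - d$true),
    mcse = sd(d$estimate) / sqrt(nrow(d)),
    coverage = mean(d$covered),
    reject05 = mean(d$p < 0.05, na.rm = TRUE),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
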