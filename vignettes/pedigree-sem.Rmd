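---
title: "Structural equation models for general pedigrees: methods and design"
author: "pedsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural equation models for general pedigrees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsem)
```

## The model

`pedsem` fits structural equation models to quantitative traits observed
on members of general pedigrees.  The causal/measurement part of the
model is the familiar LISREL system with fixed covariates,

$$\eta = \alpha + B\eta + \Gamma_\eta x + \sum_c \zeta_c, \qquad
  y = \nu + \Lambda\eta + \Gamma_y x + \sum_c \epsilon_c,$$

where $y$ are the $t$ observed traits of one individual, $\eta$ the
latent variables, and $x$ fixed covariates such as SNP allele counts
(association enters through the mean structure only).  What makes the
model a *pedigree* model is the index $c$: every latent and observed
residual is split into named variance components, and the covariance of
the stacked trait vector $y_k$ of pedigree $k$ (individual-major
stacking: the $t$ traits of each member are kept together) is the
Kronecker sum

$$\mathrm{var}(y_k) = \sum_c R_{c,k} \otimes V_c(\theta), \qquad
  V_c(\theta) = \Lambda (I-B)^{-1} \Psi_c (I-B)^{-T} \Lambda^T + \Theta_c,$$

with a coupling matrix $R_{c,k}$ per component: the numerator
relationship matrix $2\Phi_k$ for the polygenic component `p`, the
identity for the residual environment `e`, a block of ones over
household groups for `c`, and the marker-specific IBD sharing matrix
$\hat\pi$ for a linkage component `a(marker)`.  The Kronecker separation
lets the analyst think about familial correlation (the $R$ side) and the
causal model (the $V$ side) independently.

Two scaling conventions exist for the polygenic coupling: the kinship
matrix $\Phi_k$ itself (diagonal $\tfrac12(1+F_i)$) or the numerator
relationship matrix $2\Phi_k$.  `pedsem` uses $2\Phi_k$, so that a
polygenic variance parameter is the additive genetic variance of a
single non-inbred individual; the alternative convention simply rescales
all `p`-component parameters by 2.  We consider the $2\Phi$ reading the
natural one (it makes `var(y) = sigma_p^2 + sigma_e^2` for a founder)
and apply it uniformly in the simulator and the estimator, so parameter
recovery is internally consistent.

Kinship coefficients are computed by the classical recursion in
topological order, $\phi_{ii} = \tfrac12(1+\phi_{f_i m_i})$,
$\phi_{ij} = \tfrac12(\phi_{f_i j} + \phi_{m_i j})$, which handles
inbreeding, marriage loops, half-sibships and multiple generations
without special cases; the test suite checks it against a gene-dropping
Monte-Carlo oracle on random pedigrees.

## Model language

Models are written in a small equation language (lavaan-flavoured):
`=~` declares measurement equations, `~` structural equations, a
trailing `<p,e,c,a(marker)>` term declares the left-hand variable's
variance components, and `=` fixes a coefficient (`coef(from, to)`),
variance (`var(v, comp)`) or residual covariance (`cov(v1, v2, comp)`).
A latent without indicators — e.g. a pleiotropy factor whose scale is
set by a fixed path — is declared `latent(name)`.  Unannotated variables
default to a single `e` component.  Latent scales are anchored by fixing
the first loading to 1 unless the user has fixed one of the latent's
loadings explicitly; fixing a latent's variances does not release the
anchor — the latent is then doubly pinned, which keeps its scale
strongly identified (releasing the anchor would leave the scale held
only by the fixed variance, a weak constraint whenever that variance is
small relative to what flows in through the structural paths).  A
latent without indicators is anchored by a fixed outgoing path or by
fixing all of its variance components.

Identification is checked numerically: the degrees of freedom are the
number of stage-1 moments minus the number of free parameters, and the
moment-map Jacobian must have full column rank at five random parameter
draws (singular values below $10^{-8}$ of the largest count as zero).

## Two-stage estimation

Fitting follows a robust two-stage strategy rather than full-information
ML.

**Stage 1 (saturated moments).**  For every trait a univariate
variance-component model (mean coefficients plus one variance per
component) is fitted by ML over all pedigrees, then for every trait pair
the per-component cross-covariances are fitted holding the univariate
estimates fixed (a profile two-step; the likelihood internals are
compiled code).  Variances are deliberately *not* constrained to be
nonnegative: constraining them would put estimates on the boundary and
destroy the asymptotic distributions used by the fit tests.  The
stacked estimates $s$ — intercepts and covariate slopes per trait,
variances per trait and component, covariances per pair and component —
form the saturated moment vector.  Its covariance is estimated by the
sandwich $\hat\Gamma = A^{-1} B A^{-T}/N$, where $B$ is the empirical
covariance of the stacked per-pedigree scores (analytic, including
cross-fit blocks) and $A$ the Jacobian of the stacked estimating
equations (numerically differentiated analytic scores; block
lower-triangular, with the cross blocks accounting for the two-step
plug-in of univariate estimates into the pair fits).  $\hat\Gamma$
carries the $1/N$, so downstream quadratic forms are already on the
chi-square scale.  Mean moments are intercepts and slopes rather than
raw means, which makes the stage-2 match independent of the covariate
distribution.

**Stage 2 (minimum distance).**  The structural parameters minimise
$Q(\theta) = (s - \sigma(\theta))^T W (s - \sigma(\theta))$.  The
default weight is $W = \mathrm{diag}(\hat\Gamma)^{-1}$: with dozens of
moments the full $\hat\Gamma$ is noisy and its inverse can be unstable,
while the diagonal weight is robust and leaves the miscalibration it
induces in the fit statistic to the corrections below.
`weight = "full"` selects the asymptotically optimal ADF weight
$\hat\Gamma^{-}$ (an eigenvalue pseudo-inverse).  To avoid local optima
the optimiser is multi-started from a seed-deterministic evolutionary
search (population 20, 10 generations, tournament selection of size 3,
blend crossover $\alpha = 0.5$, Gaussian mutation with rate 0.2 and sd
$0.1\times$scale, elitism) initialised at a heuristic center — loadings
1, intercepts at their stage-1 values, variance components at equal
splits of the stage-1 variances; the distinct top five candidates plus
the center are each polished by quasi-Newton iteration
($|\Delta Q| < 10^{-12}$ relative, up to 500 iterations) and the best
polished optimum wins.  Parameter uncertainty uses the sandwich
$(\Delta^T W \Delta)^{-1} \Delta^T W \hat\Gamma W \Delta (\Delta^T W
\Delta)^{-1}$ with $\Delta = \partial\sigma/\partial\theta$ (central
differences, step $\max(10^{-6}, 10^{-6}|\theta_j|)$), giving Wald tests
that remain valid under non-normality.

## Ascertainment

Families sampled through an affected index case (the proband) are not a
random sample, and naive ML is badly biased — in our simulations the
uncorrected intercepts are biased upward by almost one residual
standard deviation and their confidence intervals essentially never
cover the truth.  Under *single ascertainment* (the probability that a
family is ascertained through a given member is proportional to a
function of that member's phenotype, and small), the correct likelihood
is conditional on the proband's trait values:
$\log f(y_k) - \log f(y_{k,\mathrm{proband}})$.  `pedsem` applies this
conditioning inside every stage-1 fit, using the first flagged proband
and the fit's own variables (the trait of a univariate fit, the pair of
a bivariate fit); pedigrees without probands contribute
unconditionally, and a proband with all fit variables missing falls
back to the unconditional contribution with a warning.  Conditioning on
the per-fit variables is one of two defensible readings (the other
would condition every fit on the proband's full trait vector, which a
saturated per-trait stage cannot express); it is exact when selection
depends on the fitted trait itself and an approximation when selection
depends on a composite of several traits, which is visible as a small
residual intercept bias in single-factor models with highly correlated
indicators.  For the multi-trait models used in the coverage studies the
approximation restores near-nominal coverage (see the acceptance
suite).

## Tests of overall fit

With a non-optimal $W$, $Q_{\min}$ is asymptotically distributed as a
weighted sum $\sum_j w_j \chi^2_1$ whose weights are the eigenvalues of
$U\hat\Gamma$, $U = W - W\Delta(\Delta^TW\Delta)^{-1}\Delta^TW$.  Four
tests are reported:

* **unadjusted**: $Q_{\min}$ against $\chi^2_{df}$ — only calibrated
  when $W = \hat\Gamma^{-1}$;
* **mean adjusted**: $Q_{\min}/(\sum w/df)$ against $\chi^2_{df}$
  (first-moment correction);
* **mean and variance adjusted**: $Q_{\min}\,df^*/\sum w$ against
  $\chi^2_{df^*}$ with fractional $df^* = (\sum w)^2/\sum w^2$;
* **theoretically corrected**: the Monte-Carlo tail probability of the
  estimated mixture itself ($10^5$ draws by default, never below
  $10^4$; add-one smoothing so $p > 0$), with the statistic
  back-calculated as the $\chi^2_{df}$ quantile that would have produced
  the same $p$.  The back-calculation uses the model df — the natural
  reading of reporting "the chi-square that would have produced the
  p-value".

Under a correct model with the diagonal weight, only the theoretical
test's p-values are uniform; the unadjusted test is visibly
miscalibrated (the acceptance suite checks both by Kolmogorov-Smirnov
tests).  Negative mixture-weight estimates (sampling noise in
$\hat\Gamma$) are floored at zero with a warning.  The comparative fit
index uses the theoretically corrected statistics of the model and of
an independence baseline — all covariance moments fixed at zero, means
and per-variable variances free (the baseline is not standardised in
the literature; this is the weakest model in the family and makes CFI
$\le 1$ by construction):
$\mathrm{CFI} = 1 - \max(T_m - df_m, 0)/\max(T_b - df_b, T_m - df_m, 0)$,
clamped to $[0,1]$.

## The simulator

The integrated simulator is a pure function of its configuration and
seed (byte-identical on repetition), and generates:

* **Founder haplotypes** from a synthetic phased panel built by a
  first-order binary Markov chain whose transitions match target minor
  allele frequencies (uniform in a configurable range, default
  0.1–0.45) and adjacent-marker $r^2$ exactly in expectation, standing
  in for a phased population reference panel.
* **Genotypes by gene dropping**: founders draw two panel haplotypes
  with replacement (the panel is a population, not a sample to
  exhaust), and every meiosis transmits a Haldane-model recombinant
  (1 cM/Mb by default; recombination can be disabled).  Founder-
  haplotype descent labels are tracked per allele, so the *true* IBD
  sharing matrix at any marker is available exactly — this is what the
  linkage analyses consume, written through the same IBD CSV dialect
  the reader accepts.
* **Phenotypes** by drawing, per component,
  $\zeta_c \sim N(0, R_{c,k}\otimes\Psi_c)$ and
  $\epsilon_c \sim N(0, R_{c,k}\otimes\Theta_c)$ through symmetric
  square roots of both factors (tolerating PSD-singular couplings such
  as the household block of ones), then propagating the structural
  system.  Simulation, unlike estimation, refuses non-PSD $\Psi_c$ or
  $\Theta_c$.
* **Ascertainment**: an individual is affected when the mean of the
  affection traits (default: all observed traits) exceeds the upper-
  prevalence quantile of a $10^5$-individual unrelated reference
  population simulated at the true parameters — an empirical threshold,
  because the trait mean is a genotype mixture and an analytic normal
  quantile would be slightly wrong at common-variant effect sizes.
  Affected members become proband candidates independently with the
  ascertainment probability; the first candidate in member order is the
  proband and probandless families are discarded.  Batches are resized
  adaptively from the observed retention rate until the requested
  number of families is retained.

Pedigrees sharing a structure are simulated in one vectorised batch,
which is what makes low-prevalence ascertainment sampling (retention
under 2% at prevalence 5% and ascertainment probability 0.05)
affordable.

Two structure presets mirror the simulation studies: `nuclear75`, 75
nuclear families with sibship sizes 4–11 and 477 individuals in total
(69 four-sib families plus one family each of 6–11 siblings), and
`extended5`, five 10-member three-generation structures (50 individuals)
including a half-sib and a cousin configuration.  The exact shapes of
published extended-pedigree test sets are rarely recoverable from text;
these are documented stand-ins with the stated totals.

What the simulator deliberately does *not* emulate: non-normal trait
distributions, genotyping error, dominance or epistasis, sex linkage,
and population structure in the founder panel.  Passing recovery tests
on simulated data therefore demonstrates internal consistency of
estimator and model, not robustness to those real-data features (the
sandwich standard errors are expected — but not here shown — to retain
validity under moderate non-normality).

## Numerical choices

* Pedigree likelihoods delete missing entries row/column-wise
  (pairwise across fits); individuals with a missing covariate are
  excluded from the mean model of that fit.
* A non-positive-definite covariance during optimisation returns a
  $-10^{10}$ log-likelihood sentinel rather than an error, keeping the
  unconstrained variance search safe.
* Stage-1 optimisation is quasi-Newton with analytic gradients from the
  per-pedigree scores; up to 3 restarts from perturbed starts.
* The estimating-equation Jacobian $A$ uses step
  $10^{-5}\max(1, |\tau_j|)$ and exploits the dependency structure
  (a univariate parameter touches its own fit and the pairs containing
  its trait).
* $\hat\Gamma$ is symmetrised and eigenvalue-floored at zero.
* All randomness flows from explicit user seeds through deterministic
  sub-seed streams; no global RNG state leaks (the caller's
  `.Random.seed` is restored).

## Problem sizes in the shipped test suite

The headline studies behind the acceptance tests are scaled-down
versions of full simulation grids (which run thousands of replicates per
cell over many scenario combinations).  The shipped suite uses, as the
package's own choice of desk-scale study sizes: 400 null replicates at
75 nuclear pedigrees (plus 100 at 300) for the type-1 error of the SNP
Wald test; 80/50/40/40 replicates at 300 pedigrees for parameter
recovery and coverage of the four example models (association, linkage,
multi-level, pleiotropy — nuclear structures for two, extended for the
other two, so both pedigree types are exercised); 230 replicates at 75
extended pedigrees for fit-test calibration; and 32 replicates at 100
pedigrees (prevalence 5%, ascertainment probability 0.05) for the
ascertainment comparison, analysing each simulated data set both with
and without the correction.  All studies use the default diagonal
weight; the calibration study depends on it (its purpose is precisely
the fit-statistic miscalibration that non-optimal weighting induces).  Every Monte-Carlo acceptance band is
computed from the run's own replicate count, so the scaled studies test
the same properties at honestly wider tolerances.
`scripts/acceptance.R` re-runs the same designs (with more null
replicates) and writes the headline numbers as JSON.

## Known limitations

* Two-stage minimum distance is less efficient than full-information
  ML for small samples; the gain is robustness and speed on large
  moment vectors.
* The bivariate stage holds univariate estimates fixed; the sandwich
  accounts for this, but a full joint stage 1 could be marginally more
  efficient.
* Per-fit ascertainment conditioning is approximate when selection
  depends on a composite of many traits (see above).
* Ordinal traits, multi-group models, nonlinear constraints and
  dominance components are out of scope.
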