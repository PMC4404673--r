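Package: pedsem
Title: Structural Equation Models with Latent Variables for General Pedigree Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits structural equation models (measurement and structural
    equations with latent variables) to quantitative traits observed on
    members of general pedigrees, including pedigrees with loops,
    half-sibships and multiple generations.  Familial correlation is
    modelled through Kronecker-product variance components (polygenic,
    shared household, marker-specific identity-by-descent linkage and
    residual environment), and SNP association enters through the mean
    structure.  Estimation is a robust two-stage procedure: saturated
    per-trait and per-pair variance-component maximum likelihood,
    optionally conditioned on a proband's trait values to correct for
    single ascertainment, followed by minimum-distance (ADF) fitting of
    the structural model with sandwich standard errors.  Overall fit is
    assessed by unadjusted, mean-adjusted, mean-and-variance-adjusted and
    theoretically corrected (weighted chi-square mixture) test statistics
    plus a comparative fit index.  An integrated simulator generates
    founder haplotype panels, performs gene dropping with recombination,
    tracks true identity by descent, simulates multivariate traits under
    any model, and emulates proband-based ascertainment sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
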