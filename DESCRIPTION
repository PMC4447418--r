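Package: nestvpc
Title: Variance Partitioning in Nested Three-Level Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits two- and three-level nested random-intercept Gaussian
    linear models (individuals in clusters in super-clusters, e.g. babies
    in mothers in maternal countries of birth) by a blocked Gibbs sampler
    with method-of-moments starting values, and computes the measures of
    general and specific contextual influence used in multilevel
    epidemiology: variance partition coefficients (VPC), intra-class
    correlations (ICC), proportional change in variance (PCV), the
    deviance information criterion, and empirical-Bayes shrunken
    cluster effects with league tables. Includes a synthetic
    birth-register generator that emulates the nested statistical
    structure of a national birth cohort, inclusion filters, a
    five-model covariate sequence, and sensitivity analyses, so the
    whole workflow is reproducible without register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
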