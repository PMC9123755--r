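Package: lcvar
Title: Latent-Class Vector Autoregression for Ecological Momentary
    Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters individuals by their lagged multivariate dynamics in
    intensive longitudinal (ecological momentary assessment) data.
    Implements maximum-likelihood estimation of finite mixtures of
    vector-autoregressive VAR(p) models with exogenous time-of-day
    covariates via the EM algorithm, with pseudo-random and k-means
    ("rational") start strategies, covariance resets for degenerate
    classes, and Hannan-Quinn / Akaike model selection over cluster-count
    by lag grids. Includes panel handling with compliance filtering and
    the day-boundary lag rule, single-imputation chained equations for
    item-level missingness, post-fit coefficient heatmap matrices and
    per-cluster daytime-course means, between-cluster characterisation
    (one-way ANOVA with generalised eta-squared, Tukey HSD, Pearson
    chi-squared, exact Fisher test for r x c tables), and a synthetic EMA
    panel generator with known cluster structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
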