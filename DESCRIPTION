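Package: riskdrift
Title: Stability of Polygenic Risk Classification as GWAS Catalogs Grow
Version: 0.1.0
Authors@R: person("Riskdrift", "Developers", email = "riskdrift@example.org",
    role = c("aut", "cre"))
Description: Tools to study how genetic risk classification drifts as
    genome-wide association study (GWAS) catalogs accumulate. Builds
    time-stamped panels of genome-wide-significant SNPs from catalog files
    (significance filtering, locus assignment, LD pruning, odds-ratio
    updates), simulates cohort genotypes under Hardy-Weinberg equilibrium
    or haplotype models (with an EM estimator for unphased data), scores
    individuals under a multiplicative odds model, and quantifies
    reclassification between panels (3x3 tables, net reclassification
    index, binormal and empirical AUC). Also projects the reclassification
    expected after hypothetical larger GWAS via power-based estimates of
    the number of undiscovered susceptibility loci, and ships a synthetic
    catalog generator so the whole pipeline is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
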