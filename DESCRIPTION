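Package: stresskit
Title: Stress Tolerance Indices and Tolerance Classification for
    Multi-Environment Crop Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired normal/stress yield trials of crop
    genotype collections. Computes the classical stress-tolerance indices
    (STI, TOL, GMP, MP, HARM, SSI, YSI) from replicate-mean yields, Pearson
    correlation panels with significance stars, correlation-matrix principal
    component analysis with per-variable contributions, Ward hierarchical
    clustering of genotypes into tolerance classes with rule-based labels,
    cluster trait profiling with Duncan letter groups, two-way analysis of
    variance, broad-sense heritability from variance components, and
    treatment percent-change summaries. Includes a synthetic trial generator
    with cluster-structured yield pairs so the full pipeline can be exercised
    and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
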