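Package: sortscape
Title: Sort-Seq Fitness Landscapes of Fluorescent Proteins
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for deep-mutational-scan sort-seq
    experiments on fluorescent proteins. Simulates ground-truth
    genotype-fluorescence landscapes and full FACS sort-seq experiments
    (barcoded mutant libraries, gate sorting with mis-sorting noise,
    count-control spike-ins, sequencing reads); calls barcode consensus
    genotypes; infers per-barcode log10 fluorescence by fitting gate
    cell-count vectors to a normal CDF; applies replicate-merging and
    quality filters; computes landscape statistics (single-mutant effects,
    additive-expectation epistasis with capping, mutational LD50 logistic
    fits, peak profiles, cross-ortholog comparisons); fits small neural
    networks with Monte Carlo dropout on one-hot encoded genotypes; and
    designs distant functional variants with a genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
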