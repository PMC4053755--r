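Package: episcale
Title: Scaling of Pairwise Genetic Interaction Strength with Mutational Effect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pairwise epistasis in large double-mutant fitness
    screens using the geometric (log2 fold-deviation) interaction measure,
    and characterises how the typical interaction strength scales with the
    growth-rate effects of the mutations being combined. Provides readers
    and filters for raw SGA-style double-mutant fitness tables, exponential
    binning of interaction variance with bootstrap confidence intervals,
    deconvolution of measurement noise via randomised no-epistasis mock
    datasets with Student's t perturbations, one-parameter scaling-surface
    fits, sign-epistasis probability estimation, a Fisher geometric model
    simulator for contrasting variance scaling laws, and a fully seeded
    synthetic-data generator with known ground truth for end-to-end
    validation of the entire pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nortest
Config/testthat/edition: 3
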