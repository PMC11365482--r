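Package: linecross
Title: Information-Theoretic Line Cross Analysis of Composite Genetic Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Line cross analysis (LCA) infers the genetic architecture of
    trait divergence between two lines from the phenotype means and standard
    errors of crosses derived from them (parents, F2, backcrosses).  The
    package derives the coefficient matrix (c-matrix) of composite genetic
    effects (autosomal additive and dominance, cytotype, maternal additive
    and dominance, and two-way epistatic combinations) from a sire-by-dam
    pedigree over two founder strains, fits every estimable architecture
    model by weighted least squares, ranks models by small-sample-corrected
    AIC (AICc), and model-averages effect estimates over a 95% confidence
    set of models with variable-importance and standard-error inclusion
    criteria.  Includes plant-nested cohort summaries, a synthetic-data
    generator with known true architectures for power and recovery studies,
    and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
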