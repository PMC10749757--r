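Package: crossGEx
Title: Relative Cross-Species Comparison of Gene Expression by
    Variability, Diversity and Specificity Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relative comparison of bulk RNA-seq gene expression
    across tissues and species (human, mouse, rat, zebrafish, fly, worm).
    Provides identifier and ortholog mapping from local HomoloGene-style
    tables, variance-stabilizing preprocessing of count-like expression
    values under a parametric negative-binomial mean-dispersion trend,
    coefficient-of-variation metrics across tissues or species, and
    Shannon-entropy based diversity and specificity metrics of expression
    profiles, together with a seeded synthetic-data generator, static
    plotting helpers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
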