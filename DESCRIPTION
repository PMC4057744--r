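Package: gmetric
Title: Compression-Adjusted Grantham Metric for Missense Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-specific pathogenicity scoring of non-synonymous protein
    variants from multiple-species sequence alignments. Combines the Grantham
    biochemical distance between wild-type and variant residues with an
    alignment-column diversity measure (Grantham variance) that is rescaled by
    a DEFLATE compression ratio to correct for the overestimation of
    phylogenetic diversity in deep alignments. A gene-specific attenuation
    constant is trained by particle swarm optimisation of a cluster-separation
    index between known deleterious and neutral variants, yielding binary
    calls against a derived cut-off, a gene-normalised continuous score, and
    optional Bayesian posterior probabilities. Includes leave-one-out
    cross-validation with Matthews correlation, ROC/AUC and chi-squared
    summaries, and a synthetic alignment/variant panel generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
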