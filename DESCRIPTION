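Package: flexcompare
Title: Quantifying Similarity of Protein Flexibility Signals and Rigidity Images
Version: 0.1.0
Authors@R: person("flexcompare", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to quantify similarity between proteins based on their
    flexibility characteristics rather than their sequences. One-dimensional
    flexibility signals (density of independent degrees of freedom along the
    backbone, or hydrophobicity profiles built from sequence) are compared with
    dynamic time warping; two-dimensional rigidity-susceptibility images are
    compared by similarity-transform image registration followed by a
    mean-squared pixel distance and a normalized gap measure. Includes readers
    and writers for the relevant plain-text formats, a synthetic generator of
    ensemble rigidity data for testing, a family-level comparison pipeline, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
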