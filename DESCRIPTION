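Package: surrnet
Title: Surrogate-Calibrated Gene Co-Expression Networks for Two-Group
    Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-group transcriptome analysis combining nonspecific
    interquartile-range filtering, empirical-Bayes moderated differential
    expression with Benjamini-Hochberg correction, transposed principal
    component analysis (genes as statistical units, samples as variables)
    for discriminant gene ranking, and Pearson correlation networks whose
    edge threshold is calibrated against permutation surrogate data.
    Network topology is compared between groups by average degree,
    connected components and isolated nodes; a generic Fisher-exact
    over-representation test runs on user-supplied gene sets. A synthetic
    two-group expression generator with planted mean shifts and planted
    correlation blocks provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
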