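Package: printletr
Title: Formulation Design and Release Optimization for 3D-Printed Tablets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for designing and optimizing
    extended-release tablets fabricated by vat photopolymerization (DLP)
    3D printing. Provides Scheffe canonical mixture-polynomial fitting with
    leave-one-out model-selection statistics (PRESS, predicted R-squared)
    and D-optimal design generation over a bounded mixture simplex; fitting
    and selection of drug-release kinetic models (zero-order, first-order,
    Higuchi, Korsmeyer-Peppas) with release-mechanism classification; a
    from-scratch multilayer-perceptron surrogate of dissolution trained by
    momentum backpropagation, with architecture search; Derringer-type
    desirability optimization of formulation composition against release
    targets; model-independent dissolution-profile comparison (difference
    factor f1, similarity factor f2); and a synthetic-study generator that
    emulates composition-dependent cumulative release curves for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
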