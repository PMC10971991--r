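Package: ldapanel
Title: Two-Stage Linear Discriminant Selection of Metabolite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects minimal metabolite panels that discriminate clinical
    groups from targeted-metabolomics concentration tables. Implements
    multi-class linear discriminant analysis with pooled within-class
    covariance, Mahalanobis/Gaussian posterior classification and
    leave-one-out cross-validation; a two-stage best-subset search (raw
    metabolites first, then monomial terms up to total degree three over
    the winning panel); confusion-matrix reports with one-vs-rest
    sensitivity, specificity, PPV and NPV; posterior tables; Pearson
    correlation and one-way ANOVA summaries; discriminant-plane decision
    region maps; and a synthetic-cohort generator with planted markers,
    correlated blocks and product-only (non-linear) class signals for
    testing the whole pipeline without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
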