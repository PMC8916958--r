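Package: methdecon
Title: Cell-Type Deconvolution of Bulk DNA Methylomes from Imputed and
    Single-Nucleus Reference Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds cell-type DNA-methylation reference matrices, either by
    imputing promoter methylation from annotated single-cell RNA-seq data
    using matched methylation/expression compendia and a two-state gamma
    mixture model, or directly from sparse single-nucleus methylomes.
    References are applied to bulk beta-value matrices by weighted robust
    (Huber) regression with non-negativity and sum-to-one constraints to
    estimate cell-type fractions, to call cell-type-specific differential
    methylation through fraction-by-phenotype interaction models, and to
    derive sample-level scores such as tumor purity and total immune
    fraction. A synthetic-data module generates all input kinds with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
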