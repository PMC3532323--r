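Package: ccalink
Title: Linking Chemical Descriptor Space to Genome-Wide Drug Response with
    Regularized Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A data-driven pipeline for relating a chemical descriptor table
    (compounds by structural descriptors) to genome-wide drug-response
    profiles. Batch-structured expression profiles are reduced to one
    differential-response vector per compound (robust control consolidation,
    control-variance gene filter, strongest-instance selection), converted to
    signed gene-set activation profiles in [-1, 1] via an enrichment q-value
    transform, and linked to the descriptor space by regularized canonical
    correlation analysis. Regularization is selected by cross-validated
    retrieval of functionally similar compounds (mean average precision),
    component significance is assessed by permutation, and components are
    split into sign subcomponents and characterized by top gene sets,
    moderated t-test gene lists, hypergeometric term enrichment, and
    target-sharing resampling. Includes generators for synthetic data with
    planted low-rank cross-space structure so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    fgsea
Config/testthat/edition: 3
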