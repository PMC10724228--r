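Package: polyrank
Title: Unified Polymer Degradability Ranking from Incompatible Assay Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates polymer degradability datasets measured under
    incompatible conditions into a single unified ranking using pairwise
    learning-to-rank (RankSVM on fingerprint difference vectors). Provides
    ingestion and canonicalization of repeat-unit SMILES with wildcard
    attachment points, a deterministic hashed atom-environment fingerprint
    with an optional substructure-embedding adapter, the exposure-experiment
    degradability index delta computed from total organic carbon release,
    functional-group descriptor counting via SMARTS, a variance-reduction
    regression tree for factor analysis of the learned scores, a k-nearest
    neighbor applicability-domain filter for screening external polymer
    libraries, and a synthetic multi-dataset generator with known latent
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
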