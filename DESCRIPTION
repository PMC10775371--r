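Package: glandmap
Title: Cell-Type Annotation and Spatial Interaction Analysis for Salivary Gland Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational procedures for dissecting immune-epithelial
    interactions in Sjogren's Disease salivary glands and similar exocrine
    tissues: per-cell quality-control gating of sparse expression matrices;
    gene-index S-scoring (sums of per-gene Z-scores over gene sets);
    signature-matrix cell-type annotation of multiplex marker-intensity
    tables via Cell Type Relevance scores with AIC-selected segmented
    regression breakpoints, hierarchical AND-gating and KNN resolution of
    mixed identities (TACIT); within-spot cell-type co-occurrence scoring
    and group comparison for deconvolved spatial transcriptomics spots;
    Delaunay-graph cell-cell interaction matrices with disease/healthy
    fold changes; and per-patient cell-type proportion testing with
    Benjamini-Hochberg correction. A seeded synthetic-data generator with
    recorded ground truth makes every stage testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    deldir,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
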