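Package: sesnet
Title: Socioeconomic Status and the Immune Transcriptome: Differential
    Expression, Upstream Regulator Networks, Mediation and Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking a continuous
    socioeconomic status (SES) composite to the blood immune transcriptome.
    Starting from a gene-by-sample count matrix and sample metadata, the
    package performs TMM normalization, empirical-Bayes batch adjustment and
    covariate-adjusted per-gene linear models for the SES exposure; detects
    whole-genome co-expression modules and tests eigengene-SES associations
    and module enrichment for SES-associated genes; runs hierarchical
    over-representation analysis with parent-child pooling and combined
    multi-list enrichment; builds the four upstream regulator sets (DE genes,
    DE transcription factors, their high-confidence protein neighbors, and
    modulating transcription factors) from scored regulatory and
    protein-protein interaction networks and assigns molecules to relevance
    layers; quantifies counterfactual mediation (ACME / total effect) of the
    SES-expression association through behavioral and physiological
    mediators; and assesses set-level specificity with a randomization test
    combining per-gene empirical p-values by Fisher's method. A synthetic-data
    module generates cohorts, negative-binomial counts, scored regulatory and
    protein interaction networks, and a three-level pathway ontology with
    planted, recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    sva,
    fgsea,
    Matrix,
    MASS,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
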