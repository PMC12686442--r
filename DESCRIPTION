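Package: cmaflux
Title: Chaperone-Mediated Autophagy Substrate Discovery and Activity Scoring
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying chaperone-mediated autophagy (CMA) from
    sequence and omics data. Provides sliding-window detection and
    classification of canonical and post-translationally generated
    (phosphorylation, acetylation) KFERQ-like targeting motifs in protein
    sequences; a weighted, directed transcriptional CMA activity score over a
    configurable effector/modulator gene network; row-wise differential testing
    of paired lysosomal-inhibition (NH4Cl/leupeptin) proteomics with a
    motif-gated putative-substrate caller and Jaccard overlap summaries;
    rank-based permutation enrichment and hypergeometric over-representation
    statistics for gene-set collections; and seeded generators of synthetic
    proteomes, expression matrices and paired flux-proteomics experiments with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, GeneSetEnrichment, Software
RoxygenNote: 7.3.3
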