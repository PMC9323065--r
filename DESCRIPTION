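Package: saltScreen
Title: Fuzzy-Mathematics Salt-Tolerance Screening and Leaf Transcriptome
    Analysis for Foxtail Millet
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage fuzzy membership-function pipeline for screening
    salt-tolerant crop accessions from germination and seedling phenotypes,
    together with the downstream leaf-transcriptome stages used in such
    screens: FPKM standardisation, a simplified negative-binomial
    differential-expression test with fold-change/p-value DEG filtering,
    hypergeometric term enrichment with cluster-frequency reporting,
    transcription-factor family tallies, and maximal clique centrality (MCC)
    hub-gene scoring on confidence-thresholded protein-protein interaction
    networks. A fully seeded synthetic-data generator emulates every input
    (germination censuses, seedling traits, negative-binomial count matrices
    with planted differentially expressed genes, term and TF annotations,
    and PPI graphs with planted cliques) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
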