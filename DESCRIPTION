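Package: clademark
Title: Marker-Gene Curation, Clade Delineation and Gene-Content Evolution
    for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogenomic curation of marker genes from
    metagenome-assembled genomes (MAGs): single-copy/occupancy screening of
    homolog families, monophyly and contamination screening of gene trees,
    gap-column trimming and supermatrix concatenation; identity-threshold
    delineation of 16S rRNA-style sequence groups; pathway and antioxidant
    presence profiling of genome annotation matrices; read-mapping based
    genome abundance estimation with rank correlation against environmental
    parameters; and a simplified ancestral gene-content reconstruction
    (Fitch parsimony and a two-state Markov model). Seeded simulators for
    species trees, duplication-transfer-loss gene families, group-structured
    sequence sets, annotation matrices and read counts provide planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
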