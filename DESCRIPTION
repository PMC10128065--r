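Package: beeprofiler
Title: Genomic and Community Profiling of Stingless Bee Gut Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based metabolic pathway-completeness scoring of bacterial
    genomes from KEGG Orthology (KO) annotations, CAZyme family gene counting,
    fragment-based average nucleotide identity (ANI) with 95% species-level
    clustering, 16S rRNA amplicon sequence variant (ASV) community summaries
    with Bray-Curtis dissimilarities and permutational multivariate analysis
    of variance (PERMANOVA), and construction of trimmed single-copy-ortholog
    supermatrices for core-genome phylogenomics. Includes a synthetic-data
    module that generates all inputs with known ground truth, so every stage
    of the pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
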