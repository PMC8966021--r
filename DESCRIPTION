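Package: TuppeMiner
Title: Exporter Mining and Tunable Plug-and-Play Exporter Cassette Design
    for Streptomyces Strain Engineering
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mining secondary-metabolite exporters
    from time-course transcriptomes and genomes of Streptomyces, and for
    designing tunable plug-and-play exporter (TuPPE) expression cassettes.
    Screens genes whose time-course FPKM profiles track a product-titer
    curve; triages a genome's transporters by substrate and family with
    Kyte-Doolittle transmembrane-helix prediction, Walker A motif
    detection and ABC half-transporter system assembly including
    TMD/NBD completion from neighbouring genes; diversifies candidates
    with neighbor-joining trees on Poisson-corrected protein distances
    with bootstrap supports; mines temporal promoters by hierarchical
    clustering of fold-change profiles against the production curve and
    assembles combinatorial promoter x RBS x exporter cassettes with
    EcoRI/SpeI/XbaI junctions. A synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, Genetics, Phylogenetics, SyntheticBiology
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'TuppeMiner-package.R'
    'utils.R'
    'io.R'
    'phylo.R'
    'tuppe.R'
    'triage.R'
    'screen.R'
    'pipeline.R'
    'synthetic-data.R'
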