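Package: nlrscape
Title: Comparative Genomics of Plant NB-LRR Resistance Gene Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying plant NB-LRR (nucleotide-binding,
    leucine-rich-repeat) resistance gene repertoires across species:
    PSSM-based domain scanning with exact p-values and TNL/CNL/RNL
    architecture classification, physical R-gene cluster detection from
    gene models, orthogroup inference by reciprocal best hits and Markov
    clustering, expectation-maximization decomposition of NB domains into
    ungapped motifs with MAST-style rescanning, and family-level motif
    presence/absence profiling. Includes a synthetic multi-species cohort
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'align.R'
    'domainscan.R'
    'genecluster.R'
    'io.R'
    'motifkit.R'
    'nlrscape-package.R'
    'orthology.R'
    'pipeline.R'
    'profiles.R'
    'pssm.R'
    'synthdata.R'
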