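Package: pepHLAtarget
Title: Discovery and Cross-Reactivity Prioritization of Cancer-Specific
    Peptide-HLA Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for discovering cancer-specific
    peptide-HLA class I targets and prioritizing them by predicted
    off-target cross-reactivity. Enumerates candidate 9-mer peptides from a
    canonical proteome, attaches peptide-HLA binding-affinity predictions,
    applies tumor-versus-normal RPKM percentile filters to call
    cancer-specific targets, finds proteome-wide similar peptides by degree
    of similarity (identical residues at identical positions) with an exact
    pigeonhole block index, derives 9-position contact patterns from
    peptide-HLA-TCR/antibody structures to vote positional importance, and
    validates the importance predictor by leave-one-out ROC. Ships
    synthetic-fixture generators (proteomes, affinity tables, expression
    matrices, toy structures) with verified planted truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'affinity.R'
    'expression.R'
    'importance.R'
    'pepHLAtarget-package.R'
    'pipeline.R'
    'proteome.R'
    'similarity.R'
    'structures.R'
    'synthetic.R'
    'utils.R'
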