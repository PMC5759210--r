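Package: editscope
Title: Targeted Amplicon Quantification of A-to-I RNA Editing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies adenosine-to-inosine (A-to-I) RNA editing from
    multiplexed targeted-amplicon sequencing reads. Provides a seeded
    synthetic-read generator for amplicon panels with linked editing sites,
    barcode demultiplexing, an ungapped amplicon aligner, fragment-level
    pileup with site-level editing fractions and replicate/missingness
    filters, per-read phasing of the serotonin receptor 2C (Htr2c) A-E
    editing cluster into mRNA variants and protein isoforms (with an
    independent variant-reference assignment method), orthogonal assay
    estimators (Sanger peak areas, Adarb1 alternative splicing, qPCR
    normalization) and a Mann-Whitney / Benjamini-Hochberg group-comparison
    layer with an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), jsonlite
biocViews: Sequencing, Transcriptomics, RNAEditing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
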