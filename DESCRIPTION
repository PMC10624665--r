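Package: ipQC
Title: Quality Control, Curation and Candidate Selection for MHC Class I
    Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates eluted-peptide (immunopeptidomics) datasets and
    prioritizes candidate tumour antigens. Provides parsers for search-engine
    peptide exports and FASTA proteomes, a position-specific scoring matrix
    (PSSM) binding surrogate with Monte-Carlo rank-percentile calibration and
    strong/weak/non-binder classification, per-run QC metrics (length
    distributions, binder fractions, allele-specificity deconvolution,
    UpSet-style replicate overlaps, motif summaries), a protein-coverage-ratio
    filter for proteolytic contaminants with a clean-run-derived cutoff,
    cross-sample overlap and haplotype clustering, whole-proteome 9mer
    scanning, and a multi-criteria vaccine-candidate selection pipeline.
    A synthetic-data module generates motif-consistent fixtures with known
    ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
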