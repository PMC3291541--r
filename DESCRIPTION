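Package: pmhcOverlap
Title: Self/Nonself Overlap of MHC Class I Presented Peptides Under
    Degenerate T-Cell Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how often pathogen-derived MHC class I presented
    9mer peptides are identical to, or indistinguishable by T-cells from,
    host-presented peptides. Provides k-mer peptidome indexing over FASTA
    proteomes with shuffled-sequence controls, a pluggable peptide-MHC
    binding interface with fixed (500 nM) and specificity-scaled
    presentation thresholds, exact and degenerate (region-constrained
    conservative-mismatch) T-cell recognition models built from amino-acid
    substitution or covariance matrices, a min-max scaled peptide
    similarity score, cross-reactivity footprint calculations with a
    closed-form population average, permutation enrichment and chi-square
    immunogenicity association tests, per-position entropy and
    additional-anchor selectivity, TCR-peptide contact counting in
    structures at a distance cutoff, and synthetic-data generators with
    planted ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
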