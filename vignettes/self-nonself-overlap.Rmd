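---
title: "Self/nonself overlap of presented peptides under degenerate T-cell recognition"
author: "pmhcOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self/nonself overlap of presented peptides under degenerate T-cell recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhcOverlap)
```

## The question and the model

Cytotoxic T-cells survey 9mer peptides presented on MHC class I
molecules (pMHCs) and must decide whether a cell is displaying foreign
material. The quantity this package computes is the **self/nonself
overlap**: the probability that a pathogen-derived presented 9mer is
indistinguishable — by the T-cell receptor — from some host-derived
presented 9mer. If that probability is large, self-tolerance deletes
the very clones that could respond to many foreign epitopes,
producing "holes" in the T-cell repertoire, and conversely every
self-similar foreign peptide is a potential autoimmunity trigger.

"Indistinguishable" is a modelling choice, and the package implements a
ladder of definitions as `RecognitionModel` objects:

* **complete exact** (`completeMatchModel()`): identity at P1–P9;
* **middle exact** (`middleMatchModel()`): identity at the TCR-exposed
  middle positions P3–P8 (the anchors P2/P9 sit in MHC pockets and P1
  barely affects recognition);
* **non-anchor exact** (`nonAnchorMatchModel()`): identity at P1 and
  P3–P8;
* **degenerate** (`degenerateModel(rule)`): the cross-reactive model.
  The TCR reads P3–P8; no mismatch is tolerated at the most stringently
  read position P5; at most one mismatch is allowed among the positions
  N-terminal of P5 (P3–P4) and one among those C-terminal of it
  (P6–P8); and every tolerated mismatch must be *conservative*, i.e.
  allowed by a `SimilarityRule`.

A `SimilarityRule` is derived from a symmetric 20×20 amino-acid matrix
by thresholding (`buildSimilarityRule()`): for covariance-style
matrices measured on peptide–MHC binding data the convention is
absolute covariance > 0.05; for BLOSUM-style matrices, a positive
score. Two design points were genuinely open and are resolved as
follows:

* *Absolute versus signed covariance.* The absolute-value reading is
  the default (`abs_covariance_gt`), which is the literal form of the
  published convention for covariance matrices; since a strongly
  negative covariance arguably signals dissimilarity, the signed
  variant ships as `value_gt` and can be swapped in without touching
  anything else.
* *Adjacent mismatches.* The two-region budget structure is exactly
  what forbids two substitutions next to each other; the variant that
  permits them (`adjacentMismatchModel()`) is a single region
  {P3,P4,P6,P7,P8} with budget 2, and the allele-specific variant
  (`alleleSpecificModel()`) reads an allele's six least specific
  positions, splitting at the most specific recognized position, which
  is held fixed — mirroring the default model's anatomy around P5.

Two peptides `a`, `b` are "seen by the same T-cell" iff
`isRecognized(a, b, model)`. For counting overlaps over large sets the
package never scans pairs: each self peptide is indexed by its
projection onto the recognized positions, and each nonself peptide
probes the index with its `recognizedKeys()` — the set of projections
any recognized partner must have. Under the default rule densities this
is ≈ 25 probes per peptide and scales linearly; tests assert exact
agreement with the all-pairs predicate on every instance.

## Presentation: fixed and scaled thresholds

Which 9mers are presented is delegated to a `BindingModel` contract
(predicted IC50 in nM, lower = stronger). Neural-network predictors are
deliberately out of scope: their tabulated output can be imported with
`importScoreTable()`, and a built-in position-weight
`MotifBindingModel` (built by `makeAllele()`) stands in for them in all
tests. Processing (proteasomal C-terminal cleavage + TAP) is a second
contract; the default is pass-through, with a toy C-terminal preference
model available. How cleavage and transport scores were combined in the
original predictor pipelines is not recoverable from their outputs, so
the package keeps this stage behind the contract rather than guessing.

Thresholds come in two flavours (`ThresholdSpec`):

* **fixed**: a universal cutoff, 500 nM by default — the conventional
  binder/non-binder boundary on HLA-A\*0201;
* **scaled**: per-allele calibration (`calibrateScaledThreshold()`) so
  that a target fraction of *self* peptides is presented, 2.3% by
  default (the specificity of HLA-A\*0201 at 500 nM). This removes
  between-allele variance in the number of presented self peptides,
  which otherwise dominates the overlap comparison.

Numerical conventions: the binder comparison is inclusive
(score ≤ threshold). Calibration returns the largest empirical quantile
whose achieved fraction does not exceed target + 1/N; ties at the
threshold are included and the achieved specificity is *reported*, not
forced — deterministic and auditable. A degenerate (all-equal) score
distribution is refused with a pointer to fixed mode.

## Cross-reactivity footprint

For a single T-cell (one 6mer at the recognized positions), the number
of *other* recognized residue combinations has a closed form: with one
mismatch per region it is

$$\Big(1 + \sum_{i \in \mathrm{N\text{-}region}} s_i\Big)
  \Big(1 + \sum_{i \in \mathrm{C\text{-}region}} s_i\Big) - 1,$$

where $s_i$ is the similar-set size of the residue at position $i$
(general budgets use the truncated elementary-symmetric expansion).
Averaging over uniform i.i.d. residues factorizes exactly, so
`averageFootprint()` is analytic; `exhaustiveVariantCount()` and
`monteCarloFootprint()` provide brute-force and stochastic
cross-checks, and the tests enumerate complete 6mer spaces on reduced
alphabets to validate the closed form.

One counting convention matters. For any symmetric pair rule on 20
letters the mean similar-set size is $\bar s = \text{npairs}/10$, a
multiple of 0.1, so the population mean of the *exclusive* other-count
$(1+2\bar s)(1+3\bar s)-1$ can only take values …, 21.0, 23.36, 25.84, …
— it jumps over 24. A reported average of "24 recognized combinations"
is therefore only consistent with the *inclusive* count (other + self,
24.36 at $\bar s = 1.6$). `averageFootprint()` returns both
(`meanOtherCount`, `meanRecognizedCount`) and both reciprocals; the
"1 in N" cross-reactivity uses the exclusive count, which at
$\bar s = 1.6$ gives $20^6 / 23.36 \approx 2.7$ million.

## Statistics

* `chiSquare2x2()` tests the association between immunogenicity and
  self-overlap in a 2×2 table with the uncorrected Pearson statistic
  ($\chi^2 = n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, 1 df). The
  continuity correction is off by default because the uncorrected
  statistic reproduces all four published reference p-values for this
  analysis (0.027, 0.29, 0.066, 0.0038) at two significant figures;
  Yates' correction sits behind a flag.
* `permutationEnrichment()` flags self proteins sharing 9mers with more
  pathogen species than their length predicts. The published procedure
  draws a per-protein count "based on the expected fraction of overlaps
  and given the protein length" without naming a distribution; the
  minimal faithful choice used here is Binomial(nSpecies, p) with
  p ∝ length, normalized to the global per-residue rate. A protein is
  flagged iff its observed count beats all 1000 permutation draws
  (empirical p < 1/1001) — the strict reading of the selection rule.
* `positionEntropy()` gives the per-position Shannon entropy (bits) of
  a presented set; `additionalAnchorAssessment()` flags alleles whose
  non-anchor positions (P1, P3–P8) carry more than 25% of the total
  selectivity. Selectivity is measured as information content
  (log₂20 − H) by default: the literal prescription sums *entropy*, but
  high entropy means low selectivity, so a literal-entropy mode exists
  and the tests demonstrate that it mislabels even a classical-anchor
  profile. `leastSpecificPositions()` breaks entropy ties by position
  order.
* `spearmanRank()` is tie-aware Spearman correlation with the
  two-sided t-approximation p-value.

## Structures

`countContacts()` counts, per peptide position, the distinct TCR
residues with any non-hydrogen atom strictly within 5.0 Å of any
non-hydrogen atom of that position, and normalizes to per-structure
fractions. Residue-level counting (not atoms) is the natural reading of
"number of TCR amino acids"; hydrogens are excluded because most
crystal structures lack them; altloc conformers reduce to the highest
occupancy; chains are named explicitly by annotation (with
`suggestPeptideChain()` as a helper) so results are deterministic
across PDB dialects. The boundary is strict: a residue at exactly the
cutoff does not count, and `makeToyStructure()` places atoms at exact
distances so this convention is directly testable.
`comparePositionGroups()` applies the two-sided Wilcoxon rank-sums test
to central (P4–P8) versus flanking (P1–P3, P9) contact fractions.

## What the synthetic generators emulate — and what they do not

All tests run on generated data with planted ground truth:

* `makeProteomes()` plants contiguous self-copied segments into
  background i.i.d. proteomes so that a chosen fraction of each nonself
  protein's 9mer windows matches self verbatim. This emulates the
  homology that drives real self/nonself overlap and is exactly
  recoverable (`lengthScan()` recovers the planted rate within binomial
  noise; shuffling destroys it). It does **not** emulate phylogenetic
  correlation between species, amino-acid composition bias, repeat
  structure, or the near-miss homology that inflates *degenerate* but
  not exact overlap — so passing tests certify the machinery, not the
  real-proteome percentages.
* `makeAllele()` plants anchor structure as weight dispersion; real
  binding motifs have correlated pockets and heavier tails.
* `makeSimilarityMatrix()` controls exactly one property of a
  covariance matrix — the density of its thresholded rule (mean
  similar-set size within 0.2 of target; resolution 0.1 because pair
  counts are integers). Footprint and overlap behaviour depend on the
  rule only through set sizes, so this is the right invariant to pin;
  the matrix values themselves are synthetic and carry no biochemistry.
* `makeImmunogenicityLabels()` plants a log-odds effect of
  non-overlap on immunogenicity; `makeToyStructure()` writes minimal
  CA-only PDB files realizing exact contact geometries.

Generation is deterministic given `seed` and never perturbs the
caller's RNG stream.

## Default study conditions and problem sizes

The defaults encode the analysis conditions: peptide length 9, scaled
threshold specificity 0.023 (fixed mode 500 nM), similarity cutoff
0.05 (absolute covariance) or positive score (BLOSUM), similarity-score
threshold 0.85 on the min–max scale, contact cutoff 5.0 Å, permutation
count 1000, additional-anchor fraction 0.25. Synthetic runs in the
tests and acceptance script use 40 self proteins × 400 residues,
6 species × 10 proteins × 300 residues, planted shared-9mer rates
0.02–0.05, 2000-peptide brute-force comparisons, and 100–200 replicate
simulations — sizes chosen so every stochastic assertion has comfortable
power while a full run stays interactive.

Where real inputs are wanted instead, `readProteome()` accepts any
FASTA (evidence filtering of the self proteome is the caller's
responsibility), `importScoreTable()` accepts tabulated predictor
output, and `readSubstitutionMatrix()` reads the standard 20×20
whitespace-delimited text format in which measured covariance matrices
are distributed — drop the file in and pass it to
`buildSimilarityRule()`. The package fabricates no measured matrix
values; its shipped matrices are the synthetic stand-ins described
above, and BLOSUM matrices come from Biostrings.

## Degenerate inputs and edge conventions

Non-canonical residues (X, B, Z, U) keep their protein but poison any
k-mer window containing them, matching predictor behaviour and
fabricating nothing. `extractKmers()` with k longer than every sequence
returns an empty set (not an error); an empty self set in
`overlapFraction()` warns and returns zero; a kingdom with no k-long
peptide is reported as absent from the length scan rather than as 0/0.
Redundancy reduction between proteomes uses the shared unique-9mer
fraction relative to the smaller proteome (greedy, largest first,
threshold 0.8) — a k-mer proxy for an all-to-all alignment criterion
with the same normalization direction, chosen to avoid an external
aligner; it is idempotent. Overlap is always counted per unique
peptide, for both numerator and denominator.

## Known limitations

* Real headline percentages require the original proteome snapshots and
  neural-network predictors; this package reproduces the *procedures*
  and validates them on planted ground truth.
* The key-index overlap assumes a symmetric similarity rule (all
  shipped rule builders guarantee symmetry; the class validates it).
* The min–max similarity score needs an explicit choice of reference
  peptide; `peptideSimilarityScore(query, reference, matrix)` makes the
  choice visible in the call rather than hiding a default, because
  either direction is defensible when comparing nonself against self.
* The permutation null treats species as exchangeable and ignores
  between-protein correlation (shared domains), so its flags are a
  screening tool, not calibrated genome-wide inference.
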