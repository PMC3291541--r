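## S4 class definitions for the package's central containers.

#' ProteomeSet: one species' protein sequences
#'
#' A set of protein sequences from a single species, tagged with the
#' species identifier and its kingdom (`"self"`, `"virus"` or
#' `"bacterium"`). Sequences are held as a [Biostrings::AAStringSet].
#'
#' @slot records An `AAStringSet` of protein sequences (uppercase).
#' @slot speciesId Single character, species identifier.
#' @slot kingdom One of `"self"`, `"virus"`, `"bacterium"`.
#'
#' @seealso [proteomeSet()], [readProteome()], [extractKmers()]
#' @export
setClass("ProteomeSet",
  representation(records = "AAStringSet",
                 speciesId = "character",
                 kingdom = "character"))

setValidity("ProteomeSet", function(object) {
  msg <- character(0)
  if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-empty string")
  if (length(object@kingdom) != 1L ||
      !object@kingdom %in% c("self", "virus", "bacterium"))
    msg <- c(msg, "kingdom must be one of 'self', 'virus', 'bacterium'")
  if (length(object@records) < 1L)
    msg <- c(msg, "a ProteomeSet needs at least one record")
  if (length(msg)) msg else TRUE
})

#' PeptideSet: unique k-mer peptides from one source
#'
#' The set of distinct length-`k` peptides extracted from a proteome
#' (duplicate occurrences within the proteome count once).
#'
#' @slot k Integer peptide length.
#' @slot peptides Character vector of distinct k-mers over the canonical
#'   alphabet.
#' @slot speciesId Source species identifier.
#' @slot kingdom Source kingdom.
#'
#' @seealso [extractKmers()], [overlapFraction()]
#' @export
setClass("PeptideSet",
  representation(k = "integer",
                 peptides = "character",
                 speciesId = "character",
                 kingdom = "character"))

setValidity("PeptideSet", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (anyDuplicated(object@peptides))
    msg <- c(msg, "peptides must be unique (set semantics)")
  if (length(object@peptides) && any(nchar(object@peptides) != object@k))
    msg <- c(msg, "every peptide must have length k")
  if (length(msg)) msg else TRUE
})

#' SubstitutionMatrix: a symmetric 20 x 20 amino-acid matrix
#'
#' A symmetric real-valued matrix over the 20 canonical amino acids, as
#' used for conservative-substitution rules (PMBEC covariances, BLOSUM
#' scores) and for the min-max scaled peptide similarity score.
#'
#' @slot name Matrix name (provenance).
#' @slot values Numeric square matrix with residue dimnames (20 x 20
#'   over the canonical amino acids in normal use; reduced alphabets are
#'   allowed for exhaustive validation); symmetric to within 1e-9, all
#'   pairs present.
#'
#' @seealso [substitutionMatrix()], [readSubstitutionMatrix()],
#'   [buildSimilarityRule()], [peptideSimilarityScore()]
#' @export
setClass("SubstitutionMatrix",
  representation(name = "character", values = "matrix"))

setValidity("SubstitutionMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v) || nrow(v) != ncol(v))
    msg <- c(msg, "values must be a square numeric matrix")
  else {
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
      msg <- c(msg, "values must have identical row and column residue names")
    else if (max(abs(v - t(v))) > 1e-9)
      msg <- c(msg, "values must be symmetric (tolerance 1e-9)")
    if (anyNA(v)) msg <- c(msg, "all residue pairs must be present (no NA)")
  }
  if (length(msg)) msg else TRUE
})

#' SimilarityRule: per-residue sets of allowed conservative substitutions
#'
#' For every amino acid, the set of *other* amino acids a T-cell is
#' assumed not to distinguish it from. Derived from a
#' [SubstitutionMatrix-class] by thresholding (e.g. absolute PMBEC
#' covariance > 0.05, or a positive BLOSUM score). The relation is
#' symmetric and irreflexive.
#'
#' @slot similar Named list (one element per amino acid) of character
#'   vectors of interchangeable partners.
#' @slot provenance Descriptor of the source matrix and rule.
#'
#' @seealso [buildSimilarityRule()], [emptySimilarityRule()]
#' @export
setClass("SimilarityRule",
  representation(similar = "list", provenance = "character"))

setValidity("SimilarityRule", function(object) {
  s <- object@similar
  aa <- names(s)
  msg <- character(0)
  if (is.null(aa) || anyDuplicated(aa))
    msg <- c(msg, "similar must be a uniquely named list")
  for (a in aa) {
    if (a %in% s[[a]]) {
      msg <- c(msg, sprintf("residue %s must not be similar to itself", a))
      break
    }
    for (b in s[[a]]) {
      if (!b %in% aa || !a %in% s[[b]]) {
        msg <- c(msg, sprintf("rule not symmetric: %s ~ %s", a, b))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' RecognitionModel: which peptide positions a T-cell reads, and how
#'
#' Encodes a model of TCR recognition of a 9mer peptide: the positions
#' the TCR reads (default the middle P3-P8), positions where no mismatch
#' is tolerated (default P5), mismatch-budget regions (default one
#' conservative mismatch N-terminal of P5 and one C-terminal of it), and
#' the [SimilarityRule-class] restricting which mismatches count as
#' conservative. Positions outside `recognizedPositions` are ignored
#' entirely (the anchor residues P2/P9 and usually P1).
#'
#' @slot recognizedPositions Sorted integer subset of 1..9.
#' @slot fixedPositions Subset of `recognizedPositions` requiring exact
#'   identity.
#' @slot regions List of `list(positions=, budget=)`; the `positions`
#'   fields partition `recognizedPositions` minus `fixedPositions`.
#' @slot rule A `SimilarityRule`.
#'
#' @seealso [recognitionModel()], [degenerateModel()], [isRecognized()],
#'   [recognizedKeys()]
#' @export
setClass("RecognitionModel",
  representation(recognizedPositions = "integer",
                 fixedPositions = "integer",
                 regions = "list",
                 rule = "SimilarityRule"))

setValidity("RecognitionModel", function(object) {
  msg <- character(0)
  rp <- object@recognizedPositions
  fp <- object@fixedPositions
  if (length(rp) < 1L || any(rp < 1L | rp > 9L) || is.unsorted(rp, strictly = TRUE))
    msg <- c(msg, "recognizedPositions must be a sorted subset of 1..9")
  if (!all(fp %in% rp))
    msg <- c(msg, "fixedPositions must be a subset of recognizedPositions")
  free <- setdiff(rp, fp)
  covered <- integer(0)
  for (r in object@regions) {
    if (!is.list(r) || !all(c("positions", "budget") %in% names(r))) {
      msg <- c(msg, "each region needs 'positions' and 'budget'")
      break
    }
    if (r$budget < 0L) msg <- c(msg, "region budgets must be >= 0")
    covered <- c(covered, r$positions)
  }
  if (anyDuplicated(covered) || !setequal(covered, free))
    msg <- c(msg, "regions must partition recognizedPositions minus fixedPositions")
  if (length(msg)) msg else TRUE
})

## ---- presentation ----------------------------------------------------

#' BindingModel: pluggable peptide-MHC binding contract
#'
#' Virtual parent of all binding models. A binding model predicts an
#' IC50-like affinity in nM for canonical 9mers (lower = stronger
#' binding) via [predictIC50()], deterministically. Stand-ins for
#' neural-network predictors such as NetMHC; their precomputed output can
#' be imported with [importScoreTable()].
#'
#' @slot alleleName MHC allele name (e.g. `"HLA-A*0201"`).
#' @export
setClass("BindingModel",
  representation(alleleName = "character", "VIRTUAL"))

#' MotifBindingModel: position-weight toy binding model
#'
#' Built-in [BindingModel-class]: a 9 x 20 table of per-position energy
#' contributions summed over the peptide and mapped through `exp()` to an
#' IC50-like nM scale. Anchor positions carry stronger weight dispersion,
#' so the low-IC50 tail is strongly enriched for anchor-preferred
#' residues (testable via [positionEntropy()]).
#'
#' @slot weights Numeric 9 x 20 matrix (rows P1..P9, columns amino
#'   acids) of log-scale energy contributions.
#' @slot intercept Numeric log-nM intercept.
#' @slot anchorPositions Integer anchor positions (metadata).
#'
#' @seealso [makeAllele()], [predictIC50()]
#' @export
setClass("MotifBindingModel", contains = "BindingModel",
  representation(weights = "matrix",
                 intercept = "numeric",
                 anchorPositions = "integer"))

setValidity("MotifBindingModel", function(object) {
  w <- object@weights
  if (!is.numeric(w) || any(dim(w) != c(9L, 20L)) ||
      !setequal(colnames(w), aminoAcids()))
    return("weights must be a 9 x 20 numeric matrix with amino-acid columns")
  TRUE
})

#' TableBindingModel: lookup-backed binding model
#'
#' A [BindingModel-class] backed by a table of precomputed
#' (peptide, IC50) scores, e.g. imported NetMHC-style output. Querying a
#' peptide absent from the table is an error.
#'
#' @slot scores Named numeric vector, names are peptides, values IC50 nM.
#' @seealso [importScoreTable()]
#' @export
setClass("TableBindingModel", contains = "BindingModel",
  representation(scores = "numeric"))

#' ProcessingModel: proteasomal cleavage / TAP transport contract
#'
#' Virtual parent for the processing stage (C-terminal proteasomal
#' cleavage plus TAP transport) deciding which peptides reach the ER.
#' [PassThroughProcessing-class] accepts everything;
#' [CTermCleavageModel-class] is a toy preference over the C-terminal
#' residue.
#' @export
setClass("ProcessingModel", representation("VIRTUAL"))

#' @rdname ProcessingModel-class
#' @export
setClass("PassThroughProcessing", contains = "ProcessingModel")

#' CTermCleavageModel: toy C-terminal cleavage scorer
#'
#' Passes a peptide iff the preference score of its C-terminal residue is
#' at least `threshold`.
#'
#' @slot preference Named numeric vector over the 20 amino acids.
#' @slot threshold Numeric cutoff.
#' @export
setClass("CTermCleavageModel", contains = "ProcessingModel",
  representation(preference = "numeric", threshold = "numeric"))

#' ThresholdSpec: fixed or scaled presentation threshold
#'
#' `mode = "fixed"` uses a universal IC50 cutoff (500 nM by default);
#' `mode = "scaled"` calibrates a per-allele cutoff so that a target
#' fraction of *self* peptides (2.3% by default, the specificity of
#' HLA-A*0201 at 500 nM) is presented.
#'
#' @slot mode `"fixed"` or `"scaled"`.
#' @slot fixedValue IC50 cutoff in nM (fixed mode).
#' @slot targetSpecificity Fraction of self 9mers presented (scaled mode).
#'
#' @seealso [fixedThreshold()], [scaledThreshold()],
#'   [calibrateScaledThreshold()]
#' @export
setClass("ThresholdSpec",
  representation(mode = "character",
                 fixedValue = "numeric",
                 targetSpecificity = "numeric"))

setValidity("ThresholdSpec", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("fixed", "scaled"))
    msg <- c(msg, "mode must be 'fixed' or 'scaled'")
  if (object@mode == "scaled" &&
      (object@targetSpecificity <= 0 || object@targetSpecificity > 1))
    msg <- c(msg, "targetSpecificity must be in (0, 1]")
  if (object@mode == "fixed" && object@fixedValue <= 0)
    msg <- c(msg, "fixedValue must be positive")
  if (length(msg)) msg else TRUE
})

#' PresentedSet: peptides predicted presented by one allele
#'
#' The unique 9mers from one source predicted to be presented by one
#' allele: IC50 at or below the realized threshold and accepted by the
#' processing model.
#'
#' @slot alleleName Allele.
#' @slot threshold Realized IC50 threshold in nM.
#' @slot peptides Unique presented peptides.
#' @slot speciesId,kingdom Source annotation.
#'
#' @seealso [presentedSet()]
#' @export
setClass("PresentedSet",
  representation(alleleName = "character",
                 threshold = "numeric",
                 peptides = "character",
                 speciesId = "character",
                 kingdom = "character"))

setValidity("PresentedSet", function(object) {
  if (anyDuplicated(object@peptides)) "peptides must be unique" else TRUE
})

#' OverlapResult: self/nonself overlap fractions
#'
#' Result of [overlapFraction()]: per-species overlap counts, pooled
#' fractions per kingdom (total overlaps / total peptides within the
#' kingdom), and the unweighted mean of the viral and bacterial pooled
#' fractions.
#'
#' @slot allele Allele name or `"no-MHC"`.
#' @slot model Model descriptor.
#' @slot perSpecies `data.frame` with columns `speciesId`, `kingdom`,
#'   `nPeptides`, `nOverlap`, `fraction`.
#' @slot pooled Named numeric, pooled fraction per kingdom.
#' @slot kingdomAverage Numeric scalar.
#' @export
setClass("OverlapResult",
  representation(allele = "character",
                 model = "character",
                 perSpecies = "data.frame",
                 pooled = "numeric",
                 kingdomAverage = "numeric"))

#' ContactProfile: per-position TCR contacts in one structure
#'
#' For one TCR-pMHC structure, the number of distinct TCR residues with a
#' non-hydrogen atom within the distance cutoff of each peptide position
#' P1..P9, and each position's fraction of the structure's total
#' peptide-TCR contacts.
#'
#' @slot structureId Structure identifier.
#' @slot counts Integer vector length 9.
#' @slot fractions Numeric vector length 9 (zeros if no contacts at all).
#' @seealso [countContacts()], [comparePositionGroups()]
#' @export
setClass("ContactProfile",
  representation(structureId = "character",
                 counts = "integer",
                 fractions = "numeric"))

setValidity("ContactProfile", function(object) {
  msg <- character(0)
  if (length(object@counts) != 9L || any(object@counts < 0L))
    msg <- c(msg, "counts must be 9 non-negative integers")
  if (length(object@fractions) != 9L)
    msg <- c(msg, "fractions must have length 9")
  if (sum(object@counts) > 0L &&
      abs(sum(object@fractions) - 1) > 1e-8)
    msg <- c(msg, "fractions must sum to 1 when any contact exists")
  if (length(msg)) msg else TRUE
})
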