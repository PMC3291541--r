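#' Predict peptide-MHC binding affinity
#'
#' Generic of the binding-model contract: returns the predicted IC50 in
#' nM (lower = stronger binding) for each peptide. Deterministic: the
#' same peptide always yields the same score.
#'
#' @param model A [BindingModel-class].
#' @param peptides Character vector of 9mers.
#' @return Numeric vector of IC50 values (nM), same length as `peptides`.
#' @export
setGeneric("predictIC50", function(model, peptides)
  standardGeneric("predictIC50"))

#' Processing-stage filter
#'
#' Generic of the processing contract (proteasomal C-terminal cleavage +
#' TAP transport): TRUE for peptides that reach the ER.
#'
#' @param model A [ProcessingModel-class].
#' @param peptides Character vector of peptides.
#' @return Logical vector.
#' @export
setGeneric("passesProcessing", function(model, peptides)
  standardGeneric("passesProcessing"))

#' @name accessors
#' @title Accessors for pmhcOverlap objects
#' @description Small accessor generics for the package's S4 containers:
#'   `peptides()` returns the peptide character vector of a
#'   [PeptideSet-class] or [PresentedSet-class]; `kingdom()` and
#'   `speciesId()` return source annotation; `alleleName()` the allele of
#'   a binding model or presented set; `kmerLength()` the k of a
#'   `PeptideSet`; `similarSets()` the per-residue partner sets of a
#'   [SimilarityRule-class]; `matrixValues()` the numeric matrix of a
#'   [SubstitutionMatrix-class]; `contactCounts()`/`contactFractions()`
#'   the per-position vectors of a [ContactProfile-class];
#'   `pooledFractions()`/`kingdomAverage()` the summary numbers of an
#'   [OverlapResult-class].
#' @param x An object.
#' @return The slot value (see Description).
NULL

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname accessors
#' @export
setGeneric("kingdom", function(x) standardGeneric("kingdom"))
#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setGeneric("alleleName", function(x) standardGeneric("alleleName"))
#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setGeneric("similarSets", function(x) standardGeneric("similarSets"))
#' @rdname accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setGeneric("contactFractions", function(x) standardGeneric("contactFractions"))
#' @rdname accessors
#' @export
setGeneric("pooledFractions", function(x) standardGeneric("pooledFractions"))
#' @rdname accessors
#' @export
setGeneric("kingdomAverage", function(x) standardGeneric("kingdomAverage"))
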