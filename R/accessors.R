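## Accessor and show methods.

#' @rdname accessors
#' @aliases peptides,PeptideSet-method
setMethod("peptides", "PeptideSet", function(x) x@peptides)
#' @rdname accessors
setMethod("peptides", "PresentedSet", function(x) x@peptides)
#' @rdname accessors
setMethod("kingdom", "PeptideSet", function(x) x@kingdom)
#' @rdname accessors
setMethod("kingdom", "ProteomeSet", function(x) x@kingdom)
#' @rdname accessors
setMethod("kingdom", "PresentedSet", function(x) x@kingdom)
#' @rdname accessors
setMethod("speciesId", "PeptideSet", function(x) x@speciesId)
#' @rdname accessors
setMethod("speciesId", "ProteomeSet", function(x) x@speciesId)
#' @rdname accessors
setMethod("speciesId", "PresentedSet", function(x) x@speciesId)
#' @rdname accessors
setMethod("alleleName", "BindingModel", function(x) x@alleleName)
#' @rdname accessors
setMethod("alleleName", "PresentedSet", function(x) x@alleleName)
#' @rdname accessors
setMethod("kmerLength", "PeptideSet", function(x) x@k)
#' @rdname accessors
setMethod("similarSets", "SimilarityRule", function(x) x@similar)
#' @rdname accessors
setMethod("matrixValues", "SubstitutionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("contactCounts", "ContactProfile", function(x) {
  stats::setNames(x@counts, paste0("P", 1:9))
})
#' @rdname accessors
setMethod("contactFractions", "ContactProfile", function(x) {
  stats::setNames(x@fractions, paste0("P", 1:9))
})
#' @rdname accessors
setMethod("pooledFractions", "OverlapResult", function(x) x@pooled)
#' @rdname accessors
setMethod("kingdomAverage", "OverlapResult", function(x) x@kingdomAverage)

#' Protein records of a ProteomeSet
#'
#' @param x A [ProteomeSet-class].
#' @return The underlying [Biostrings::AAStringSet].
#' @export
proteinRecords <- function(x) {
  stopifnot(is(x, "ProteomeSet"))
  x@records
}

#' Realized presentation threshold of a PresentedSet
#'
#' @param x A [PresentedSet-class].
#' @return IC50 threshold in nM.
#' @export
presentationThreshold <- function(x) {
  stopifnot(is(x, "PresentedSet"))
  x@threshold
}

#' Per-species overlap table of an OverlapResult
#'
#' @param x An [OverlapResult-class].
#' @return `data.frame` with columns `speciesId`, `kingdom`,
#'   `nPeptides`, `nOverlap`, `fraction`.
#' @export
perSpeciesOverlap <- function(x) {
  stopifnot(is(x, "OverlapResult"))
  x@perSpecies
}

setMethod("show", "ProteomeSet", function(object) {
  cat(sprintf("ProteomeSet '%s' (%s): %d proteins, %d residues\n",
              object@speciesId, object@kingdom, length(object@records),
              sum(Biostrings::width(object@records))))
})

setMethod("show", "PeptideSet", function(object) {
  cat(sprintf("PeptideSet '%s' (%s): %d unique %d-mers\n",
              object@speciesId, object@kingdom,
              length(object@peptides), object@k))
})

setMethod("show", "SimilarityRule", function(object) {
  sizes <- lengths(object@similar)
  cat(sprintf("SimilarityRule [%s]: %d residues, %d pairs, mean set size %.2f\n",
              object@provenance, length(sizes), sum(sizes) / 2L,
              mean(sizes)))
})

setMethod("show", "SubstitutionMatrix", function(object) {
  cat(sprintf("SubstitutionMatrix '%s' (20 x 20, symmetric)\n", object@name))
})

setMethod("show", "RecognitionModel", function(object) {
  fmt <- function(p) if (length(p)) paste0("P", p, collapse = ",") else "-"
  regs <- vapply(object@regions, function(r)
    sprintf("{%s}<=%d", fmt(r$positions), r$budget), character(1))
  cat(sprintf("RecognitionModel: recognized %s; fixed %s; regions %s; rule %s\n",
              fmt(object@recognizedPositions), fmt(object@fixedPositions),
              if (length(regs)) paste(regs, collapse = " ") else "-",
              object@rule@provenance))
})

setMethod("show", "MotifBindingModel", function(object) {
  cat(sprintf("MotifBindingModel '%s': anchors %s\n", object@alleleName,
              paste0("P", object@anchorPositions, collapse = ",")))
})

setMethod("show", "TableBindingModel", function(object) {
  cat(sprintf("TableBindingModel '%s': %d stored peptide scores\n",
              object@alleleName, length(object@scores)))
})

setMethod("show", "ThresholdSpec", function(object) {
  if (object@mode == "fixed")
    cat(sprintf("ThresholdSpec: fixed %.0f nM\n", object@fixedValue))
  else
    cat(sprintf("ThresholdSpec: scaled to self specificity %.3f\n",
                object@targetSpecificity))
})

setMethod("show", "PresentedSet", function(object) {
  cat(sprintf("PresentedSet '%s' on %s: %d peptides (threshold %.1f nM)\n",
              object@speciesId, object@alleleName,
              length(object@peptides), object@threshold))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult [%s, %s]: %d species\n", object@allele,
              object@model, nrow(object@perSpecies)))
  for (kg in names(object@pooled))
    cat(sprintf("  pooled %-9s %.4f\n", kg, object@pooled[[kg]]))
  cat(sprintf("  kingdom average %.4f\n", object@kingdomAverage))
})

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile '%s': counts %s\n", object@structureId,
              paste(object@counts, collapse = " ")))
})
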