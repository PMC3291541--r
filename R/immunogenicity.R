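## Immunogenicity labelling and the 2x2 self-overlap association table.

#' Classify assay outcomes into immunogenic / non-immunogenic pMHCs
#'
#' Applies the standard epitope-database reading of T-cell assay
#' outcomes to a table of per-assay records: a (peptide, allele) pair
#' with at least one positive record (`"Positive"`, `"Positive-High"`,
#' `"Positive-Low"`; case-insensitive) is immunogenic; a pair whose
#' records are all negative (`"Negative"`) is non-immunogenic. Records
#' with an unknown outcome string are excluded with a warning, as are
#' pairs left without any usable record. Upstream filters (e.g. binding
#' < 500 nM, assay restrictions) are the caller's responsibility.
#'
#' @param table `data.frame` (or TSV path) with columns `peptide`,
#'   `allele`, `assay_outcome`.
#' @param positiveOutcomes,negativeOutcomes Outcome strings (lowercase)
#'   read as positive / negative; override to encode a source's rule
#'   set (e.g. `"dominant"`/`"subdominant"` vs `"negative"`).
#' @return `data.frame` with columns `peptide`, `allele`, `label`
#'   (`"immunogenic"` / `"non-immunogenic"`), one row per pair.
#' @export
classifyLabels <- function(table,
                           positiveOutcomes = c("positive", "positive-high",
                                                "positive-low"),
                           negativeOutcomes = "negative") {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "assay_outcome")
  if (!all(need %in% names(table)))
    stop("label table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  outcome <- tolower(trimws(table$assay_outcome))
  known <- outcome %in% c(positiveOutcomes, negativeOutcomes)
  if (any(!known)) {
    warning(sum(!known), " record(s) with unknown outcome excluded: ",
            paste(unique(table$assay_outcome[!known]), collapse = ", "),
            call. = FALSE)
  }
  tab <- table[known, , drop = FALSE]
  outcome <- outcome[known]
  if (!nrow(tab))
    return(data.frame(peptide = character(0), allele = character(0),
                      label = character(0)))
  keyf <- interaction(tab$peptide, tab$allele, drop = TRUE)
  pos <- tapply(outcome %in% positiveOutcomes, keyf, any)
  first <- !duplicated(keyf)
  data.frame(peptide = tab$peptide[first], allele = tab$allele[first],
             label = ifelse(pos[as.character(keyf[first])],
                            "immunogenic", "non-immunogenic"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the immunogenicity x self-overlap contingency table
#'
#' Marks each labeled peptide as self-overlapping iff at least one self
#' presented peptide is recognized as "the same" under the recognition
#' model, and assembles the 2x2 table (rows: immunogenic /
#' non-immunogenic; columns: self-overlapping / not overlapping) that
#' [chiSquare2x2()] tests.
#'
#' @param labeled `data.frame` with columns `peptide` and `label` (as
#'   from [classifyLabels()]).
#' @param selfPresented Self presented peptides ([PresentedSet-class],
#'   [PeptideSet-class] or character vector of 9mers).
#' @param model A [RecognitionModel-class].
#' @return Integer 2x2 matrix with dimnames.
#' @export
overlapTable <- function(labeled, selfPresented, model) {
  stopifnot(all(c("peptide", "label") %in% names(labeled)))
  assertPeptides9(labeled$peptide)
  classes <- c("immunogenic", "non-immunogenic")
  if (!all(classes %in% labeled$label))
    stop("empty label class: need both immunogenic and non-immunogenic ",
         "peptides", call. = FALSE)
  flags <- overlapFlags(labeled$peptide, .peptidesOf(selfPresented), model)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(classes, c("overlapping", "not_overlapping")))
  for (cl in classes) {
    f <- flags[labeled$label == cl]
    tab[cl, ] <- c(sum(f), sum(!f))
  }
  tab
}
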