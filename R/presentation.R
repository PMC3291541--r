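## MHC-I presentation: binding-model methods, threshold calibration and
## presented-set construction.

#' @describeIn predictIC50 position-weight motif model: IC50 =
#'   `exp(intercept + sum of per-position weights)`.
setMethod("predictIC50", "MotifBindingModel", function(model, peptides) {
  if (!length(peptides)) return(numeric(0))
  assertPeptides9(peptides)
  m <- peptideMatrix(peptides, 9L)
  e <- model@intercept
  w <- model@weights
  s <- rep(0, length(peptides))
  for (p in 1:9) s <- s + w[p, m[, p]]
  unname(exp(e + s))
})

#' @describeIn predictIC50 lookup model: errors on a peptide absent from
#'   the stored table.
setMethod("predictIC50", "TableBindingModel", function(model, peptides) {
  out <- model@scores[peptides]
  if (anyNA(out)) {
    missing <- peptides[is.na(out)]
    stop("no stored score for peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "", call. = FALSE)
  }
  unname(out)
})

#' @describeIn passesProcessing accepts every peptide.
setMethod("passesProcessing", "PassThroughProcessing",
          function(model, peptides) rep(TRUE, length(peptides)))

#' @describeIn passesProcessing C-terminal residue preference at or
#'   above the threshold.
setMethod("passesProcessing", "CTermCleavageModel",
          function(model, peptides) {
  if (!length(peptides)) return(logical(0))
  cterm <- substring(peptides, nchar(peptides), nchar(peptides))
  unname(model@preference[cterm] >= model@threshold)
})

#' Processing model constructors
#'
#' `passThroughProcessing()` accepts everything (the default).
#' `cTermCleavageModel()` is a toy C-terminal cleavage scorer: a
#' preference value per amino acid for the peptide's C-terminal residue,
#' passed iff at least `threshold`.
#'
#' @param preference Named numeric vector over the 20 amino acids.
#' @param threshold Numeric cutoff.
#' @return A [ProcessingModel-class].
#' @export
passThroughProcessing <- function() new("PassThroughProcessing")

#' @rdname passThroughProcessing
#' @export
cTermCleavageModel <- function(preference, threshold = 0.5) {
  stopifnot(all(aminoAcids() %in% names(preference)))
  new("CTermCleavageModel", preference = preference[aminoAcids()],
      threshold = threshold)
}

#' Threshold specifications
#'
#' `fixedThreshold()` is a universal IC50 cutoff (500 nM default, the
#' conventional binder threshold on HLA-A*0201); `scaledThreshold()`
#' requests per-allele calibration so that a target fraction of self
#' peptides is presented (0.023, HLA-A*0201's specificity at 500 nM).
#'
#' @param nM IC50 cutoff in nM.
#' @param targetSpecificity Target presented fraction of self in (0, 1].
#' @return A [ThresholdSpec-class].
#' @export
fixedThreshold <- function(nM = 500) {
  new("ThresholdSpec", mode = "fixed", fixedValue = nM,
      targetSpecificity = NA_real_)
}

#' @rdname fixedThreshold
#' @export
scaledThreshold <- function(targetSpecificity = 0.023) {
  new("ThresholdSpec", mode = "scaled", fixedValue = NA_real_,
      targetSpecificity = targetSpecificity)
}

#' Calibrate a scaled presentation threshold on self peptides
#'
#' Returns the empirical score quantile such that the achieved fraction
#' of self peptides scoring at or below it is the largest value not
#' exceeding `target + 1/N`. Ties at the threshold are included (the
#' comparison is inclusive throughout), so the achieved specificity is
#' reported rather than forced to the target.
#'
#' @param model A [BindingModel-class].
#' @param selfPeptides Non-empty character vector of self 9mers.
#' @param targetSpecificity Target presented fraction of self.
#' @return List with `threshold` (nM), `achievedSpecificity` and `n`.
#' @export
calibrateScaledThreshold <- function(model, selfPeptides,
                                     targetSpecificity = 0.023) {
  if (!length(selfPeptides)) stop("selfPeptides is empty", call. = FALSE)
  stopifnot(targetSpecificity > 0, targetSpecificity <= 1)
  scores <- predictIC50(model, selfPeptides)
  if (diff(range(scores)) == 0)
    stop("degenerate score distribution (all scores equal); ",
         "use a fixed threshold instead", call. = FALSE)
  n <- length(scores)
  sorted <- sort(scores)
  k <- max(1L, floor(targetSpecificity * n))
  repeat {
    thr <- sorted[k]
    achieved <- mean(scores <= thr)
    if (achieved <= targetSpecificity + 1 / n || k == 1L) break
    # ties pushed the achieved fraction too high; back off
    k <- sum(sorted < thr)
    if (k == 0L) {
      k <- 1L
      thr <- sorted[1L]
      achieved <- mean(scores <= thr)
      break
    }
  }
  list(threshold = thr, achievedSpecificity = achieved, n = n)
}

#' Predict the presented peptide set of an allele
#'
#' Filters unique 9mers to those with predicted IC50 at or below the
#' threshold (inclusive) that also pass the processing model. With a
#' scaled [ThresholdSpec-class], the threshold is first calibrated on
#' `selfPeptides`.
#'
#' @param model A [BindingModel-class].
#' @param peptideSet A [PeptideSet-class] or character vector of 9mers.
#' @param threshold A [ThresholdSpec-class] or a numeric IC50 cutoff
#'   in nM.
#' @param processing A [ProcessingModel-class] (default pass-through).
#' @param selfPeptides Self 9mers, required for scaled calibration.
#' @return A [PresentedSet-class].
#' @export
presentedSet <- function(model, peptideSet, threshold = fixedThreshold(),
                         processing = passThroughProcessing(),
                         selfPeptides = NULL) {
  if (is(peptideSet, "PeptideSet")) {
    pep <- peptideSet@peptides
    sid <- peptideSet@speciesId
    kg <- peptideSet@kingdom
  } else {
    pep <- unique(as.character(peptideSet))
    sid <- "unknown"
    kg <- "self"
  }
  assertPeptides9(pep)
  if (is.numeric(threshold)) {
    thr <- threshold
  } else if (is(threshold, "ThresholdSpec")) {
    thr <- if (threshold@mode == "fixed") {
      threshold@fixedValue
    } else {
      if (is.null(selfPeptides))
        stop("scaled threshold needs selfPeptides for calibration",
             call. = FALSE)
      calibrateScaledThreshold(model, selfPeptides,
                               threshold@targetSpecificity)$threshold
    }
  } else {
    stop("threshold must be numeric or a ThresholdSpec", call. = FALSE)
  }
  keep <- logical(length(pep))
  if (length(pep)) {
    keep <- predictIC50(model, pep) <= thr & passesProcessing(processing, pep)
  }
  new("PresentedSet", alleleName = model@alleleName, threshold = thr,
      peptides = pep[keep], speciesId = sid, kingdom = kg)
}

#' Import a NetMHC-style score table as a binding model
#'
#' Reads a TSV with columns `peptide`, `allele`, `ic50_nm` (as produced
#' by tabulating an external predictor's output) into a lookup-backed
#' [TableBindingModel-class]. Duplicate (peptide, allele) rows with
#' conflicting scores are an error; consistent duplicates collapse.
#'
#' @param path TSV file.
#' @param allele Allele to select; default: the single allele present.
#' @return A [TableBindingModel-class].
#' @seealso [writeScoreTable()]
#' @export
importScoreTable <- function(path, allele = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "ic50_nm")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(allele)) {
    alleles <- unique(tab$allele)
    if (length(alleles) != 1L)
      stop("table holds several alleles; pick one of: ",
           paste(alleles, collapse = ", "), call. = FALSE)
    allele <- alleles
  }
  tab <- tab[tab$allele == allele, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for allele ", allele, call. = FALSE)
  dup <- duplicated(tab$peptide)
  if (any(dup)) {
    chk <- tapply(tab$ic50_nm, tab$peptide, function(x) diff(range(x)) > 0)
    if (any(chk))
      stop("conflicting duplicate scores for: ",
           paste(names(chk)[chk], collapse = ", "), call. = FALSE)
    tab <- tab[!dup, , drop = FALSE]
  }
  new("TableBindingModel", alleleName = allele,
      scores = stats::setNames(tab$ic50_nm, tab$peptide))
}

#' @rdname importScoreTable
#' @param model A [BindingModel-class] to tabulate.
#' @param peptidesChr Peptides to score and store.
#' @export
writeScoreTable <- function(model, peptidesChr, path) {
  tab <- data.frame(peptide = peptidesChr,
                    allele = model@alleleName,
                    ic50_nm = predictIC50(model, peptidesChr))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
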