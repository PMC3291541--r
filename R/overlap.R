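## Self/nonself overlap enumeration: key-index overlap fractions, the
## peptide-length scan with shuffled controls, and per-protein species
## counts.

## Coerce input to a list of PeptideSet
.asPeptideSets <- function(x) {
  if (is(x, "PeptideSet") || is(x, "PresentedSet")) return(list(x))
  if (is.character(x)) {
    return(list(new("PeptideSet", k = nchar(x[1]), peptides = unique(x),
                    speciesId = "unknown", kingdom = "virus")))
  }
  stopifnot(is.list(x))
  x
}

.peptidesOf <- function(x) {
  if (is(x, "PeptideSet") || is(x, "PresentedSet")) peptides(x)
  else unique(as.character(x))
}

## Flag, for each nonself peptide, whether >= 1 self peptide is
## recognized as the same under the model (key-index lookup).
overlapFlags <- function(nonselfPeptides, selfPeptides, model) {
  if (!length(nonselfPeptides)) return(logical(0))
  selfProj <- unique(projectPeptides(selfPeptides, model))
  degenerate <- length(model@regions) > 0L &&
    any(vapply(model@regions, function(r) r$budget, integer(1)) > 0L) &&
    any(lengths(model@rule@similar) > 0L)
  if (!degenerate) {
    return(projectPeptides(nonselfPeptides, model) %in% selfProj)
  }
  vapply(nonselfPeptides, function(p)
    any(recognizedKeys(p, model) %in% selfProj), logical(1),
    USE.NAMES = FALSE)
}

#' Self/nonself overlap fraction under a recognition model
#'
#' A nonself peptide counts as overlapping iff at least one self peptide
#' is recognized as "the same" under the model (exact models: equality
#' of the recognized-position projection; degenerate models: membership
#' of any recognition key in the self projection index). Fractions are
#' pooled per kingdom (total overlaps / total unique nonself peptides in
#' the kingdom) and the kingdom average is the unweighted mean of the
#' viral and bacterial pooled fractions.
#'
#' @param nonselfSets List of [PeptideSet-class]/[PresentedSet-class]
#'   (or a single one, or a character vector).
#' @param selfSet Self peptides ([PeptideSet-class],
#'   [PresentedSet-class] or character vector).
#' @param model A [RecognitionModel-class].
#' @param allele Label recorded in the result (`"no-MHC"` for raw
#'   proteome overlaps).
#' @return An [OverlapResult-class].
#' @export
overlapFraction <- function(nonselfSets, selfSet, model, allele = "no-MHC") {
  stopifnot(is(model, "RecognitionModel"))
  nonselfSets <- .asPeptideSets(nonselfSets)
  selfPeptides <- .peptidesOf(selfSet)
  if (!length(selfPeptides)) {
    warning("empty self set: all overlap fractions are 0", call. = FALSE)
  }
  rows <- lapply(nonselfSets, function(s) {
    pep <- .peptidesOf(s)
    nOv <- if (length(selfPeptides))
      sum(overlapFlags(pep, selfPeptides, model)) else 0L
    data.frame(speciesId = if (is.character(s)) "unknown" else speciesId(s),
               kingdom = if (is.character(s)) "virus" else kingdom(s),
               nPeptides = length(pep), nOverlap = nOv,
               fraction = if (length(pep)) nOv / length(pep) else NA_real_,
               stringsAsFactors = FALSE)
  })
  perSpecies <- do.call(rbind, rows)
  pooled <- vapply(split(perSpecies, perSpecies$kingdom), function(d) {
    if (sum(d$nPeptides) == 0L) NA_real_ else
      sum(d$nOverlap) / sum(d$nPeptides)
  }, numeric(1))
  kavg <- mean(pooled[names(pooled) %in% c("virus", "bacterium")],
               na.rm = TRUE)
  if (!is.finite(kavg)) kavg <- mean(pooled, na.rm = TRUE)
  new("OverlapResult", allele = allele, model = describeModel(model),
      perSpecies = perSpecies, pooled = pooled, kingdomAverage = kavg)
}

describeModel <- function(model) {
  fmt <- function(p) paste0("P", p, collapse = "")
  degenerate <- any(vapply(model@regions, function(r) r$budget,
                           integer(1)) > 0L)
  sprintf("%s[%s]", if (degenerate) "degenerate" else "exact",
          fmt(model@recognizedPositions))
}

#' Overlap of nonself k-mers with self across peptide lengths
#'
#' For each `k`, the fraction of each kingdom's unique nonself k-mers
#' that occur verbatim in the self proteome (full-length exact match, no
#' MHC presentation), pooled per kingdom; optionally the same fractions
#' after within-protein shuffling of the nonself sequences (the control
#' that destroys homology while conserving composition). Kingdoms whose
#' proteins are all shorter than `k` are reported as absent (no row).
#'
#' @param self A [ProteomeSet-class] (the host).
#' @param nonself List of nonself [ProteomeSet-class].
#' @param kRange Integer vector of peptide lengths (subset of 1..20).
#' @param shuffled Also compute shuffled-control fractions?
#' @param seed Seed for the shuffle.
#' @return `data.frame` with columns `k`, `kingdom`, `shuffled`,
#'   `nPeptides`, `nOverlap`, `fraction`.
#' @export
lengthScan <- function(self, nonself, kRange = 1:12, shuffled = TRUE,
                       seed = NULL) {
  stopifnot(is(self, "ProteomeSet"), all(kRange >= 1L), all(kRange <= 20L))
  nonself <- if (is(nonself, "ProteomeSet")) list(nonself) else nonself
  shuf <- if (shuffled) {
    seeds <- withSeed(seed, sample.int(.Machine$integer.max %/% 2L,
                                       length(nonself)))
    lapply(seq_along(nonself), function(i)
      shuffleRecords(nonself[[i]], seed = seeds[i]))
  }
  out <- list()
  for (k in sort(unique(as.integer(kRange)))) {
    selfSet <- peptides(extractKmers(self, k))
    scan1 <- function(protList, isShuffled) {
      sets <- lapply(protList, extractKmers, k = k)
      byKing <- split(sets, vapply(sets, kingdom, character(1)))
      for (kg in names(byKing)) {
        npep <- sum(vapply(byKing[[kg]], function(s)
          length(peptides(s)), integer(1)))
        if (npep == 0L) next  # undefined denominator: entry absent
        nov <- sum(vapply(byKing[[kg]], function(s)
          sum(peptides(s) %in% selfSet), integer(1)))
        out[[length(out) + 1L]] <<- data.frame(
          k = k, kingdom = kg, shuffled = isShuffled,
          nPeptides = npep, nOverlap = nov, fraction = nov / npep,
          stringsAsFactors = FALSE)
      }
    }
    scan1(nonself, FALSE)
    if (shuffled) scan1(shuf, TRUE)
  }
  if (!length(out)) {
    return(data.frame(k = integer(0), kingdom = character(0),
                      shuffled = logical(0), nPeptides = integer(0),
                      nOverlap = integer(0), fraction = numeric(0)))
  }
  do.call(rbind, out)
}

#' Count, per self protein, the pathogen species sharing a 9mer
#'
#' For each self protein, the number of distinct nonself species whose
#' unique k-mer set intersects the protein's k-mer set.
#'
#' @param self A [ProteomeSet-class].
#' @param nonself List of nonself [ProteomeSet-class].
#' @param k Peptide length (default 9).
#' @return `data.frame` with columns `protein`, `length`, `nSpecies`.
#' @export
perProteinSpeciesCounts <- function(self, nonself, k = 9L) {
  stopifnot(is(self, "ProteomeSet"))
  nonself <- if (is(nonself, "ProteomeSet")) list(nonself) else nonself
  seqs <- as.character(self@records)
  protKmers <- lapply(seqs, function(s) unique(kmerWindows(s, k)))
  counts <- integer(length(seqs))
  for (sp in nonself) {
    spSet <- peptides(extractKmers(sp, k))
    hit <- vapply(protKmers, function(km)
      length(km) > 0L && any(km %in% spSet), logical(1))
    counts <- counts + hit
  }
  data.frame(protein = names(seqs), length = nchar(seqs),
             nSpecies = counts, stringsAsFactors = FALSE)
}

#' Uniform subsample of a proteome's proteins
#'
#' Supports overlap analyses against a randomly chosen fraction of the
#' self proteome (e.g. 50%).
#'
#' @param x A [ProteomeSet-class].
#' @param fraction Fraction of proteins to keep, in (0, 1].
#' @param seed Seed.
#' @return A [ProteomeSet-class].
#' @export
subsampleProteome <- function(x, fraction = 0.5, seed = NULL) {
  stopifnot(is(x, "ProteomeSet"), fraction > 0, fraction <= 1)
  n <- length(x@records)
  keep <- withSeed(seed, sort(sample.int(n, max(1L, round(fraction * n)))))
  new("ProteomeSet", records = x@records[keep],
      speciesId = x@speciesId, kingdom = x@kingdom)
}
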