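## Cross-reactivity footprint of a single T-cell: closed-form and
## exhaustive recognized-variant counts and the population average.

## Sum over t = 0..budget of the elementary symmetric polynomial e_t of
## s (the per-position similar-set sizes): the number of ways to place
## at most `budget` substitutions in one region.
.regionFactor <- function(s, budget) {
  # coefficients of prod(1 + s_i x), truncated at x^budget
  coefs <- 1
  for (si in s) coefs <- c(coefs, 0) + c(0, coefs * si)
  sum(coefs[seq_len(min(budget, length(s)) + 1L)])
}

#' Recognized-variant count of one peptide (closed form)
#'
#' For a peptide's residues at the model's recognized positions, the
#' number of *other* residue combinations at those positions that the
#' same T-cell would recognize. With per-region mismatch budget 1 this
#' is `prod_regions(1 + sum_i s_i) - 1` where `s_i` is the similar-set
#' size of the residue at position i; general budgets use the truncated
#' elementary-symmetric expansion. Fixed positions contribute factor 1.
#'
#' @param residues Character vector (or single string) of the residues
#'   at the model's recognized positions, in order; a full 9mer is also
#'   accepted and projected.
#' @param model A [RecognitionModel-class].
#' @return Integer count of other recognized combinations.
#' @seealso [exhaustiveVariantCount()] for the brute-force check,
#'   [averageFootprint()] for the population mean.
#' @export
recognizedVariantCount <- function(residues, model) {
  stopifnot(is(model, "RecognitionModel"))
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  rp <- model@recognizedPositions
  if (length(residues) == 9L && length(rp) != 9L) residues <- residues[rp]
  if (length(residues) != length(rp))
    stop("residues must cover the model's recognized positions",
         call. = FALSE)
  sim <- model@rule@similar
  total <- 1
  for (r in model@regions) {
    idx <- match(r$positions, rp)
    s <- lengths(sim[residues[idx]])
    total <- total * .regionFactor(s, r$budget)
  }
  as.integer(round(total - 1))
}

#' Recognized-variant count by exhaustive enumeration
#'
#' Independent brute-force oracle for [recognizedVariantCount()]: scans
#' every combination of `alphabet` residues at the model's non-fixed
#' recognized positions and counts those recognized via
#' [isRecognized()]-style rule evaluation. Exponential in the number of
#' free positions; intended for reduced alphabets.
#'
#' @param residues Residues at the recognized positions (as in
#'   [recognizedVariantCount()]).
#' @param model A [RecognitionModel-class].
#' @param alphabet Alphabet to enumerate over.
#' @return Integer count of other recognized combinations.
#' @export
exhaustiveVariantCount <- function(residues, model,
                                   alphabet = aminoAcids()) {
  stopifnot(is(model, "RecognitionModel"))
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  rp <- model@recognizedPositions
  stopifnot(length(residues) == length(rp))
  free <- setdiff(rp, model@fixedPositions)
  freeIdx <- match(free, rp)
  grids <- rep(list(alphabet), length(freeIdx))
  combos <- as.matrix(expand.grid(grids, stringsAsFactors = FALSE))
  sim <- model@rule@similar
  count <- 0L
  for (i in seq_len(nrow(combos))) {
    cand <- residues
    cand[freeIdx] <- combos[i, ]
    if (identical(cand, residues)) next
    ok <- TRUE
    for (r in model@regions) {
      idx <- match(r$positions, rp)
      mism <- which(cand[idx] != residues[idx])
      if (length(mism) > r$budget) { ok <- FALSE; break }
      for (j in mism) {
        if (!cand[idx[j]] %in% sim[[residues[idx[j]]]]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) count <- count + 1L
  }
  count
}

#' Population-average recognition footprint
#'
#' Expected recognized-variant count over uniform, independent residues
#' at the recognized positions, computed analytically: each region
#' contributes `sum_t C(n_r, t) * sbar^t` for `t = 0..budget` (the
#' expectation of the truncated elementary-symmetric expansion under
#' i.i.d. residues), where `sbar` is the mean similar-set size over the
#' alphabet; the mean *other*-combination count is the product over
#' regions minus 1. The reciprocal cross-reactivity is reported as
#' `alphabetSize^m / meanOtherCount` with `m` the number of recognized
#' positions (the "1 in N" form); the inclusive variant
#' (`meanOtherCount + 1` in the denominator) is reported alongside.
#'
#' @param model A [RecognitionModel-class].
#' @param alphabetSize Alphabet size (20 for the canonical amino acids).
#' @return List with `meanOtherCount`, `meanRecognizedCount`
#'   (= other + 1), `reciprocal` and `reciprocalInclusive`.
#' @export
#' @examples
#' m <- degenerateModel(emptySimilarityRule())
#' averageFootprint(m)$reciprocal   # 20^6: each T-cell sees only itself
averageFootprint <- function(model, alphabetSize = 20) {
  stopifnot(is(model, "RecognitionModel"))
  sizes <- lengths(model@rule@similar)
  if (length(sizes) != alphabetSize)
    stop("similarity rule must be defined on the full alphabet (",
         alphabetSize, " letters)", call. = FALSE)
  sbar <- mean(sizes)
  total <- 1
  for (r in model@regions) {
    nr <- length(r$positions)
    b <- min(r$budget, nr)
    total <- total * sum(choose(nr, 0:b) * sbar^(0:b))
  }
  meanOther <- total - 1
  space <- alphabetSize^length(model@recognizedPositions)
  list(meanOtherCount = meanOther,
       meanRecognizedCount = meanOther + 1,
       reciprocal = if (meanOther > 0) space / meanOther else space,
       reciprocalInclusive = space / (meanOther + 1))
}

#' Monte-Carlo recognition footprint
#'
#' Estimates the mean other-combination count by averaging
#' [recognizedVariantCount()] over uniform random draws of residues at
#' the recognized positions. Serves as a stochastic cross-check of
#' [averageFootprint()].
#'
#' @param model A [RecognitionModel-class].
#' @param nDraws Number of random draws.
#' @param alphabet Alphabet to draw from.
#' @param seed Seed.
#' @return List with `mean`, `se` (standard error) and `nDraws`.
#' @export
monteCarloFootprint <- function(model, nDraws = 1e4,
                                alphabet = aminoAcids(), seed = NULL) {
  rp <- model@recognizedPositions
  counts <- withSeed(seed, {
    vapply(seq_len(nDraws), function(i) {
      recognizedVariantCount(sample(alphabet, length(rp), replace = TRUE),
                             model)
    }, integer(1))
  })
  list(mean = mean(counts), se = stats::sd(counts) / sqrt(nDraws),
       nDraws = nDraws)
}
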