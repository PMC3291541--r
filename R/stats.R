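## Statistical procedures: 2x2 chi-square, permutation enrichment test,
## per-position Shannon entropy, additional-anchor selectivity, least
## specific positions, Spearman rank correlation.

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square for a 2x2 table (rows: immunogenic /
#' non-immunogenic; columns: self-overlapping / not overlapping), by the
#' closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' p-value from the chi-square distribution with 1 df. The continuity
#' correction is off by default; Yates' correction is available behind
#' the flag.
#'
#' @param table 2x2 numeric matrix, or the count `a` with `b`, `c`, `d`
#'   given separately (row-major: a,b = first row).
#' @param b,c,d Optional counts when `table` is scalar `a`.
#' @param correct Apply Yates' continuity correction?
#' @return List with `statistic`, `p.value` and `table`.
#' @export
#' @examples
#' chiSquare2x2(4, 29, 18, 36)$p.value   # ~0.027
chiSquare2x2 <- function(table, b = NULL, c = NULL, d = NULL,
                         correct = FALSE) {
  if (!is.null(b)) table <- matrix(c(table, b, c, d), 2L, 2L, byrow = TRUE)
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  n <- sum(table)
  if (n <= 0) stop("table total must be positive", call. = FALSE)
  rowS <- rowSums(table)
  colS <- colSums(table)
  margins <- c("row 1 (immunogenic)" = rowS[1], "row 2 (non-immunogenic)" = rowS[2],
               "column 1 (overlapping)" = colS[1], "column 2 (not overlapping)" = colS[2])
  if (any(margins == 0))
    stop("degenerate margin with zero total: ",
         paste(names(margins)[margins == 0], collapse = ", "),
         call. = FALSE)
  a <- table[1, 1]; bb <- table[1, 2]; cc <- table[2, 1]; dd <- table[2, 2]
  delta <- abs(a * dd - bb * cc)
  if (correct) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / prod(rowS, colS)
  list(statistic = unname(stat),
       p.value = stats::pchisq(unname(stat), df = 1L, lower.tail = FALSE),
       table = table)
}

#' Permutation test for proteins with excess cross-species overlap
#'
#' Identifies self proteins whose number of overlapping pathogen species
#' exceeds the length-adjusted expectation. The global per-residue rate
#' is `lambda = sum(counts) / sum(lengths)`; the null draws, for protein
#' i, `Binomial(nSpecies, p_i)` counts with
#' `p_i = min(1, lambda * length_i / nSpecies)` in each of `nPerm`
#' permutations. A protein is flagged iff its observed count is strictly
#' greater than all `nPerm` draws (empirical p < 1/(nPerm+1)).
#'
#' @param counts Observed per-protein species counts (e.g. the
#'   `nSpecies` column of [perProteinSpeciesCounts()]).
#' @param lengths Protein lengths (same order).
#' @param nSpecies Number of species tested.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Seed.
#' @return `data.frame` with columns `observed`, `length`, `expected`,
#'   `maxPermuted`, `flagged`.
#' @export
permutationEnrichment <- function(counts, lengths, nSpecies,
                                  nPerm = 1000L, seed = NULL) {
  stopifnot(length(counts) == length(lengths), nPerm >= 1L, nSpecies >= 1L)
  total <- sum(counts)
  lambda <- if (sum(lengths) > 0) total / sum(lengths) else 0
  p <- pmin(1, lambda * lengths / nSpecies)
  maxPermuted <- withSeed(seed, {
    vapply(p, function(pi) {
      if (total == 0) return(Inf)  # nothing can be flagged
      max(stats::rbinom(nPerm, nSpecies, pi))
    }, numeric(1))
  })
  data.frame(observed = counts, length = lengths,
             expected = p * nSpecies, maxPermuted = maxPermuted,
             flagged = counts > maxPermuted)
}

#' Per-position Shannon entropy of a peptide set
#'
#' Entropy in bits of the residue frequencies at each position P1..P9 of
#' a set of presented peptides: `H = -sum f log2 f`. Ranges from 0 (all
#' peptides share one residue; a strict anchor) to `log2(20) ~ 4.32`
#' (uniform usage). Used as the per-position selectivity measure of an
#' allele.
#'
#' @param peptideSetOrChr A [PresentedSet-class], [PeptideSet-class] or
#'   character vector of 9mers (non-empty).
#' @return Named numeric vector `P1..P9` of entropies in bits.
#' @export
positionEntropy <- function(peptideSetOrChr) {
  pep <- .peptidesOf(peptideSetOrChr)
  if (!length(pep)) stop("empty peptide set", call. = FALSE)
  assertPeptides9(pep)
  m <- peptideMatrix(pep, 9L)
  H <- apply(m, 2L, function(col) {
    f <- table(col) / length(col)
    -sum(f * log2(f))
  })
  stats::setNames(H, paste0("P", 1:9))
}

#' Additional-anchor selectivity of an allele
#'
#' An allele has "additional anchors" when its presented peptides are
#' selective at positions beyond the classical anchors (P2, P9). The
#' per-position selectivity is the information content
#' `log2(20) - H` by default; the flag is raised when the summed
#' selectivity at the non-anchor positions (P1, P3-P8) exceeds
#' `threshold` (25%) of the summed selectivity over all nine positions.
#' The literal-entropy mode (`mode = "entropy"`, summing raw entropy as
#' the selectivity measure) is provided for comparison, but high entropy
#' means *low* selectivity, so the information-content reading is the
#' default.
#'
#' @param entropy Named 9-position entropy profile (bits), as returned
#'   by [positionEntropy()].
#' @param anchorPositions Classical anchor positions (default P2, P9).
#' @param threshold Flagging fraction (default 0.25).
#' @param mode `"information"` (default) or `"entropy"`.
#' @return List with `selectivityScore` (non-anchor sum),
#'   `totalSelectivity` (all-position sum) and `hasAdditionalAnchors`.
#' @export
additionalAnchorAssessment <- function(entropy,
                                       anchorPositions = c(2L, 9L),
                                       threshold = 0.25,
                                       mode = c("information", "entropy")) {
  mode <- match.arg(mode)
  stopifnot(length(entropy) == 9L)
  sel <- switch(mode, information = log2(20) - entropy, entropy = entropy)
  nonAnchor <- setdiff(1:9, anchorPositions)
  score <- sum(sel[nonAnchor])
  total <- sum(sel)
  list(selectivityScore = unname(score),
       totalSelectivity = unname(total),
       hasAdditionalAnchors = unname(score > threshold * total))
}

#' The n least specific peptide positions of an allele
#'
#' The `n` positions with the highest entropy (lowest selectivity) in an
#' allele's 9-position profile; ties are broken by position order. Used
#' by the allele-specific recognition model variant, which reads the six
#' least specific positions instead of the fixed P3-P8 window.
#'
#' @param entropy Named 9-position entropy profile (bits).
#' @param n Number of positions to return.
#' @return Sorted integer vector of positions.
#' @export
#' @examples
#' leastSpecificPositions(rep(4, 9))   # flat: P1..P6 by tie-break
leastSpecificPositions <- function(entropy, n = 6L) {
  stopifnot(length(entropy) == 9L, n >= 1L, n <= 9L)
  sort(order(-unname(entropy), seq_len(9L))[seq_len(n)])
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-aware Spearman rho (Pearson correlation of midranks) with the
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p.value`.
#' @export
spearmanRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p.value = p)
}
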