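## Shared fixtures and independent oracles for the test suite.

AA20 <- aminoAcids()

## Biostrings BLOSUM matrices as SubstitutionMatrix objects
loadBlosum <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  substitutionMatrix(get(name, envir = e), name)
}

## Rule in which every residue has exactly one similar partner
## (10 disjoint pairs over the alphabet)
onePartnerRule <- function() {
  similarityRule(stats::setNames(as.list(AA20[seq(2, 20, 2)]),
                                 AA20[seq(1, 20, 2)]),
                 provenance = "one-partner")
}

## The synthetic covariance-regime rule used throughout (mean
## similar-set size targeted at the measured-covariance regime)
regimeRule <- function(seed = 421L, target = 1.63) {
  buildSimilarityRule(makeSimilarityMatrix(target, seed = seed),
                      "abs_covariance_gt", 0.05)
}

## Independent O(n^2) oracle for degenerate-overlap flags: an all-pairs
## matrix scan over the model's regions, sharing no code with the
## key-index path.
bruteOverlapFlags <- function(nonself, self, model) {
  rule <- similarSets(model@rule)
  allowed <- matrix(FALSE, 20, 20, dimnames = list(AA20, AA20))
  for (a in names(rule)) allowed[a, rule[[a]]] <- TRUE
  sm <- do.call(rbind, strsplit(self, ""))
  nm <- do.call(rbind, strsplit(nonself, ""))
  fp <- model@fixedPositions
  vapply(seq_along(nonself), function(i) {
    ok <- rep(TRUE, length(self))
    if (length(fp)) {
      for (p in fp) ok <- ok & sm[, p] == nm[i, p]
    }
    for (r in model@regions) {
      p <- r$positions
      mism <- sm[, p, drop = FALSE] != matrix(nm[i, p], nrow(sm),
                                              length(p), byrow = TRUE)
      ok <- ok & rowSums(mism) <= r$budget
      # every mismatching pair must be an allowed substitution
      # (direction: nonself residue -> self residue)
      allow <- matrix(allowed[cbind(as.vector(
        matrix(nm[i, p], nrow(sm), length(p), byrow = TRUE)),
        as.vector(sm[, p, drop = FALSE]))], nrow(sm))
      ok <- ok & rowSums(mism & !allow) == 0L
    }
    any(ok)
  }, logical(1))
}

## a peptide set in which every residue appears equally often at every
## position (exactly uniform per-position frequencies)
uniformPositionPeptides <- function() {
  vapply(0:19, function(i)
    paste(AA20[(i + 0:8) %% 20 + 1], collapse = ""), character(1))
}
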