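test_that("2x2 chi-square matches the closed form and base R on random tables", {
  set.seed(111L)
  for (i in 1:100) {
    tab <- matrix(stats::rpois(4L, 20) + 1L, 2L, 2L)
    got <- chiSquare2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value)
    expect_gt(got$p.value, 0)
    expect_lte(got$p.value, 1)
    gotY <- chiSquare2x2(tab, correct = TRUE)
    refY <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(gotY$statistic, unname(refY$statistic))
  }
  # no association: ad = bc
  expect_equal(chiSquare2x2(10, 20, 30, 60)$statistic, 0)
  expect_equal(chiSquare2x2(10, 20, 30, 60)$p.value, 1)
  # degenerate margin named in the error
  expect_error(chiSquare2x2(0, 0, 5, 5), "row 1")
  expect_error(chiSquare2x2(0, 5, 0, 5), "column 1")
})

test_that("permutation enrichment flags planted excess, never zero counts", {
  nSpecies <- 50L
  set.seed(112L)
  lengths <- sample(100:1000, 300L, replace = TRUE)
  lambda <- 0.003
  counts <- stats::rbinom(300L, nSpecies, pmin(1, lambda * lengths / nSpecies))
  counts[1L] <- 0L
  lengths[2L] <- 1000L
  counts[2L] <- round(10 * lambda * lengths[2L])  # planted 10x protein
  res <- permutationEnrichment(counts, lengths, nSpecies, nPerm = 1000L,
                               seed = 113L)
  expect_false(res$flagged[1L])   # observed 0 can never exceed draws
  expect_true(res$flagged[2L])    # planted enrichment recovered
  # zero totals flag nothing
  res0 <- permutationEnrichment(rep(0L, 10L), lengths[1:10], nSpecies,
                                nPerm = 100L, seed = 114L)
  expect_false(any(res0$flagged))
})

test_that("permutation enrichment flags are stable under doubling length and count", {
  nSpecies <- 40L
  set.seed(115L)
  lengths <- sample(200:800, 200L, replace = TRUE)
  counts <- stats::rbinom(200L, nSpecies, pmin(1, 0.002 * lengths / nSpecies))
  counts[5L] <- counts[5L] + 15L  # clearly enriched
  r1 <- permutationEnrichment(counts, lengths, nSpecies, seed = 116L)
  r2 <- permutationEnrichment(2L * counts, 2L * lengths, nSpecies,
                              seed = 116L)
  # the normalization keeps the planted protein flagged and the clear
  # nulls unflagged in both scalings
  expect_true(r1$flagged[5L] && r2$flagged[5L])
  clearNull <- counts <= stats::quantile(counts, 0.5)
  expect_false(any(r1$flagged[clearNull]))
  expect_false(any(r2$flagged[clearNull]))
})

test_that("position entropy attains its exact bounds", {
  # point mass at P2: zero bits
  pep <- paste0(AA20, "A", strrep("C", 7))
  H <- positionEntropy(pep)
  expect_equal(unname(H["P2"]), 0)
  # exactly uniform usage at every position: log2(20) bits
  Hu <- positionEntropy(uniformPositionPeptides())
  expect_equal(unname(Hu), rep(log2(20), 9L))
  expect_true(all(H >= 0 & H <= log2(20) + 1e-12))
})

test_that("planted anchors depress entropy at anchor positions", {
  al <- makeAllele("anchors", anchorPositions = c(2L, 9L),
                   anchorStrength = 2, seed = 117L)
  pep <- unique(randomPeptides(30000L, seed = 118L))
  pres <- presentedSet(al, pep, scaledThreshold(), selfPeptides = pep)
  H <- positionEntropy(peptides(pres))
  expect_lt(H["P2"], H["P6"])
  expect_lt(H["P9"], H["P6"])
  expect_lt(max(H["P2"], H["P9"]), min(H[paste0("P", c(1, 3:8))]))
})

test_that("additional-anchor assessment follows the 25% information rule", {
  # zero information everywhere
  flat <- stats::setNames(rep(log2(20), 9L), paste0("P", 1:9))
  a0 <- additionalAnchorAssessment(flat)
  expect_equal(a0$selectivityScore, 0)
  expect_false(a0$hasAdditionalAnchors)
  # information only at the classical anchors
  classic <- flat
  classic[c("P2", "P9")] <- 0
  expect_false(additionalAnchorAssessment(classic)$hasAdditionalAnchors)
  # planted atypical anchor at P5 carrying 40% of total information
  atypical <- flat
  atypical[c("P2", "P9")] <- log2(20) - 1.5
  atypical["P5"] <- log2(20) - 2      # 2 of 5 total bits at P5
  aa <- additionalAnchorAssessment(atypical)
  expect_true(aa$hasAdditionalAnchors)
  # literal-entropy mode mislabels even the classical-anchor profile
  # (high entropy = low selectivity), motivating the information default
  expect_true(additionalAnchorAssessment(classic,
                                         mode = "entropy")$hasAdditionalAnchors)
})

test_that("least specific positions use entropy order with positional tie-break", {
  flat <- stats::setNames(rep(2, 9L), paste0("P", 1:9))
  expect_identical(leastSpecificPositions(flat), 1:6)
  prof <- stats::setNames(c(4, 1, 4, 4, 1.5, 4, 4, 4, 0.5), paste0("P", 1:9))
  expect_identical(leastSpecificPositions(prof), c(1L, 3L, 4L, 6L, 7L, 8L))
  expect_identical(leastSpecificPositions(prof, n = 9L), 1:9)
})

test_that("Spearman correlation: exact values, ties, and recovery", {
  x <- 1:20
  expect_equal(spearmanRank(x, x^3)$rho, 1)
  expect_equal(spearmanRank(x, rev(x))$rho, -1)
  expect_error(spearmanRank(rep(1, 10), 1:10), "constant")
  # tie-aware rho agrees with base R
  set.seed(119L)
  a <- sample(1:5, 30L, replace = TRUE)
  b <- a + sample(0:2, 30L, replace = TRUE)
  expect_equal(spearmanRank(a, b)$rho,
               stats::cor(a, b, method = "spearman"))
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  expect_equal(spearmanRank(a, b)$p.value, ct$p.value, tolerance = 1e-10)
  # planted monotone relation with noise, 28 allele-sized samples:
  # mean rho over replicates within 3 SE of the large-sample value
  gen <- function(n) {
    x <- stats::rnorm(n)
    list(x = x, y = x + stats::rnorm(n, sd = 0.7))
  }
  big <- gen(100000L)
  target <- stats::cor(big$x, big$y, method = "spearman")
  rhos <- replicate(300L, {
    d <- gen(28L)
    spearmanRank(d$x, d$y)$rho
  })
  expect_lte(abs(mean(rhos) - target), 3 * stats::sd(rhos) / sqrt(300L) + 0.02)
})
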