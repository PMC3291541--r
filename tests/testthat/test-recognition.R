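test_that("similarity rules derive correctly from matrices", {
  # identity-like matrix: no off-diagonal signal, all sets empty
  idm <- substitutionMatrix(diag(20) |>
    (\(m) {dimnames(m) <- list(AA20, AA20); m})(), "identity")
  rule <- buildSimilarityRule(idm, "abs_covariance_gt", 0.05)
  expect_true(all(lengths(similarSets(rule)) == 0L))

  # single off-diagonal pair
  v <- diag(20) * 0
  dimnames(v) <- list(AA20, AA20)
  v["I", "L"] <- v["L", "I"] <- 0.2
  diag(v) <- 1
  rule <- buildSimilarityRule(substitutionMatrix(v, "pair"),
                              "abs_covariance_gt", 0.05)
  s <- similarSets(rule)
  expect_identical(s[["I"]], "L")
  expect_identical(s[["L"]], "I")
  expect_true(all(lengths(s[setdiff(AA20, c("I", "L"))]) == 0L))

  # negative covariance counts under the absolute rule, not the signed one
  v["D", "W"] <- v["W", "D"] <- -0.2
  expect_identical(
    similarSets(buildSimilarityRule(substitutionMatrix(v, "neg"),
                                    "abs_covariance_gt", 0.05))[["D"]], "W")
  expect_length(
    similarSets(buildSimilarityRule(substitutionMatrix(v, "neg"),
                                    "value_gt", 0.05))[["D"]], 0L)
})

test_that("BLOSUM62 positive-score rule matches a column scan and is symmetric", {
  bl62 <- loadBlosum("BLOSUM62")
  rule <- buildSimilarityRule(bl62, "positive_score")
  v <- matrixValues(bl62)
  s <- similarSets(rule)
  for (a in AA20) {
    # brute-force column scan oracle
    expect_setequal(s[[a]], setdiff(AA20[v[, a] > 0], a))
    for (b in s[[a]]) expect_true(a %in% s[[b]])
  }
})

test_that("matrix file round-trip preserves values", {
  m <- makeSimilarityMatrix(1.6, seed = 8L)
  f <- withr::local_tempfile(fileext = ".txt")
  writeSubstitutionMatrix(m, f)
  back <- readSubstitutionMatrix(f)
  expect_equal(matrixValues(back)[AA20, AA20], matrixValues(m)[AA20, AA20])
})

test_that("asymmetric matrices are rejected", {
  v <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  v["A", "C"] <- 1  # not mirrored
  expect_error(substitutionMatrix(v, "bad"), "symmetric")
})

test_that("isRecognized implements the region-budget mismatch rule", {
  rule <- onePartnerRule()
  dm <- degenerateModel(rule)
  # reflexive for every model
  peps <- randomPeptides(50L, seed = 1L)
  for (m in list(completeMatchModel(), middleMatchModel(),
                 nonAnchorMatchModel(), dm)) {
    expect_true(all(isRecognized(peps, peps, m)))
  }
  # unrecognized positions (P1, P2) are ignored by the middle models
  a <- "ACDEFGHIK"
  b1 <- "CDDEFGHIK"  # differs at P1 and P2 only
  expect_true(isRecognized(a, b1, dm))
  expect_true(isRecognized(a, b1, middleMatchModel()))
  expect_false(isRecognized(a, b1, completeMatchModel()))
  # two mismatches within one region exceed its budget of 1, even if
  # both substitutions are conservative (A~C, D~E in the pair rule)
  b2 <- "ACCFFGHIK"  # P3 D->C? construct explicitly below
  a <- "ACACDGHIK"   # P3=A, P4=C
  b2 <- "ACCADGHIK"  # P3 A->C (allowed), P4 C->A (allowed): 2 in region 1
  expect_false(isRecognized(a, b2, dm))
  # one conservative mismatch per region is allowed
  b3 <- "ACCCDGHIK"  # P3 A->C only
  expect_true(isRecognized(a, b3, dm))
  # non-conservative single mismatch is rejected
  b4 <- "ACWCDGHIK"  # P3 A->W, not similar under the pair rule
  expect_false(isRecognized(a, b4, dm))
  # fixed position P5 must match exactly
  b5 <- "ACACCGHIK"  # P5 D->C (even though similar)
  expect_false(isRecognized(a, b5, dm))
  expect_error(isRecognized("ACDE", a, dm), "9mer")
})

test_that("isRecognized is symmetric under a symmetric rule", {
  dm <- degenerateModel(regimeRule())
  a <- randomPeptides(1000L, seed = 11L)
  b <- vapply(a, function(p) {
    # mutate 0-2 middle positions so that recognitions actually occur
    ch <- strsplit(p, "")[[1L]]
    for (pos in sample(c(3, 4, 6, 7, 8), sample(0:2, 1))) {
      ch[pos] <- sample(AA20, 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  set.seed(12L)
  expect_identical(isRecognized(a, b, dm), isRecognized(b, a, dm))
  expect_gt(sum(isRecognized(a, b, dm)), 100L)  # informative sample
})

test_that("recognizedKeys enumerates exactly the recognized projections", {
  dm0 <- degenerateModel(emptySimilarityRule())
  expect_identical(recognizedKeys("ACDEFGHIK", dm0),
                   substring("ACDEFGHIK", 3L, 8L))
  # one partner each, default regions of sizes 2 and 3: (1+2)(1+3) keys
  dm1 <- degenerateModel(onePartnerRule())
  expect_length(recognizedKeys("ACDEFGHIK", dm1), 12L)
})

test_that("key count equals the closed form for random peptide/rule draws", {
  set.seed(21L)
  for (i in 1:25) {
    rule <- buildSimilarityRule(
      makeSimilarityMatrix(stats::runif(1, 0, 4), seed = 500L + i),
      "abs_covariance_gt", 0.05)
    model <- degenerateModel(rule)
    for (p in randomPeptides(40L, seed = 600L + i)) {
      expect_length(recognizedKeys(p, model),
                    recognizedVariantCount(p, model) + 1L)
    }
  }
})

test_that("key membership is equivalent to the pairwise predicate", {
  dm <- degenerateModel(regimeRule())
  a <- randomPeptides(500L, seed = 31L)
  b <- vapply(a, function(p) {
    ch <- strsplit(p, "")[[1L]]
    for (pos in sample(3:8, sample(0:2, 1))) ch[pos] <- sample(AA20, 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  set.seed(32L)
  viaKeys <- vapply(seq_along(a), function(i)
    projectPeptides(b[i], dm) %in% recognizedKeys(a[i], dm), logical(1))
  expect_identical(viaKeys, isRecognized(a, b, dm))
})

test_that("weaker models recognize supersets (nesting)", {
  ruleB <- regimeRule(seed = 41L, target = 1.2)
  # A: same pairs plus extras, and a laxer budget structure
  extra <- makeSimilarityMatrix(3.0, seed = 42L)
  sA <- similarSets(buildSimilarityRule(extra, "abs_covariance_gt", 0.05))
  sB <- similarSets(ruleB)
  ruleA <- similarityRule(mapply(union, sA, sB, SIMPLIFY = FALSE), "superset")
  mB <- degenerateModel(ruleB)
  mA <- adjacentMismatchModel(ruleA)   # single region, budget 2
  a <- randomPeptides(300L, seed = 43L)
  b <- vapply(a, function(p) {
    ch <- strsplit(p, "")[[1L]]
    for (pos in sample(3:8, sample(0:2, 1))) ch[pos] <- sample(AA20, 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  set.seed(44L)
  recB <- isRecognized(a, b, mB)
  recA <- isRecognized(a, b, mA)
  expect_true(all(recA[recB]))   # B-recognized implies A-recognized
})

test_that("peptide similarity score applies min-max scaling", {
  # worked single-position example: raw 3, min 1, max 11 -> 0.2
  v <- matrix(c(11, 3, 1,
                 3, 11, 0,
                 1, 0, 11), 3, 3,
              dimnames = list(c("A", "C", "D"), c("A", "C", "D")))
  m <- substitutionMatrix(v, "worked")
  expect_equal(peptideSimilarityScore("C", "A", m), 0.2)
  expect_equal(peptideSimilarityScore("A", "A", m), 1)

  bl50 <- loadBlosum("BLOSUM50")
  # identical peptides score 1 when the diagonal dominates every column
  p <- randomPeptides(20L, seed = 51L)
  for (q in p) expect_equal(peptideSimilarityScore(q, q, bl50), 1)

  # 100 random pairs: in [0,1] and equal to an explicit position-by-
  # position recomputation
  vm <- matrixValues(bl50)
  qs <- randomPeptides(100L, seed = 52L)
  rs <- randomPeptides(100L, seed = 53L)
  for (i in seq_len(100L)) {
    got <- peptideSimilarityScore(qs[i], rs[i], bl50)
    qc <- strsplit(qs[i], "")[[1L]]
    rc <- strsplit(rs[i], "")[[1L]]
    raw <- mn <- mx <- 0
    for (j in 1:9) {
      raw <- raw + vm[rc[j], qc[j]]
      mn <- mn + min(vm[rc[j], AA20])
      mx <- mx + max(vm[rc[j], AA20])
    }
    expect_equal(got, (raw - mn) / (mx - mn))
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
  # degenerate matrix: min == max
  flat <- matrix(1, 20, 20, dimnames = list(AA20, AA20))
  expect_error(peptideSimilarityScore("ACDEFGHIK", "ACDEFGHIK",
                                      substitutionMatrix(flat, "flat")),
               "degenerate")
})

test_that("allele-specific model anatomy mirrors the default around its fixed position", {
  H <- stats::setNames(c(4.1, 1.0, 4.2, 4.0, 2.0, 4.3, 4.2, 4.1, 0.9),
                       paste0("P", 1:9))
  pos <- leastSpecificPositions(H, 6L)
  expect_identical(pos, c(1L, 3L, 4L, 6L, 7L, 8L))
  m <- alleleSpecificModel(pos, H, onePartnerRule())
  # most specific recognized position (P4 has lowest H among pos? no: P1=4.1,
  # P3=4.2, P4=4.0, P6=4.3, P7=4.2, P8=4.1 -> P4) becomes the fixed one
  expect_identical(m@fixedPositions, 4L)
  expect_identical(sort(unlist(lapply(m@regions, `[[`, "positions"))),
                   c(1L, 3L, 6L, 7L, 8L))
})
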