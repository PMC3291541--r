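test_that("generators are bit-identical under a fixed seed", {
  p1 <- makeProteomes(nSelfProteins = 5L, nSpecies = 2L,
                      sharedKmerRate = 0.05, seed = 151L)
  p2 <- makeProteomes(nSelfProteins = 5L, nSpecies = 2L,
                      sharedKmerRate = 0.05, seed = 151L)
  expect_identical(as.character(proteinRecords(p1$self)),
                   as.character(proteinRecords(p2$self)))
  expect_identical(p1$truth, p2$truth)
  a1 <- makeAllele("d", seed = 152L)
  a2 <- makeAllele("d", seed = 152L)
  expect_identical(a1@weights, a2@weights)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  spec <- list(list(position = 4L, nResidues = 2L, distance = 4.2))
  makeToyStructure(spec, f1)
  makeToyStructure(spec, f2)
  expect_identical(readLines(f1), readLines(f2))
  # generators leave the caller's RNG stream untouched
  set.seed(153L)
  before <- .Random.seed
  invisible(makeProteomes(nSelfProteins = 2L, nSpecies = 1L, seed = 1L))
  expect_identical(.Random.seed, before)
})

test_that("planted shared-9mer segments carry the requested rate and truth", {
  prot <- makeProteomes(nSelfProteins = 20L, nSpecies = 3L,
                        proteinsPerSpecies = 5L, sharedKmerRate = 0.1,
                        seed = 154L)
  expect_identical(nrow(prot$truth), 15L)  # one segment per nonself protein
  # every planted window occurs in self (ground truth is verifiable)
  selfSet <- peptides(extractKmers(prot$self, 9L))
  for (r in seq_len(nrow(prot$truth))) {
    tr <- prot$truth[r, ]
    sp <- Filter(function(p) speciesId(p) == tr$speciesId, prot$nonself)[[1L]]
    seg <- substr(as.character(proteinRecords(sp))[[tr$protein]],
                  tr$start, tr$start + tr$segLength - 1L)
    segKmers <- substring(seg, 1:(nchar(seg) - 8L), 9:nchar(seg))
    expect_true(all(segKmers %in% selfSet))
  }
})

test_that("extreme planting rates hit their boundary behaviour", {
  # rate 0: overlap at chance level (effectively zero for 9mers)
  p0 <- makeProteomes(nSelfProteins = 10L, nSpecies = 2L,
                      proteinsPerSpecies = 5L, sharedKmerRate = 0,
                      seed = 155L)
  scan0 <- lengthScan(p0$self, p0$nonself, kRange = 9L, shuffled = FALSE)
  # analytic chance baseline: 1 - (1 - 20^-9)^Nself is ~ 2e-8
  expect_true(all(scan0$fraction <= 1e-3))
  # rate 1 with nonself shorter than self: every window is planted
  p1 <- makeProteomes(nSelfProteins = 5L, nSpecies = 1L,
                      proteinsPerSpecies = 3L, selfLength = 400L,
                      nonselfLength = 200L, sharedKmerRate = 1,
                      seed = 156L)
  scan1 <- lengthScan(p1$self, p1$nonself, kRange = 9L, shuffled = FALSE)
  expect_equal(scan1$fraction, 1)
  # unachievable rate errors
  expect_error(makeProteomes(nSelfProteins = 2L, nSpecies = 1L,
                             selfLength = 100L, nonselfLength = 200L,
                             sharedKmerRate = 1, seed = 1L),
               "longer than self")
  expect_error(makeProteomes(sharedKmerRate = 1.2, seed = 1L), "\\[0, 1\\]")
})

test_that("synthetic similarity matrices hit the requested rule density", {
  for (target in c(0, 1.63, 5, 19)) {
    m <- makeSimilarityMatrix(target, seed = 157L)
    rule <- buildSimilarityRule(m, "abs_covariance_gt", 0.05)
    expect_lte(abs(mean(lengths(similarSets(rule))) - target), 0.2)
  }
  # mean 0: empty rule, footprint reciprocal is the whole space
  m0 <- makeSimilarityMatrix(0, seed = 158L)
  r0 <- buildSimilarityRule(m0, "abs_covariance_gt", 0.05)
  expect_true(all(lengths(similarSets(r0)) == 0L))
  expect_equal(averageFootprint(degenerateModel(r0))$reciprocal, 20^6)
  # mean 19: complete graph
  r19 <- buildSimilarityRule(makeSimilarityMatrix(19, seed = 159L),
                             "abs_covariance_gt", 0.05)
  expect_true(all(lengths(similarSets(r19)) == 19L))
})

test_that("synthetic alleles express their planted anchor structure", {
  pep <- unique(randomPeptides(30000L, seed = 160L))
  # anchors P2/P9
  al <- makeAllele("classic", anchorPositions = c(2L, 9L), seed = 161L)
  H <- positionEntropy(peptides(presentedSet(al, pep, scaledThreshold(),
                                             selfPeptides = pep)))
  expect_lt(max(H[c("P2", "P9")]), min(H[paste0("P", c(1, 3:8))]))
  expect_false(additionalAnchorAssessment(H)$hasAdditionalAnchors)
  # added atypical anchor at P5 trips the 25% rule
  al3 <- makeAllele("atypical", anchorPositions = c(2L, 5L, 9L),
                    seed = 162L)
  H3 <- positionEntropy(peptides(presentedSet(al3, pep, scaledThreshold(),
                                              selfPeptides = pep)))
  expect_true(additionalAnchorAssessment(H3)$hasAdditionalAnchors)
  # no motif at all: scores are flat, so scaled calibration refuses and
  # a fixed threshold presents everything with near-maximal entropy
  al0 <- makeAllele("flat", anchorStrength = 0, baseSd = 0, seed = 163L)
  expect_error(calibrateScaledThreshold(al0, pep), "fixed")
  H0 <- positionEntropy(peptides(presentedSet(al0, pep, fixedThreshold(1e6))))
  expect_true(all(H0 > log2(20) - 0.02))
})

test_that("label generation respects its base-rate boundaries", {
  pep <- randomPeptides(200L, seed = 165L)
  lab0 <- makeImmunogenicityLabels(pep, rep(FALSE, 200L), baseRate = 0,
                                   oddsRatio = 3.5, seed = 166L)
  expect_true(all(lab0$label == "non-immunogenic"))
  lab1 <- makeImmunogenicityLabels(pep, rep(TRUE, 200L), baseRate = 1,
                                   oddsRatio = 2, seed = 167L)
  expect_true(all(lab1$label == "immunogenic"))
  expect_error(makeImmunogenicityLabels(pep, rep(TRUE, 200L),
                                        oddsRatio = -1), "oddsRatio")
})
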