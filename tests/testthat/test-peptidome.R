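test_that("FASTA round-trip preserves synthetic sequences", {
  prot <- makeProteomes(nSelfProteins = 5L, nSpecies = 1L,
                        proteinsPerSpecies = 3L, selfLength = 60L,
                        nonselfLength = 40L, seed = 101L)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeProteome(prot$self, f)
  back <- readProteome(f, kingdom = "self")
  expect_identical(as.character(proteinRecords(back)),
                   as.character(proteinRecords(prot$self)))
})

test_that("FASTA reader parses entries, errors on bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKVLATTPWLAG",
               ">p2", paste(rep("ACDEFGHIKL", 3), collapse = "")), f)
  ps <- readProteome(f, "toy", "virus")
  expect_s4_class(ps, "ProteomeSet")
  expect_identical(unname(Biostrings::width(proteinRecords(ps))),
                   c(12L, 30L))
  expect_identical(names(proteinRecords(ps)), c("p1", "p2"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(readProteome(empty), "empty|FASTA")
  expect_error(readProteome(tempfile()), "not found")
})

test_that("records with non-canonical residues are kept, their k-mer windows dropped", {
  ps <- proteomeSet(c(p1 = "ACDXFGHIKLMN"), "toy", "virus")
  expect_length(proteinRecords(ps), 1L)  # protein retained
  km <- extractKmers(ps, 3L)
  expect_false(any(grepl("X", peptides(km))))
  # windows not touching the X survive
  expect_true(all(c("FGH", "KLM") %in% peptides(km)))
})

test_that("extractKmers enumerates distinct canonical windows", {
  ps <- proteomeSet(c(a = "ACDEF"), "toy", "virus")
  expect_setequal(peptides(extractKmers(ps, 3L)), c("ACD", "CDE", "DEF"))
  ps2 <- proteomeSet(c(a = "AAAA"), "toy", "virus")
  expect_identical(peptides(extractKmers(ps2, 2L)), "AA")
  # k exceeding every sequence: empty set, not an error
  expect_length(peptides(extractKmers(ps, 10L)), 0L)
  expect_error(extractKmers(ps, 0L), "k must be")
})

test_that("extractKmers matches brute-force window enumeration on a synthetic proteome", {
  prot <- makeProteomes(nSelfProteins = 30L, nSpecies = 1L,
                        selfLength = 120L, seed = 77L)
  got <- peptides(extractKmers(prot$self, 9L))
  # independent oracle: explicit loop over every window
  seqs <- as.character(proteinRecords(prot$self))
  exp <- character(0)
  for (s in seqs) {
    for (i in seq_len(nchar(s) - 8L)) exp <- c(exp, substr(s, i, i + 8L))
  }
  exp <- unique(exp)
  expect_setequal(got, exp)
  # size bound: <= sum(len - k + 1), equality iff all windows distinct
  expect_lte(length(got), sum(nchar(seqs) - 8L))
})

test_that("shuffleRecords conserves composition, is deterministic, keeps 1mers", {
  ps <- proteomeSet(c(a = "M", b = "ACDEFGHIKLMNPQRSTVWY"), "toy", "virus")
  sh1 <- shuffleRecords(ps, seed = 5L)
  sh2 <- shuffleRecords(ps, seed = 5L)
  seqs <- as.character(proteinRecords(sh1))
  expect_identical(seqs[["a"]], "M")  # single residue unchanged
  comp <- function(x) sort(strsplit(x, "")[[1L]])
  expect_identical(comp(seqs[["b"]]),
                   comp(as.character(proteinRecords(ps))[["b"]]))
  expect_identical(as.character(proteinRecords(sh1)),
                   as.character(proteinRecords(sh2)))  # seed-deterministic
  expect_false(identical(as.character(proteinRecords(shuffleRecords(ps, 6L)))[["b"]],
                         seqs[["b"]]))
})

test_that("reduceRedundancy keeps one of an identical pair, all of disjoint sets", {
  prot <- makeProteomes(nSelfProteins = 2L, nSpecies = 2L,
                        proteinsPerSpecies = 4L, nonselfLength = 120L,
                        seed = 31L)
  a <- prot$nonself[[1L]]
  dupA <- proteomeSet(as.character(proteinRecords(a)), "copyA", "virus")
  expect_length(reduceRedundancy(list(a, dupA), 0.8), 1L)
  expect_length(reduceRedundancy(prot$nonself, 0.8), 2L)  # independent randoms
  expect_error(reduceRedundancy(list(), 0.8), "no proteomes")
  expect_error(reduceRedundancy(list(a), 1.5), "maxSimilarity")
})

test_that("reduceRedundancy resolves planted near-duplicate pairs and is idempotent", {
  # 5 independent proteomes; each gets a near-copy sharing ~90% of proteins
  set.seed(99L)
  bases <- lapply(1:5, function(i) {
    p <- makeProteomes(nSelfProteins = 1L, nSpecies = 1L,
                       proteinsPerSpecies = 10L, nonselfLength = 100L,
                       seed = 300L + i)$nonself[[1L]]
    proteomeSet(as.character(proteinRecords(p)), paste0("base_", i), "virus")
  })
  pairs <- unlist(lapply(seq_along(bases), function(i) {
    seqs <- as.character(proteinRecords(bases[[i]]))
    seqs[10L] <- paste(sample(AA20, 100L, replace = TRUE), collapse = "")
    list(bases[[i]], proteomeSet(seqs, paste0("near_", i), "virus"))
  }), recursive = FALSE)
  kept <- reduceRedundancy(pairs, 0.8)
  expect_length(kept, 5L)
  # exactly one member of each planted pair retained (brute-force check)
  keptIds <- vapply(kept, speciesId, character(1))
  for (i in 1:5) {
    expect_equal(sum(keptIds %in% c(speciesId(bases[[i]]),
                                    paste0("near_", i))), 1L)
  }
  expect_identical(vapply(reduceRedundancy(kept, 0.8), speciesId, character(1)),
                   keptIds)  # idempotent
})

test_that("peptide sets round-trip through plain text", {
  prot <- makeProteomes(nSelfProteins = 3L, nSpecies = 1L, seed = 9L)
  km <- extractKmers(prot$self, 9L)
  f <- withr::local_tempfile(fileext = ".txt")
  writePeptides(km, f)
  back <- readPeptides(f, kingdom = "self")
  expect_setequal(peptides(back), peptides(km))
  expect_identical(kmerLength(back), 9L)
})
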