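## End-to-end pipeline: wires the synthetic generators, presentation,
## recognition models and statistics into one reproducible run emitting
## TSV reports and a manifest.

.pipelineDefaults <- function() {
  list(seed = 1L,
       nSelfProteins = 40L, nSpecies = 6L, proteinsPerSpecies = 8L,
       selfLength = 300L, nonselfLength = 250L, sharedKmerRate = 0.02,
       alleles = list(list(name = "synthA", anchorPositions = c(2L, 9L),
                           anchorStrength = 2),
                      list(name = "synthB", anchorPositions = c(2L, 5L, 9L),
                           anchorStrength = 2)),
       thresholdMode = "scaled", targetSpecificity = 0.023,
       fixedThresholdNM = 500,
       meanSimilarPartners = 1.6,
       models = c("complete", "middle", "nonanchor", "degenerate"),
       kRange = c(1L, 3L, 5L, 7L, 9L, 11L),
       nEntropyPeptides = 20000L)
}

.stageSeed <- function(root, stage) {
  as.integer((as.numeric(root) * 7919 + stage * 104729) %% 2147483629 + 1)
}

.writeTsv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full self/nonself overlap pipeline on synthetic data
#'
#' Generates proteomes, allele motifs and a similarity matrix from one
#' root seed (every stage derives its own sub-seed deterministically),
#' then emits: the peptide-length overlap scan with shuffled controls,
#' per-allele overlap tables under the exact and degenerate recognition
#' models, the cross-reactivity footprint, per-allele entropy profiles
#' with the additional-anchor flag, a synthetic immunogenicity
#' contingency analysis, and a manifest with content hashes. Reruns with
#' the same config and seed are bit-identical.
#'
#' @param config Named list overriding the defaults, or a YAML file
#'   path. Keys include `seed`, `nSelfProteins`, `nSpecies`,
#'   `proteinsPerSpecies`, `sharedKmerRate`, `alleles` (list of
#'   `name`/`anchorPositions`/`anchorStrength`), `thresholdMode`
#'   (`"scaled"` or `"fixed"`), `meanSimilarPartners`, `models`,
#'   `kRange`.
#' @param outDir Output directory (created; must not already contain a
#'   manifest).
#' @return Invisibly, a list with the output paths, the run `manifest`
#'   data.frame and the `manifestHash`.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("pmhcRun")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipelineDefaults(), config)
  if (cfg$nSpecies < 1L) stop("config error: need at least one nonself ",
                              "proteome (nSpecies >= 1)", call. = FALSE)
  if (!length(cfg$alleles)) stop("config error: no alleles", call. = FALSE)
  if (!cfg$thresholdMode %in% c("scaled", "fixed"))
    stop("config error: thresholdMode must be 'scaled' or 'fixed'",
         call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  message("stage 1/6: synthetic proteomes")
  prot <- makeProteomes(nSelfProteins = cfg$nSelfProteins,
                        nSpecies = cfg$nSpecies,
                        proteinsPerSpecies = cfg$proteinsPerSpecies,
                        selfLength = cfg$selfLength,
                        nonselfLength = cfg$nonselfLength,
                        sharedKmerRate = cfg$sharedKmerRate,
                        seed = .stageSeed(cfg$seed, 1L))
  selfKmers <- extractKmers(prot$self, 9L)
  message("  self 9mers: ", length(peptides(selfKmers)))

  message("stage 2/6: length scan")
  scan <- lengthScan(prot$self, prot$nonself, kRange = cfg$kRange,
                     shuffled = TRUE, seed = .stageSeed(cfg$seed, 2L))
  scanPath <- file.path(outDir, "length_scan.tsv")
  .writeTsv(scan, scanPath, sprintf("length scan; seed %d", cfg$seed))

  message("stage 3/6: recognition models")
  simMat <- makeSimilarityMatrix(cfg$meanSimilarPartners,
                                 seed = .stageSeed(cfg$seed, 3L))
  rule <- buildSimilarityRule(simMat, "abs_covariance_gt", 0.05)
  models <- list(complete = completeMatchModel(),
                 middle = middleMatchModel(),
                 nonanchor = nonAnchorMatchModel(),
                 degenerate = degenerateModel(rule))[cfg$models]

  message("stage 4/6: presentation and per-allele overlaps")
  thresholdSpec <- if (cfg$thresholdMode == "scaled")
    scaledThreshold(cfg$targetSpecificity) else
    fixedThreshold(cfg$fixedThresholdNM)
  overlapRows <- list()
  entropyRows <- list()
  for (ai in seq_along(cfg$alleles)) {
    al <- cfg$alleles[[ai]]
    bm <- makeAllele(al$name, anchorPositions = al$anchorPositions,
                     anchorStrength = al$anchorStrength,
                     seed = .stageSeed(cfg$seed, 40L + ai))
    selfPresented <- presentedSet(bm, selfKmers, thresholdSpec,
                                  selfPeptides = peptides(selfKmers))
    nonselfPresented <- lapply(prot$nonself, function(sp)
      presentedSet(bm, extractKmers(sp, 9L),
                   presentationThreshold(selfPresented)))
    message("  ", al$name, ": ", length(peptides(selfPresented)),
            " self pMHCs (threshold ",
            format(presentationThreshold(selfPresented), digits = 4),
            " nM)")
    for (mn in names(models)) {
      ov <- overlapFraction(nonselfPresented, selfPresented, models[[mn]],
                            allele = al$name)
      pooled <- pooledFractions(ov)
      getPool <- function(kg) if (kg %in% names(pooled)) pooled[[kg]] else NA_real_
      overlapRows[[length(overlapRows) + 1L]] <- data.frame(
        allele = al$name, model = mn,
        virus = getPool("virus"), bacterium = getPool("bacterium"),
        kingdomAverage = kingdomAverage(ov), stringsAsFactors = FALSE)
    }
    ent <- positionEntropy(peptides(presentedSet(
      bm, unique(randomPeptides(cfg$nEntropyPeptides,
                                seed = .stageSeed(cfg$seed, 60L + ai))),
      presentationThreshold(selfPresented))))
    aa <- additionalAnchorAssessment(ent)
    entropyRows[[length(entropyRows) + 1L]] <- data.frame(
      allele = al$name, t(ent),
      additionalAnchors = aa$hasAdditionalAnchors,
      stringsAsFactors = FALSE)
  }
  overlapPath <- file.path(outDir, "overlap_by_allele.tsv")
  .writeTsv(do.call(rbind, overlapRows), overlapPath,
            sprintf("pooled overlap fractions; thresholds %s; seed %d",
                    cfg$thresholdMode, cfg$seed))
  entropyPath <- file.path(outDir, "entropy_profiles.tsv")
  .writeTsv(do.call(rbind, entropyRows), entropyPath,
            sprintf("per-position entropy (bits) of presented peptides; seed %d",
                    cfg$seed))

  message("stage 5/6: cross-reactivity footprint")
  fp <- averageFootprint(degenerateModel(rule))
  fpPath <- file.path(outDir, "footprint.tsv")
  .writeTsv(data.frame(rule = rule@provenance,
                       meanOtherCount = fp$meanOtherCount,
                       meanRecognizedCount = fp$meanRecognizedCount,
                       reciprocal = fp$reciprocal,
                       reciprocalInclusive = fp$reciprocalInclusive),
            fpPath, "single T-cell recognition footprint")

  message("stage 6/6: synthetic immunogenicity analysis")
  pep <- unique(randomPeptides(800L, seed = .stageSeed(cfg$seed, 5L)))
  flags <- overlapFlags(pep, peptides(selfKmers), models[[length(models)]])
  lab <- makeImmunogenicityLabels(pep, flags,
                                  seed = .stageSeed(cfg$seed, 6L))
  ct <- overlapTable(lab, peptides(selfKmers), models[[length(models)]])
  chi <- chiSquare2x2(ct)
  contPath <- file.path(outDir, "contingency.tsv")
  .writeTsv(data.frame(a = ct[1, 1], b = ct[1, 2], c = ct[2, 1],
                       d = ct[2, 2], statistic = chi$statistic,
                       p.value = chi$p.value),
            contPath, "synthetic immunogenicity x self-overlap 2x2")

  paths <- c(scanPath, overlapPath, entropyPath, fpPath, contPath)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  md5 <- tools::md5sum(c(paths, cfgPath))
  manifest <- data.frame(file = basename(names(md5)), md5 = unname(md5),
                         stringsAsFactors = FALSE)
  manifest <- rbind(manifest,
                    data.frame(file = "package-version",
                               md5 = as.character(utils::packageVersion(
                                 "pmhcOverlap"))),
                    data.frame(file = "seed", md5 = as.character(cfg$seed)))
  manifestPath <- file.path(outDir, "manifest.tsv")
  .writeTsv(manifest, manifestPath, "run manifest")
  manifestHash <- unname(tools::md5sum(manifestPath))
  invisible(list(outDir = outDir, paths = paths, manifest = manifest,
                 manifestHash = manifestHash))
}
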