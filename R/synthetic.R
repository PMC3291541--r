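## Synthetic-data generators with planted ground truth: proteome pairs
## with a controlled shared-9mer rate, allele binding motifs, labelled
## immunogenicity with a planted odds ratio, similarity matrices with a
## controlled rule density, and toy TCR-pMHC structures.

.randomProtein <- function(len, aaFreqs) {
  paste(sample(names(aaFreqs), len, replace = TRUE, prob = aaFreqs),
        collapse = "")
}

#' Generate a self proteome and nonself proteomes with planted homology
#'
#' Background residues are i.i.d. from `aaFreqs`. Into each nonself
#' protein a contiguous segment copied from a random self protein is
#' planted such that a fraction `sharedKmerRate` of the protein's 9mer
#' windows lies fully inside copied sequence and therefore matches a
#' self 9mer verbatim (a window of length w has `w - 8` 9mers, so a
#' planted rate r uses a segment of `round(r * (L - 8)) + 8` residues).
#' `sharedKmerRate = 1` copies the entire protein from self (requires a
#' self protein at least as long). The planted positions are returned as
#' ground truth.
#'
#' @param nSelfProteins Number of self proteins.
#' @param nSpecies Number of nonself species.
#' @param proteinsPerSpecies Proteins per nonself species.
#' @param selfLength,nonselfLength Protein lengths (residues).
#' @param aaFreqs Named residue frequencies (default uniform over the
#'   canonical 20).
#' @param sharedKmerRate Target fraction of nonself 9mer windows planted
#'   from self, in `[0, 1]`.
#' @param kingdoms Kingdom per species (recycled; default alternating
#'   virus / bacterium).
#' @param seed Seed (generation is deterministic given the seed).
#' @return List with `self` (a [ProteomeSet-class]), `nonself` (list of
#'   [ProteomeSet-class]), `truth` (`data.frame` of planted segments)
#'   and `params`.
#' @export
makeProteomes <- function(nSelfProteins = 50L, nSpecies = 10L,
                          proteinsPerSpecies = 10L,
                          selfLength = 400L, nonselfLength = 300L,
                          aaFreqs = NULL, sharedKmerRate = 0,
                          kingdoms = c("virus", "bacterium"),
                          seed = NULL) {
  if (sharedKmerRate < 0 || sharedKmerRate > 1)
    stop("sharedKmerRate must be in [0, 1]", call. = FALSE)
  if (is.null(aaFreqs))
    aaFreqs <- stats::setNames(rep(1 / 20, 20), aminoAcids())
  nWindows <- nonselfLength - 8L
  segLen <- if (sharedKmerRate > 0)
    round(sharedKmerRate * nWindows) + 8L else 0L
  if (segLen > nonselfLength)
    stop("sharedKmerRate ", sharedKmerRate,
         " not achievable for proteins of length ", nonselfLength,
         call. = FALSE)
  if (segLen > selfLength)
    stop("planted segment (", segLen, ") longer than self proteins (",
         selfLength, ")", call. = FALSE)
  withSeed(seed, {
    selfSeqs <- vapply(seq_len(nSelfProteins), function(i)
      .randomProtein(selfLength, aaFreqs), character(1))
    names(selfSeqs) <- sprintf("self_%03d", seq_len(nSelfProteins))
    self <- proteomeSet(selfSeqs, "self", "self")
    kingdoms <- rep_len(kingdoms, nSpecies)
    truth <- list()
    nonself <- lapply(seq_len(nSpecies), function(s) {
      sid <- sprintf("species_%03d", s)
      seqs <- vapply(seq_len(proteinsPerSpecies), function(i)
        .randomProtein(nonselfLength, aaFreqs), character(1))
      names(seqs) <- sprintf("%s_p%03d", sid, seq_len(proteinsPerSpecies))
      if (segLen >= 9L) {
        for (i in seq_len(proteinsPerSpecies)) {
          donor <- sample.int(nSelfProteins, 1L)
          dStart <- sample.int(selfLength - segLen + 1L, 1L)
          seg <- substr(selfSeqs[donor], dStart, dStart + segLen - 1L)
          tStart <- sample.int(nonselfLength - segLen + 1L, 1L)
          substr(seqs[i], tStart, tStart + segLen - 1L) <- seg
          truth[[length(truth) + 1L]] <<- data.frame(
            speciesId = sid, protein = names(seqs)[i], start = tStart,
            segLength = segLen, donor = names(selfSeqs)[donor],
            donorStart = dStart, stringsAsFactors = FALSE)
        }
      }
      proteomeSet(seqs, sid, kingdoms[s])
    })
    list(self = self, nonself = nonself,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(speciesId = character(0), protein = character(0),
                      start = integer(0), segLength = integer(0),
                      donor = character(0), donorStart = integer(0)),
         params = list(sharedKmerRate = sharedKmerRate, segLen = segLen,
                       nWindows = nWindows))
  })
}

#' Generate a motif binding model for a synthetic allele
#'
#' Position-weight model with strong weight dispersion (standard
#' deviation `anchorStrength` on the log-IC50 scale) at the anchor
#' positions and near-flat weights (`baseSd`) elsewhere. The intercept
#' is set from the realized weight dispersion so that roughly 2.3% of
#' random uniform peptides score below 500 nM, mimicking the specificity
#' of a typical allele at the conventional binder threshold. Presented
#' peptides of a strong-anchor allele show visibly reduced entropy at
#' the anchors ([positionEntropy()]).
#'
#' @param name Allele name.
#' @param anchorPositions Anchor positions (default P2, P9).
#' @param anchorStrength Log-scale weight sd at anchors (0 = no motif).
#' @param baseSd Log-scale weight sd at non-anchor positions.
#' @param seed Seed.
#' @return A [MotifBindingModel-class].
#' @export
makeAllele <- function(name, anchorPositions = c(2L, 9L),
                       anchorStrength = 2, baseSd = 0.1, seed = NULL) {
  stopifnot(all(anchorPositions %in% 1:9))
  withSeed(seed, {
    w <- matrix(0, 9L, 20L, dimnames = list(paste0("P", 1:9), aminoAcids()))
    for (p in 1:9) {
      sd <- if (p %in% anchorPositions) anchorStrength else baseSd
      row <- stats::rnorm(20L, 0, sd)
      w[p, ] <- row - mean(row)
    }
    sdTot <- sqrt(sum(apply(w, 1L, function(r) mean(r^2))))
    intercept <- log(500) - stats::qnorm(0.023) * max(sdTot, 1e-6)
    new("MotifBindingModel", alleleName = name, weights = w,
        intercept = intercept,
        anchorPositions = sort(as.integer(anchorPositions)))
  })
}

#' Generate random 9mer peptides
#'
#' @param n Number of peptides.
#' @param aaFreqs Residue frequencies (default uniform).
#' @param k Peptide length.
#' @param seed Seed.
#' @return Character vector of peptides (not necessarily unique).
#' @export
randomPeptides <- function(n, aaFreqs = NULL, k = 9L, seed = NULL) {
  if (is.null(aaFreqs))
    aaFreqs <- stats::setNames(rep(1 / 20, 20), aminoAcids())
  withSeed(seed, {
    m <- matrix(sample(names(aaFreqs), n * k, replace = TRUE,
                       prob = aaFreqs), n, k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
}

#' Generate immunogenicity labels with a planted self-overlap effect
#'
#' Bernoulli immunogenicity with
#' `logit(p) = logit(baseRate) + log(oddsRatio) * (1 - overlapFlag)`:
#' `baseRate` is the immunogenicity probability of self-overlapping
#' peptides and non-overlapping peptides are `oddsRatio` times more
#' likely (on the odds scale) to be immunogenic, emulating T-cell
#' tolerance of self-similar peptides.
#'
#' @param peptidesChr Peptides.
#' @param overlapFlags Logical vector: self-overlapping?
#' @param baseRate Immunogenicity probability at `overlapFlag = TRUE`.
#' @param oddsRatio Planted odds ratio (> 0).
#' @param allele Allele annotation.
#' @param seed Seed.
#' @return `data.frame` with columns `peptide`, `allele`, `label`,
#'   `overlap`, and attribute `params` recording the ground truth.
#' @export
makeImmunogenicityLabels <- function(peptidesChr, overlapFlags,
                                     baseRate = 0.25, oddsRatio = 3.5,
                                     allele = "synthetic", seed = NULL) {
  stopifnot(length(peptidesChr) == length(overlapFlags), oddsRatio > 0)
  p <- stats::plogis(stats::qlogis(baseRate) +
                     log(oddsRatio) * (1 - as.numeric(overlapFlags)))
  imm <- withSeed(seed, stats::runif(length(p)) < p)
  out <- data.frame(peptide = peptidesChr, allele = allele,
                    label = ifelse(imm, "immunogenic", "non-immunogenic"),
                    overlap = as.logical(overlapFlags),
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(baseRate = baseRate, oddsRatio = oddsRatio)
  out
}

#' Generate a symmetric similarity matrix with controlled rule density
#'
#' Builds a synthetic covariance-style [SubstitutionMatrix-class] whose
#' `abs_covariance_gt 0.05` rule has a mean similar-set size as close to
#' `meanSimilarPartners` as a symmetric pair relation allows (the mean
#' is `2 * npairs / 20`, so the achievable resolution is 0.1; always
#' within 0.2 of the target). Similar pairs get covariance 0.2,
#' dissimilar pairs 0, the diagonal 1. Clearly synthetic: a controlled
#' stand-in with the same rule density regime as measured covariance
#' matrices, not their values.
#'
#' @param meanSimilarPartners Target mean similar-set size in `[0, 19]`.
#' @param seed Seed (which pairs are similar is random).
#' @param alphabet Alphabet (default the canonical 20).
#' @return A [SubstitutionMatrix-class] (name `"synthetic-cov"`).
#' @export
makeSimilarityMatrix <- function(meanSimilarPartners, seed = NULL,
                                 alphabet = aminoAcids()) {
  nA <- length(alphabet)
  stopifnot(meanSimilarPartners >= 0, meanSimilarPartners <= nA - 1)
  nPairs <- round(meanSimilarPartners * nA / 2)
  allPairs <- utils::combn(nA, 2L)
  pick <- withSeed(seed, sample.int(ncol(allPairs), nPairs))
  v <- matrix(0, nA, nA, dimnames = list(alphabet, alphabet))
  for (j in pick) {
    i1 <- allPairs[1L, j]; i2 <- allPairs[2L, j]
    v[i1, i2] <- v[i2, i1] <- 0.2
  }
  diag(v) <- 1
  new("SubstitutionMatrix", name = "synthetic-cov", values = v)
}

## ---- toy structures --------------------------------------------------

.pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                         element) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resno, x, y, z, 1.00, 0.00, element)
}

#' Write a toy TCR-pMHC structure realizing a contact specification
#'
#' Writes a syntactically valid PDB file with a 9-residue peptide chain
#' `C` (one CA atom per residue, 20 angstrom apart along x) and TCR
#' chains `D` and `E`. For each entry of `contactSpec`, `nResidues` TCR
#' residues are placed exactly `distance` angstrom from the CA of the
#' requested peptide position (fanned out in the y-z plane, so each is
#' nearest to its own position). Distances are exact, so the strict
#' "within cutoff" convention of [countContacts()] is directly testable:
#' a residue at exactly the cutoff does not count. Each TCR chain also
#' carries one remote residue (1000 angstrom away) so both chains exist
#' even with an empty spec; a far-away MHC stand-in chain `A` is
#' included.
#'
#' @param contactSpec List of `list(position=, nResidues=, distance=)`
#'   entries (possibly empty).
#' @param path Output PDB path.
#' @param structureId Identifier recorded in the HEADER.
#' @return `path`, invisibly.
#' @export
makeToyStructure <- function(contactSpec = list(), path,
                             structureId = "TOY") {
  spacing <- 20
  for (s in contactSpec) {
    if (!all(c("position", "nResidues", "distance") %in% names(s)))
      stop("each contactSpec entry needs position, nResidues, distance",
           call. = FALSE)
    if (!s$position %in% 1:9)
      stop("contact position must be in 1..9", call. = FALSE)
    if (s$distance <= 0 || s$distance >= spacing / 2)
      stop("infeasible geometry: distance must be in (0, ", spacing / 2,
           ") angstrom", call. = FALSE)
  }
  lines <- c(sprintf("HEADER    TOY TCR-PMHC COMPLEX              %s",
                     structureId))
  serial <- 0L
  addAtom <- function(chain, resno, x, y, z) {
    serial <<- serial + 1L
    lines[[length(lines) + 1L]] <<- .pdbAtomLine(serial, "CA", "ALA",
                                                 chain, resno, x, y, z, "C")
  }
  # MHC stand-in, far below the peptide
  addAtom("A", 1L, 0, -500, 0)
  addAtom("A", 2L, spacing, -500, 0)
  # peptide chain C: 9 CA atoms along x
  for (i in 1:9) addAtom("C", i, spacing * i, 0, 0)
  # TCR chains D and E, alternating per spec entry
  tcrChains <- c("D", "E")
  resCounter <- c(D = 0L, E = 0L)
  for (si in seq_along(contactSpec)) {
    s <- contactSpec[[si]]
    chain <- tcrChains[(si - 1L) %% 2L + 1L]
    for (j in seq_len(s$nResidues)) {
      theta <- (j - 1L) * 0.4
      resCounter[chain] <- resCounter[chain] + 1L
      addAtom(chain, resCounter[chain],
              spacing * s$position,
              s$distance * cos(theta), s$distance * sin(theta))
    }
  }
  # remote residue per TCR chain so both chains always exist
  for (chain in tcrChains) {
    resCounter[chain] <- resCounter[chain] + 1L
    addAtom(chain, resCounter[chain], 0, 1000, 500)
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
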