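## TCR-pMHC structural analysis: per-position TCR contact counting at a
## distance cutoff, and the group comparison of contact fractions.

## Non-hydrogen ATOM/HETATM records, highest-occupancy altloc conformer
## only, for the given chains.
.cleanAtoms <- function(pdb, chains) {
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% chains, , drop = FALSE]
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1L, 1L), at$elesy)))
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  if (!nrow(at)) return(at)
  occ <- ifelse(is.na(at$o), 1, at$o)
  at <- at[order(-occ), , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at[!duplicated(key), , drop = FALSE]
}

#' Count TCR contacts per peptide position
#'
#' For each position P1..P9 of the presented peptide, the number of
#' distinct TCR residues having at least one non-hydrogen atom strictly
#' within `cutoff` angstrom of at least one non-hydrogen atom of that
#' peptide residue. Chain identification is explicit (annotation, not
#' heuristics); altloc conformers are reduced to the highest-occupancy
#' one. Fractions are the per-position share of the structure's total
#' peptide-TCR contacts; a structure without any contact reports zero
#' fractions with a warning.
#'
#' @param pdb A `bio3d` pdb object ([bio3d::read.pdb()]) or a PDB file
#'   path.
#' @param peptideChain Chain id of the presented peptide (must have
#'   exactly 9 residues).
#' @param tcrChains Character vector of TCR chain ids.
#' @param cutoff Distance cutoff in angstrom (default 5.0; "within" is
#'   strict less-than).
#' @param structureId Identifier recorded in the profile.
#' @return A [ContactProfile-class].
#' @seealso [suggestPeptideChain()], [makeToyStructure()]
#' @export
countContacts <- function(pdb, peptideChain, tcrChains, cutoff = 5.0,
                          structureId = "structure") {
  if (is.character(pdb)) {
    structureId <- sub("\\.pdb$", "", basename(pdb))
    pdb <- bio3d::read.pdb(pdb)
  }
  pep <- .cleanAtoms(pdb, peptideChain)
  if (!nrow(pep)) stop("missing peptide chain '", peptideChain, "'",
                       call. = FALSE)
  tcr <- .cleanAtoms(pdb, tcrChains)
  found <- unique(pdb$atom$chain[pdb$atom$type == "ATOM"])
  missingChains <- setdiff(tcrChains, found)
  if (length(missingChains))
    stop("missing TCR chain(s): ", paste(missingChains, collapse = ", "),
         call. = FALSE)
  pepRes <- sort(unique(pep$resno))
  if (length(pepRes) != 9L)
    stop("peptide chain '", peptideChain, "' has ", length(pepRes),
         " residues; expected 9", call. = FALSE)
  counts <- integer(9L)
  if (nrow(tcr)) {
    txyz <- as.matrix(tcr[, c("x", "y", "z")])
    tres <- paste(tcr$chain, tcr$resno, sep = "|")
    for (i in seq_len(9L)) {
      pa <- pep[pep$resno == pepRes[i], , drop = FALSE]
      pxyz <- as.matrix(pa[, c("x", "y", "z")])
      # squared distances peptide-atoms x tcr-atoms
      d2 <- outer(rowSums(pxyz^2), rowSums(txyz^2), "+") -
        2 * pxyz %*% t(txyz)
      close <- colSums(d2 < cutoff^2) > 0L   # per TCR atom
      counts[i] <- length(unique(tres[close]))
    }
  }
  total <- sum(counts)
  fractions <- if (total > 0L) counts / total else {
    warning("no peptide-TCR contacts within ", cutoff,
            " angstrom; fractions reported as zeros", call. = FALSE)
    numeric(9L)
  }
  new("ContactProfile", structureId = structureId,
      counts = counts, fractions = fractions)
}

#' Suggest the peptide chain of a structure
#'
#' Helper for annotation: returns the ids of chains with exactly 9
#' amino-acid residues (candidate presented 9mers).
#'
#' @param pdb A `bio3d` pdb object or PDB file path.
#' @return Character vector of chain ids.
#' @export
suggestPeptideChain <- function(pdb) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  nres <- vapply(split(at$resno, at$chain), function(r)
    length(unique(r)), integer(1))
  names(nres)[nres == 9L]
}

#' Compare contact fractions between position groups
#'
#' Two-sided Wilcoxon rank-sums test on the pooled per-structure contact
#' fractions of the positions in group A versus those in group B (e.g.
#' the central positions P4-P8 against P1-P3 and P9).
#'
#' @param profiles List of [ContactProfile-class] (at least 2).
#' @param groupA,groupB Non-empty integer position sets (1..9).
#' @return List with `p.value`, `statistic` and the pooled group
#'   fraction vectors.
#' @export
comparePositionGroups <- function(profiles, groupA = 4:8,
                                  groupB = c(1:3, 9L)) {
  stopifnot(length(profiles) >= 2L)
  if (!length(groupA) || !length(groupB))
    stop("position groups must be non-empty", call. = FALSE)
  fr <- do.call(rbind, lapply(profiles, function(p) p@fractions))
  a <- as.vector(fr[, groupA])
  b <- as.vector(fr[, groupB])
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = FALSE, correct = FALSE)
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       groupA = a, groupB = b)
}
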