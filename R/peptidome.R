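## Proteome reading, k-mer extraction, shuffled controls, redundancy
## reduction.

#' Construct a ProteomeSet from sequences
#'
#' @param sequences Named character vector or `AAStringSet` of protein
#'   sequences. Sequences are uppercased; entries whose sequence is empty
#'   after sanitization are dropped with a warning.
#' @param speciesId Species identifier.
#' @param kingdom `"self"`, `"virus"` or `"bacterium"`.
#' @return A [ProteomeSet-class].
#' @export
#' @examples
#' proteomeSet(c(p1 = "MKVLATTPW", p2 = "ACDEFGHIKLMNP"), "toy", "virus")
proteomeSet <- function(sequences, speciesId, kingdom) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0(speciesId, "_", seq_along(sequences))
  sequences <- toupper(gsub("[[:space:]*]", "", sequences))
  empty <- !nzchar(sequences)
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty sequence dropped from '",
            speciesId, "'", call. = FALSE)
    sequences <- sequences[!empty]
  }
  if (!length(sequences))
    stop("no non-empty sequences for '", speciesId, "'", call. = FALSE)
  new("ProteomeSet", records = Biostrings::AAStringSet(sequences),
      speciesId = speciesId, kingdom = kingdom)
}

#' Read a proteome from a FASTA file
#'
#' One record per FASTA entry; sequences are uppercased and `*`
#' stop-codon characters stripped. Records that are empty after
#' sanitization are dropped with a warning. Non-canonical residues
#' (X, B, Z, U) are retained in the records; k-mer windows containing
#' them are excluded later by [extractKmers()], matching the behaviour of
#' presentation predictors.
#'
#' @param path FASTA file.
#' @param speciesId Species identifier (default: file base name).
#' @param kingdom `"self"`, `"virus"` or `"bacterium"`.
#' @return A [ProteomeSet-class].
#' @export
readProteome <- function(path, speciesId = NULL, kingdom = "self") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e)
                     stop("malformed FASTA '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (!length(seqs)) stop("empty FASTA file: ", path, call. = FALSE)
  # keep only the identifier part of the header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(speciesId))
    speciesId <- sub("\\.(fa|fasta|faa)$", "", basename(path))
  proteomeSet(seqs, speciesId, kingdom)
}

#' Write a ProteomeSet to FASTA
#'
#' @param x A [ProteomeSet-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(x, path) {
  stopifnot(is(x, "ProteomeSet"))
  Biostrings::writeXStringSet(x@records, path)
  invisible(path)
}

#' Extract the unique k-mer peptide set of a proteome
#'
#' All distinct length-`k` windows (stride 1) over all proteins.
#' Duplicates are counted once (set semantics); windows containing a
#' non-canonical letter are excluded. A `k` larger than every sequence
#' yields an empty set, not an error.
#'
#' @param x A [ProteomeSet-class], or a character vector of sequences.
#' @param k Peptide length (>= 1).
#' @return A [PeptideSet-class].
#' @export
#' @examples
#' ps <- proteomeSet(c(a = "ACDEF"), "toy", "virus")
#' peptides(extractKmers(ps, 3))   # "ACD" "CDE" "DEF"
extractKmers <- function(x, k = 9L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (is(x, "ProteomeSet")) {
    seqs <- as.character(x@records)
    sid <- x@speciesId
    kg <- x@kingdom
  } else {
    seqs <- as.character(x)
    sid <- "unknown"
    kg <- "self"
  }
  out <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE))
  out <- out[isCanonical(out)]
  new("PeptideSet", k = k, peptides = out, speciesId = sid, kingdom = kg)
}

## k-mers of a single sequence (all windows, canonical only, NOT deduplicated)
kmerWindows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, 1:(n - k + 1L), k:n)
  w[isCanonical(w)]
}

#' Shuffle protein sequences (within-protein permutation)
#'
#' Independently permutes the residues of each protein, conserving each
#' protein's amino-acid composition exactly. Used as the control that
#' breaks up homology-driven self/nonself overlap while keeping
#' composition fixed.
#'
#' @param x A [ProteomeSet-class].
#' @param seed Integer seed; the shuffle is deterministic given the seed
#'   and the caller's RNG stream is left untouched.
#' @return A new [ProteomeSet-class] with shuffled sequences.
#' @export
shuffleRecords <- function(x, seed = NULL) {
  stopifnot(is(x, "ProteomeSet"))
  seqs <- as.character(x@records)
  shuffled <- withSeed(seed, {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      paste(ch[sample.int(length(ch))], collapse = "")
    }, character(1))
  })
  names(shuffled) <- names(seqs)
  new("ProteomeSet", records = Biostrings::AAStringSet(shuffled),
      speciesId = x@speciesId, kingdom = x@kingdom)
}

#' Greedy redundancy reduction between proteomes
#'
#' Proteomes are visited in order of decreasing size (total residues);
#' one is discarded if its shared unique-9mer fraction, relative to the
#' smaller proteome of the pair, exceeds `maxSimilarity` against any
#' already-retained proteome. The shared-9mer fraction is a k-mer proxy
#' for an all-to-all exact-match alignment criterion normalized to the
#' smaller proteome; the operation is idempotent.
#'
#' @param proteomes List of [ProteomeSet-class].
#' @param maxSimilarity Maximum allowed similarity in (0, 1].
#' @param k k-mer length used for the similarity proxy (default 9).
#' @return The retained subset of `proteomes` (same order as visited,
#'   i.e. by decreasing size).
#' @export
reduceRedundancy <- function(proteomes, maxSimilarity = 0.8, k = 9L) {
  if (!length(proteomes)) stop("no proteomes given", call. = FALSE)
  if (maxSimilarity <= 0 || maxSimilarity > 1)
    stop("maxSimilarity must be in (0, 1]", call. = FALSE)
  sizes <- vapply(proteomes, function(p)
    sum(Biostrings::width(p@records)), numeric(1))
  ord <- order(sizes, decreasing = TRUE)
  kmers <- lapply(proteomes, function(p) peptides(extractKmers(p, k)))
  keptIdx <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keptIdx) {
      shared <- sum(kmers[[i]] %in% kmers[[j]])
      denom <- min(length(kmers[[i]]), length(kmers[[j]]))
      if (denom > 0L && shared / denom > maxSimilarity) {
        ok <- FALSE
        break
      }
    }
    if (ok) keptIdx <- c(keptIdx, i)
  }
  proteomes[keptIdx]
}

#' Read / write peptide sets as plain text
#'
#' One peptide per line; lines starting with `#` are ignored on read.
#'
#' @param x A [PeptideSet-class] (write) or file path (read).
#' @param path Output file (write).
#' @param k,speciesId,kingdom Annotation used on read.
#' @return `writePeptides` returns `path` invisibly; `readPeptides`
#'   returns a [PeptideSet-class].
#' @export
writePeptides <- function(x, path) {
  stopifnot(is(x, "PeptideSet") || is(x, "PresentedSet"))
  writeLines(peptides(x), path)
  invisible(path)
}

#' @rdname writePeptides
#' @export
readPeptides <- function(path, k = NULL, speciesId = "unknown",
                         kingdom = "self") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no peptides in ", path, call. = FALSE)
  if (is.null(k)) k <- nchar(lines[1L])
  new("PeptideSet", k = as.integer(k), peptides = unique(lines),
      speciesId = speciesId, kingdom = kingdom)
}
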