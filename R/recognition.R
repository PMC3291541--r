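## T-cell recognition models: similarity rules from substitution/
## covariance matrices, exact and degenerate position-mask recognition,
## key enumeration for index lookups, and the min-max scaled peptide
## similarity score.

#' Construct a SubstitutionMatrix
#'
#' @param values Numeric 20 x 20 matrix with amino-acid dimnames (any
#'   consistent ordering); symmetric to within 1e-9. A larger matrix
#'   (e.g. a BLOSUM matrix including ambiguity codes) is subset to the
#'   canonical 20 letters.
#' @param name Matrix name.
#' @return A [SubstitutionMatrix-class].
#' @export
#' @examples
#' bl62 <- local({data(BLOSUM62, package = "Biostrings", envir = environment())
#'                BLOSUM62})
#' substitutionMatrix(bl62, "BLOSUM62")
substitutionMatrix <- function(values, name = "custom") {
  aa <- aminoAcids()
  if (!is.null(rownames(values)) && all(aa %in% rownames(values)) &&
      all(aa %in% colnames(values))) {
    values <- values[aa, aa]
  }
  new("SubstitutionMatrix", name = name, values = values)
}

#' Read a substitution matrix from a whitespace-delimited text file
#'
#' Expected format: a header row with the 20 amino-acid letters, then 20
#' rows each starting with the row letter followed by 20 numbers (the
#' format in which covariance matrices such as PMBEC are distributed).
#' A header-less 20-column layout (letters assumed in the file's row
#' order) is also accepted if the first row parses as numbers.
#'
#' @param path File path.
#' @param name Matrix name (default: file base name).
#' @return A [SubstitutionMatrix-class].
#' @seealso [writeSubstitutionMatrix()]
#' @export
readSubstitutionMatrix <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tok <- strsplit(trimws(readLines(path)), "[[:space:]]+")
  tok <- tok[lengths(tok) > 0L & !vapply(tok, function(x)
    startsWith(x[1L], "#"), logical(1))]
  if (length(tok) < 20L) stop("not a 20 x 20 matrix: ", path, call. = FALSE)
  header <- tok[[1L]]
  if (all(header %in% c(aminoAcids(), letters))) {
    cols <- toupper(header)
    tok <- tok[-1L]
  } else {
    cols <- NULL
  }
  if (length(tok) != 20L)
    stop("expected 20 data rows in ", path, call. = FALSE)
  hasRowLabel <- lengths(tok)[1L] == 21L
  rows <- character(20)
  vals <- matrix(NA_real_, 20, 20)
  for (i in seq_len(20L)) {
    r <- tok[[i]]
    if (hasRowLabel) {
      rows[i] <- toupper(r[1L])
      r <- r[-1L]
    }
    if (length(r) != 20L)
      stop("row ", i, " of ", path, " does not have 20 values", call. = FALSE)
    vals[i, ] <- as.numeric(r)
  }
  if (!hasRowLabel) rows <- if (is.null(cols)) aminoAcids() else cols
  if (is.null(cols)) cols <- rows
  dimnames(vals) <- list(rows, cols)
  substitutionMatrix(vals, name)
}

#' @rdname readSubstitutionMatrix
#' @param x A [SubstitutionMatrix-class].
#' @export
writeSubstitutionMatrix <- function(x, path) {
  stopifnot(is(x, "SubstitutionMatrix"))
  v <- x@values
  lines <- c(paste(colnames(v), collapse = " "),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], format(v[i, ], trim = TRUE)),
                     collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Derive a conservative-substitution rule from a matrix
#'
#' Thresholds a [SubstitutionMatrix-class] into a symmetric
#' [SimilarityRule-class]:
#' * `abs_covariance_gt`: `b` is similar to `a` iff `|M(a,b)| > cutoff`
#'   (the PMBEC convention, cutoff 0.05);
#' * `value_gt`: iff `M(a,b) > cutoff` (signed variant);
#' * `positive_score`: iff `M(a,b) > 0` (the BLOSUM convention).
#' A residue is never similar to itself.
#'
#' @param matrix A [SubstitutionMatrix-class].
#' @param ruleKind One of `"abs_covariance_gt"`, `"value_gt"`,
#'   `"positive_score"`.
#' @param cutoff Threshold (ignored for `positive_score`).
#' @return A [SimilarityRule-class].
#' @export
buildSimilarityRule <- function(matrix,
                                ruleKind = c("abs_covariance_gt", "value_gt",
                                             "positive_score"),
                                cutoff = 0.05) {
  stopifnot(is(matrix, "SubstitutionMatrix"))
  ruleKind <- match.arg(ruleKind)
  v <- matrix@values
  aa <- rownames(v)
  sel <- switch(ruleKind,
    abs_covariance_gt = abs(v) > cutoff,
    value_gt = v > cutoff,
    positive_score = v > 0)
  diag(sel) <- FALSE
  similar <- lapply(stats::setNames(aa, aa), function(a) aa[sel[a, ]])
  new("SimilarityRule", similar = similar,
      provenance = sprintf("%s %s %s", matrix@name, ruleKind,
                           if (ruleKind == "positive_score") "" else
                             format(cutoff)))
}

#' The empty similarity rule (no substitution tolerated)
#'
#' @param alphabet Alphabet (default the 20 canonical amino acids).
#' @return A [SimilarityRule-class] with all partner sets empty.
#' @export
emptySimilarityRule <- function(alphabet = aminoAcids()) {
  new("SimilarityRule",
      similar = lapply(stats::setNames(alphabet, alphabet),
                       function(a) character(0)),
      provenance = "empty")
}

#' Build a SimilarityRule directly from partner sets
#'
#' @param similar Named list of character vectors; symmetrized (a pair is
#'   included if listed in either direction) and made irreflexive.
#' @param provenance Descriptor.
#' @return A [SimilarityRule-class].
#' @export
similarityRule <- function(similar, provenance = "custom") {
  alphabet <- union(names(similar), unlist(similar, use.names = FALSE))
  out <- lapply(stats::setNames(alphabet, alphabet), function(a) character(0))
  for (a in names(similar)) for (b in similar[[a]]) {
    if (a == b) next
    out[[a]] <- union(out[[a]], b)
    out[[b]] <- union(out[[b]], a)
  }
  new("SimilarityRule", similar = out, provenance = provenance)
}

## ---- recognition models ----------------------------------------------

#' Construct a RecognitionModel
#'
#' The default is the degenerate middle-position model: the TCR reads
#' P3-P8; no mismatch at P5; at most one conservative mismatch among the
#' recognized positions N-terminal of P5 and one among those C-terminal
#' of it.
#'
#' @param recognizedPositions Positions read by the TCR (subset of 1..9).
#' @param fixedPositions Positions requiring exact identity.
#' @param regions List of `list(positions=, budget=)` partitioning the
#'   non-fixed recognized positions. `NULL` (default) splits the
#'   non-fixed positions into an N-terminal region (P1-P4) and a
#'   C-terminal region (P6-P9), budget 1 each; regions that come out
#'   empty are dropped.
#' @param rule A [SimilarityRule-class]; the empty rule means no
#'   mismatch is ever tolerated (exact matching on the position mask).
#' @return A [RecognitionModel-class].
#' @export
#' @examples
#' recognitionModel()                      # degenerate P3-8 skeleton
#' recognitionModel(1:9, fixedPositions = 1:9)  # complete exact match
recognitionModel <- function(recognizedPositions = 3:8,
                             fixedPositions = 5L,
                             regions = NULL,
                             rule = emptySimilarityRule()) {
  rp <- sort(as.integer(recognizedPositions))
  fp <- sort(as.integer(fixedPositions))
  if (is.null(regions)) {
    free <- setdiff(rp, fp)
    split5 <- if (length(fp)) min(fp) else 5L
    regions <- list(list(positions = free[free < split5], budget = 1L),
                    list(positions = free[free >= split5], budget = 1L))
    regions <- Filter(function(r) length(r$positions) > 0L, regions)
  } else {
    regions <- lapply(regions, function(r)
      list(positions = sort(as.integer(r$positions)),
           budget = as.integer(r$budget)))
  }
  new("RecognitionModel", recognizedPositions = rp, fixedPositions = fp,
      regions = regions, rule = rule)
}

#' Canonical recognition models
#'
#' Convenience constructors for the models used throughout the overlap
#' analyses:
#' * `completeMatchModel()`: exact identity at all positions P1-P9;
#' * `middleMatchModel()`: exact identity at the TCR-exposed middle
#'   positions P3-P8;
#' * `nonAnchorMatchModel()`: exact identity at the non-anchor positions
#'   P1 and P3-P8;
#' * `degenerateModel(rule)`: the degenerate middle-position model (P5
#'   fixed, one conservative mismatch allowed in P3-P4 and one in
#'   P6-P8);
#' * `adjacentMismatchModel(rule)`: variant allowing the two mismatches
#'   to sit anywhere among P3,P4,P6,P7,P8 (including adjacent), a single
#'   region with budget 2;
#' * `alleleSpecificModel(positions, rule)`: degenerate model over an
#'   allele's six least specific positions, split at the most specific
#'   recognized position, which is fixed (mirrors the default model's
#'   anatomy around P5).
#'
#' @param rule A [SimilarityRule-class].
#' @param positions For `alleleSpecificModel`, the recognized positions
#'   (e.g. from [leastSpecificPositions()]).
#' @param entropy For `alleleSpecificModel`, the allele's 9-position
#'   entropy profile used to pick the most specific recognized position.
#' @return A [RecognitionModel-class].
#' @export
completeMatchModel <- function() {
  recognitionModel(1:9, fixedPositions = 1:9, regions = list())
}

#' @rdname completeMatchModel
#' @export
middleMatchModel <- function() {
  recognitionModel(3:8, fixedPositions = 3:8, regions = list())
}

#' @rdname completeMatchModel
#' @export
nonAnchorMatchModel <- function() {
  recognitionModel(c(1L, 3:8), fixedPositions = c(1L, 3:8), regions = list())
}

#' @rdname completeMatchModel
#' @export
degenerateModel <- function(rule) {
  recognitionModel(3:8, fixedPositions = 5L, rule = rule)
}

#' @rdname completeMatchModel
#' @export
adjacentMismatchModel <- function(rule) {
  recognitionModel(3:8, fixedPositions = 5L,
                   regions = list(list(positions = c(3L, 4L, 6L, 7L, 8L),
                                       budget = 2L)),
                   rule = rule)
}

#' @rdname completeMatchModel
#' @export
alleleSpecificModel <- function(positions, entropy, rule) {
  rp <- sort(as.integer(positions))
  fixed <- rp[which.min(entropy[rp])]
  free <- setdiff(rp, fixed)
  regions <- Filter(function(r) length(r$positions) > 0L,
                    list(list(positions = free[free < fixed], budget = 1L),
                         list(positions = free[free > fixed], budget = 1L)))
  recognitionModel(rp, fixedPositions = fixed, regions = regions, rule = rule)
}

## ---- recognition predicate and key enumeration -----------------------

#' Would the same T-cell recognize both peptides?
#'
#' TRUE iff, under the model, `a` and `b` are indistinguishable: equal at
#' every fixed position, within each region the number of mismatching
#' positions does not exceed the region's budget, and every mismatch pair
#' is allowed by the similarity rule. Positions outside
#' `recognizedPositions` are ignored.
#'
#' @param a,b 9mer peptides (vectors are recycled elementwise).
#' @param model A [RecognitionModel-class].
#' @return Logical vector.
#' @export
#' @examples
#' m <- middleMatchModel()
#' isRecognized("ALFNTVATL", "SLFNTVATL", m)  # differs only at P1: TRUE
isRecognized <- function(a, b, model) {
  stopifnot(is(model, "RecognitionModel"))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(c(a, b)) != 9L))
    stop("peptides must be 9mers", call. = FALSE)
  am <- peptideMatrix(a, 9L)
  bm <- peptideMatrix(b, 9L)
  sim <- model@rule@similar
  out <- rep(TRUE, n)
  fp <- model@fixedPositions
  if (length(fp)) {
    out <- out & rowSums(am[, fp, drop = FALSE] !=
                         bm[, fp, drop = FALSE]) == 0L
  }
  for (r in model@regions) {
    p <- r$positions
    if (!length(p)) next
    mism <- am[, p, drop = FALSE] != bm[, p, drop = FALSE]
    out <- out & rowSums(mism) <= r$budget
    idx <- which(out & rowSums(mism) > 0L)
    for (i in idx) {
      for (j in which(mism[i, ])) {
        if (!bm[i, p[j]] %in% sim[[am[i, p[j]]]]) {
          out[i] <- FALSE
          break
        }
      }
    }
  }
  out
}

## All region variants of `base` (character vector of the region's
## residues) with at most `budget` substitutions, each substitution
## drawn from the similarity sets of the ORIGINAL residues.
.regionVariants <- function(base, sim, budget) {
  res <- list(base)
  if (budget < 1L || !length(base)) return(res)
  recurse <- function(v, start, b) {
    for (j in start:length(base)) {
      for (s in sim[[base[j]]]) {
        w <- v
        w[j] <- s
        res[[length(res) + 1L]] <<- w
        if (b > 1L && j < length(base)) recurse(w, j + 1L, b - 1L)
      }
    }
  }
  recurse(base, 1L, budget)
  res
}

#' Enumerate the recognition keys of a peptide
#'
#' The set of projections (strings over the model's recognized
#' positions, in order) such that any peptide whose recognized-position
#' projection is a member is recognized as "the same" by a T-cell seeing
#' `peptide`. Backs the linear-time key-index overlap computation: self
#' peptides are indexed by their projection and each nonself peptide
#' probes the index with its keys. For symmetric rules the key count
#' equals the closed form of [recognizedVariantCount()] plus one.
#'
#' @param peptide A single 9mer.
#' @param model A [RecognitionModel-class].
#' @return Character vector of keys (first element is the peptide's own
#'   projection).
#' @export
recognizedKeys <- function(peptide, model) {
  stopifnot(is(model, "RecognitionModel"), length(peptide) == 1L)
  if (nchar(peptide) != 9L) stop("peptide must be a 9mer", call. = FALSE)
  rp <- model@recognizedPositions
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]][rp]
  names(chars) <- as.character(rp)
  sim <- model@rule@similar
  variantSets <- lapply(model@regions, function(r) {
    idx <- match(r$positions, rp)
    .regionVariants(chars[idx], sim, r$budget)
  })
  keys <- list(chars)
  for (ri in seq_along(variantSets)) {
    idx <- match(model@regions[[ri]]$positions, rp)
    newKeys <- vector("list", length(keys) * length(variantSets[[ri]]))
    n <- 0L
    for (k in keys) for (v in variantSets[[ri]]) {
      k[idx] <- v
      n <- n + 1L
      newKeys[[n]] <- k
    }
    keys <- newKeys
  }
  unique(vapply(keys, paste, character(1), collapse = ""))
}

#' Project peptides onto a model's recognized positions
#'
#' @param peptidesChr Character vector of 9mers.
#' @param model A [RecognitionModel-class].
#' @return Character vector of projections (one per peptide).
#' @export
projectPeptides <- function(peptidesChr, model) {
  stopifnot(is(model, "RecognitionModel"))
  if (!length(peptidesChr)) return(character(0))
  assertPeptides9(peptidesChr)
  m <- peptideMatrix(peptidesChr, 9L)[, model@recognizedPositions,
                                      drop = FALSE]
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## ---- min-max scaled peptide similarity score -------------------------

#' Min-max scaled peptide similarity score
#'
#' Position-wise substitution-matrix similarity between `query` and
#' `reference`, scaled to the minimal and maximal scores attainable by
#' any peptide against the reference:
#' `score = (raw - min) / (max - min)` with
#' `raw = sum_i M(ref_i, query_i)`, `min = sum_i min_x M(ref_i, x)` and
#' `max = sum_i max_x M(ref_i, x)`. This normalizes away the intrinsic
#' similarity a given reference has to all peptides; with a
#' diagonal-dominant matrix the reference scores 1 against itself.
#'
#' @param query,reference Peptides of equal length.
#' @param matrix A [SubstitutionMatrix-class] (e.g. BLOSUM35 in the
#'   original description of the method).
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' bl62 <- local({data(BLOSUM62, package = "Biostrings", envir = environment())
#'                substitutionMatrix(BLOSUM62, "BLOSUM62")})
#' peptideSimilarityScore("SLFNTVATL", "SLFNTVATL", bl62)  # 1
peptideSimilarityScore <- function(query, reference, matrix) {
  stopifnot(is(matrix, "SubstitutionMatrix"))
  if (nchar(query) != nchar(reference))
    stop("query and reference must have equal length", call. = FALSE)
  v <- matrix@values
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  r <- strsplit(reference, "", fixed = TRUE)[[1L]]
  raw <- sum(v[cbind(r, q)])
  lo <- sum(apply(v[r, , drop = FALSE], 1L, min))
  hi <- sum(apply(v[r, , drop = FALSE], 1L, max))
  if (hi == lo)
    stop("degenerate matrix: min and max similarity coincide", call. = FALSE)
  (raw - lo) / (hi - lo)
}
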