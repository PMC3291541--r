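#' The 20 canonical amino-acid letters
#'
#' One-letter codes of the 20 canonical amino acids, in alphabetical order.
#' All peptide and matrix machinery in the package is defined over this
#' alphabet; residues outside it (X, B, Z, U, *) are treated as
#' non-canonical and excluded at the k-mer level.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. seed = NULL means: use the current
## stream (no restore).
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Split peptides (equal length) into an n x k character matrix.
peptideMatrix <- function(peptides, k = NULL) {
  if (length(peptides) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = if (is.null(k)) 0L else k))
  }
  nc <- nchar(peptides)
  if (is.null(k)) k <- nc[1L]
  if (any(nc != k)) {
    stop("all peptides must have length ", k, call. = FALSE)
  }
  matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
         nrow = length(peptides), ncol = k, byrow = TRUE)
}

## TRUE for strings composed only of the canonical alphabet.
isCanonical <- function(x) {
  !grepl(sprintf("[^%s]", paste(aminoAcids(), collapse = "")), x)
}

assertPeptides9 <- function(x, what = "peptides") {
  if (length(x) && any(nchar(x) != 9L)) {
    stop(what, " must all be 9mers (9 amino acids)", call. = FALSE)
  }
  invisible(x)
}
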