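#' Amino-acid substitution matrices
#'
#' `blosum62()` returns the BLOSUM62 substitution matrix restricted to the
#' 20 standard amino acids, taken from the table shipped with Biostrings.
#' `substitution_matrix()` validates an arbitrary user matrix.
#'
#' Scores are dimensionless log-odds units.  The `X` wildcard is handled
#' outside the matrix: it scores 0 against every residue (ambiguous
#' translation products are common in transcriptome data and should
#' neither reward nor punish an alignment column).
#'
#' @param scores Square numeric matrix with identical row and column
#'   names covering the 20-letter amino-acid alphabet.
#' @param name Label carried along for reporting.
#' @return An object of class `substitution_matrix`: the 20x20 score
#'   matrix with a `name` attribute.
#' @examples
#' sm <- blosum62()
#' sm["A", "A"]  # 4
#' @export
substitution_matrix <- function(scores, name = "custom") {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("'scores' must have row and column names", call. = FALSE)
  missing <- setdiff(AA_ALPHABET, rownames(scores))
  if (length(missing))
    stop("substitution matrix lacks rows for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  scores <- scores[AA_ALPHABET, AA_ALPHABET]
  if (!isTRUE(all.equal(scores, t(scores), tolerance = 0)))
    stop("substitution matrix must be symmetric", call. = FALSE)
  structure(scores, name = name, class = c("substitution_matrix", "matrix"))
}

#' @rdname substitution_matrix
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  substitution_matrix(env$BLOSUM62[AA_ALPHABET, AA_ALPHABET],
                      name = "BLOSUM62")
}

# Extend a 20x20 matrix to the internal 22x22 code space (gap, 20 aa, X).
# Gap and X rows/columns are zero; gap penalties are applied by the DP,
# never through this matrix.
extend_matrix <- function(sm) {
  s <- matrix(0, 22L, 22L)
  s[2:21, 2:21] <- unclass(sm)[AA_ALPHABET, AA_ALPHABET]
  s
}
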