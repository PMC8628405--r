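#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment of two protein sequences.  A
#' gap of length k costs `gap_open + k * gap_extend` (the opening column
#' is charged both the open and the first extension), and terminal gaps
#' are penalized like internal ones, so coordinates are mapped
#' end-to-end — the property the site-mapping stage relies on.
#'
#' Ties in the traceback prefer an aligned column, then a gap in the
#' query, then a gap in the reference, so results are deterministic.
#' `X` is tolerated as a wildcard scoring 0 against anything.
#'
#' @param query,ref Residue strings over the 20-letter amino-acid
#'   alphabet (plus `X`).
#' @param sm A [substitution_matrix], by default BLOSUM62.
#' @param gap_open,gap_extend Nonnegative gap penalties (positive
#'   numbers; they are subtracted).  Requires
#'   `gap_open >= gap_extend >= 0`.
#' @param query_id,ref_id Ids carried into the result.
#' @return An object of class `pairwise_alignment`: list with
#'   `query_id`, `ref_id`, `aligned_query`, `aligned_ref`, `score`.
#' @examples
#' aln <- nw_align("ACD", "ACD")
#' aln$score  # 4 + 9 + 6 = 19
#' @export
nw_align <- function(query, ref, sm = blosum62(), gap_open = 11,
                     gap_extend = 1, query_id = "query", ref_id = "ref") {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(ref), length(ref) == 1L)
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0",
         call. = FALSE)
  if (nchar(query) == 0L && nchar(ref) == 0L)
    stop("both sequences are empty", call. = FALSE)

  q <- encode_residues(query, what = sprintf("query '%s'", query_id))
  r <- encode_residues(ref, what = sprintf("reference '%s'", ref_id))
  if (any(q == GAP_CODE) || any(r == GAP_CODE))
    stop("input sequences must not contain gap characters", call. = FALSE)

  if (length(q) == 0L) {
    return(new_pairwise_alignment(query_id, ref_id,
                                  strrep("-", length(r)), ref,
                                  -(gap_open + length(r) * gap_extend)))
  }
  if (length(r) == 0L) {
    return(new_pairwise_alignment(query_id, ref_id,
                                  query, strrep("-", length(q)),
                                  -(gap_open + length(q) * gap_extend)))
  }

  s22 <- extend_matrix(sm)
  colscore <- s22[q + 1L, r + 1L, drop = FALSE]
  res <- C_gotoh(colscore, gap_open, gap_extend)

  qa <- character(length(res$moves))
  ra <- character(length(res$moves))
  i <- 0L; j <- 0L
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (k in seq_along(res$moves)) {
    mv <- res$moves[k]
    if (mv == 1L) { i <- i + 1L; j <- j + 1L; qa[k] <- qc[i]; ra[k] <- rc[j] }
    else if (mv == 2L) { j <- j + 1L; qa[k] <- "-"; ra[k] <- rc[j] }
    else { i <- i + 1L; qa[k] <- qc[i]; ra[k] <- "-" }
  }
  new_pairwise_alignment(query_id, ref_id,
                         paste(qa, collapse = ""),
                         paste(ra, collapse = ""),
                         res$score)
}

new_pairwise_alignment <- function(query_id, ref_id, aligned_query,
                                   aligned_ref, score) {
  structure(list(query_id = query_id, ref_id = ref_id,
                 aligned_query = aligned_query,
                 aligned_ref = aligned_ref,
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global affine-gap alignment (score %.6g)\n", x$score))
  cat(sprintf("  %s: %s\n", x$query_id, x$aligned_query))
  cat(sprintf("  %s: %s\n", x$ref_id, x$aligned_ref))
  invisible(x)
}

#' Evaluate the affine-gap objective on an existing alignment
#'
#' Sums substitution scores over aligned residue columns and charges
#' `gap_open + k * gap_extend` for every maximal gap run of length k.
#' Columns that are gap in both rows are skipped (they can arise when a
#' pair of rows is projected out of a larger multiple alignment).
#'
#' @param aligned_a,aligned_b Gapped rows of equal length.
#' @inheritParams nw_align
#' @return Numeric score.
#' @export
alignment_score <- function(aligned_a, aligned_b, sm = blosum62(),
                            gap_open = 11, gap_extend = 1) {
  a <- encode_residues(aligned_a, "aligned row a")
  b <- encode_residues(aligned_b, "aligned row b")
  if (length(a) != length(b))
    stop("aligned rows differ in length", call. = FALSE)
  keep <- !(a == GAP_CODE & b == GAP_CODE)
  a <- a[keep]; b <- b[keep]
  s22 <- extend_matrix(sm)
  both <- a != GAP_CODE & b != GAP_CODE
  score <- sum(s22[cbind(a[both] + 1L, b[both] + 1L)])
  for (g in list(a == GAP_CODE, b == GAP_CODE)) {
    if (any(g)) {
      runs <- rle(g)
      lens <- runs$lengths[runs$values]
      score <- score - sum(gap_open + lens * gap_extend)
    }
  }
  score
}

#' Proportion of differing sites between two aligned rows
#'
#' The p-distance: the fraction of mismatching columns among columns
#' where both rows carry a residue.  Columns with a gap in either row
#' are excluded by the mask; comparisons involving the `X` wildcard
#' count as mismatches (an ambiguous residue is never evidence of
#' identity).
#'
#' @param row_a,row_b Gapped rows of equal length sharing at least one
#'   residue-vs-residue column.
#' @return A number in \[0, 1\].
#' @examples
#' pdistance("AC", "AD")    # 0.5
#' pdistance("A-CD", "AEC-")  # 0 over the 2 shared columns
#' @export
pdistance <- function(row_a, row_b) {
  a <- encode_residues(row_a, "row a")
  b <- encode_residues(row_b, "row b")
  if (length(a) != length(b))
    stop("rows differ in length", call. = FALSE)
  shared <- a != GAP_CODE & b != GAP_CODE
  if (!any(shared))
    stop("rows share no non-gap columns", call. = FALSE)
  a <- a[shared]; b <- b[shared]
  mean(a != b | a == X_CODE)
}
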