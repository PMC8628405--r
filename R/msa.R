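#' Multiple sequence alignment container
#'
#' An `msa` is an ordered set of equal-length gapped rows with unique
#' ids.  Construction validates equal lengths, id uniqueness and the
#' absence of all-gap columns.
#'
#' @param rows Named character vector of gapped rows.
#' @return An object of class `msa`.
#' @export
msa <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("msa rows must be named", call. = FALSE)
  if (anyDuplicated(names(rows)))
    stop("duplicate row ids: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "),
         call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("msa rows differ in length", call. = FALSE)
  m <- as_char_matrix(rows)
  if (ncol(m) > 0L && any(colSums(m != "-") == 0L))
    stop("msa contains an all-gap column", call. = FALSE)
  structure(list(rows = rows, column_count = unname(widths[1L])),
            class = "msa")
}

as_char_matrix <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d rows x %d columns\n",
              length(x$rows), x$column_count))
  show <- utils::head(x$rows, 6L)
  for (id in names(show)) {
    row <- show[[id]]
    if (nchar(row) > 60L) row <- paste0(substr(row, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", id, row))
  }
  if (length(x$rows) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read/write an msa as aligned FASTA
#' @param path File path.
#' @param x An `msa`.
#' @export
read_msa <- function(path) msa(read_fasta(path))

#' @rdname read_msa
#' @export
write_msa <- function(x, path) write_fasta(x$rows, path)

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on pairwise p-distances (each
#' pair aligned globally first), then merges sub-alignments by
#' profile-profile Gotoh alignment in postorder.  Profile columns are
#' scored by the mean pairwise substitution score over all row pairs
#' (gap-vs-residue contributes 0); once a gap is inserted into a merged
#' profile it is never removed.
#'
#' With exactly two sequences this reduces to [nw_align()].
#'
#' @param seqs Named character vector of two or more ungapped sequences.
#' @inheritParams nw_align
#' @return An [msa] with rows in the input order.
#' @export
progressive_msa <- function(seqs, sm = blosum62(), gap_open = 11,
                            gap_extend = 1) {
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs)))
    stop("sequences must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)

  if (length(seqs) == 2L) {
    aln <- nw_align(seqs[[1L]], seqs[[2L]], sm, gap_open, gap_extend,
                    query_id = names(seqs)[1L], ref_id = names(seqs)[2L])
    return(msa(setNames(c(aln$aligned_query, aln$aligned_ref),
                        names(seqs))))
  }

  ids <- names(seqs)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      aln <- nw_align(seqs[[i]], seqs[[j]], sm, gap_open, gap_extend,
                      query_id = ids[i], ref_id = ids[j])
      D[i, j] <- D[j, i] <- pdistance(aln$aligned_query, aln$aligned_ref)
    }
  }
  guide <- neighbor_joining(D)

  s22 <- extend_matrix(sm)
  profiles <- lapply(ids, function(id)
    matrix(encode_residues(seqs[[id]], id), nrow = 1L,
           dimnames = list(id, NULL)))
  names(profiles) <- ids

  merged <- merge_by_guide(guide, profiles, s22, gap_open, gap_extend)
  rows <- vapply(seq_len(nrow(merged)), function(i)
    decode_residues(merged[i, ]), "")
  names(rows) <- rownames(merged)
  msa(rows[ids])
}

# Postorder traversal of the guide tree, merging child profiles
# left-to-right at every internal node (the basal trifurcation of the
# unrooted NJ tree merges its three children sequentially).
merge_by_guide <- function(guide, profiles, s22, gap_open, gap_extend) {
  edge <- guide$edge
  ntip <- length(guide$tip.label)
  build <- function(node) {
    if (node <= ntip) return(profiles[[guide$tip.label[node]]])
    kids <- edge[edge[, 1L] == node, 2L]
    Reduce(function(a, b) merge_profiles(a, b, s22, gap_open, gap_extend),
           lapply(kids, build))
  }
  build(ntip + 1L)
}

merge_profiles <- function(A, B, s22, gap_open, gap_extend) {
  cntA <- profile_counts(A)
  cntB <- profile_counts(B)
  colscore <- (cntA %*% s22 %*% t(cntB)) / (nrow(A) * nrow(B))
  res <- C_gotoh(colscore, gap_open, gap_extend)
  moves <- res$moves
  L <- length(moves)
  out <- matrix(GAP_CODE, nrow(A) + nrow(B), L,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- 0L; ib <- 0L
  a_rows <- seq_len(nrow(A)); b_rows <- nrow(A) + seq_len(nrow(B))
  for (k in seq_len(L)) {
    mv <- moves[k]
    if (mv != 2L) { ia <- ia + 1L; out[a_rows, k] <- A[, ia] }
    if (mv != 3L) { ib <- ib + 1L; out[b_rows, k] <- B[, ib] }
  }
  out
}

profile_counts <- function(P) {
  L <- ncol(P)
  cnt <- matrix(0, L, 22L)
  for (code in 0:21) cnt[, code + 1L] <- colSums(P == code)
  cnt
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Sum over all row pairs of the affine-gap objective evaluated on the
#' pair projection (columns gapped in both rows of the pair are
#' dropped, so each pair is scored as its own pairwise alignment).
#'
#' @param x An [msa].
#' @inheritParams nw_align
#' @return Numeric score.
#' @export
sp_score <- function(x, sm = blosum62(), gap_open = 11, gap_extend = 1) {
  ids <- names(x$rows)
  total <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1L), length(ids))) {
      total <- total + alignment_score(x$rows[[i]], x$rows[[j]],
                                       sm, gap_open, gap_extend)
    }
  }
  total
}

#' Drop poorly occupied alignment columns
#'
#' Retains the columns whose non-gap fraction is at least
#' `min_occupancy`; a reproducible stand-in for manual removal of gappy,
#' low-quality alignment regions before tree inference.
#'
#' @param x An [msa].
#' @param min_occupancy Threshold in (0, 1]; default 0.5.
#' @return A filtered [msa] (row order preserved).
#' @export
filter_columns <- function(x, min_occupancy = 0.5) {
  stopifnot(inherits(x, "msa"))
  if (!(min_occupancy > 0 && min_occupancy <= 1))
    stop("min_occupancy must be in (0, 1]", call. = FALSE)
  m <- as_char_matrix(x$rows)
  keep <- colMeans(m != "-") >= min_occupancy
  if (!any(keep))
    stop("no columns meet the occupancy threshold", call. = FALSE)
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  msa(setNames(rows, names(x$rows)))
}
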