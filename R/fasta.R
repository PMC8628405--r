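#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings.  On read, sequence ids are the first
#' whitespace-delimited token of the header and `*` stop symbols are
#' stripped with a warning.  On write, sequences are wrapped at 60
#' columns.  Aligned FASTA (gapped rows) round-trips through the same
#' functions.
#'
#' @param path File path.
#' @param seqs Named character vector of (possibly gapped) sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  n_stop <- sum(vapply(gregexpr("*", seqs, fixed = TRUE),
                       function(m) sum(m > 0L), 0L))
  if (n_stop > 0L) {
    warning(sprintf("stripped %d '*' stop symbol(s) from %s",
                    n_stop, path), call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  seqs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}
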