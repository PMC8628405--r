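#' Poisson-corrected distance matrix from a multiple alignment
#'
#' For every pair of rows the p-distance is computed over their shared
#' non-gap columns and corrected as d = -ln(1 - p), the expected number
#' of substitutions per site under a Poisson model.  Because the
#' correction diverges as p approaches 1, p is capped at `cap` (default
#' 0.95) and capped entries are reported with a warning; the number of
#' capped entries is also attached as attribute `n_capped`.
#'
#' @param x An [msa].
#' @param cap Saturation cap applied to p before correction.
#' @param warn Emit a warning when entries are capped (the count is
#'   always recorded in the `n_capped` attribute).
#' @return Symmetric numeric matrix (substitutions/site) with row ids as
#'   dimnames and zero diagonal.
#' @export
poisson_distance <- function(x, cap = 0.95, warn = TRUE) {
  stopifnot(inherits(x, "msa"))
  m <- as_char_matrix(x$rows)
  pdist_matrix_correct(m, cap = cap, warn = warn)
}

# Core shared with the bootstrap loop, which resamples the character
# matrix directly rather than re-building msa objects.
pdist_matrix_correct <- function(m, cap = 0.95, warn = TRUE) {
  ids <- rownames(m)
  n <- nrow(m)
  codes <- m != "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  n_capped <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq((i + 1L), n)) {
      shared <- codes[i, ] & codes[j, ]
      if (!any(shared))
        stop(sprintf("rows '%s' and '%s' share no non-gap columns",
                     ids[i], ids[j]), call. = FALSE)
      p <- mean(m[i, shared] != m[j, shared] |
                  m[i, shared] == "X" |
                  m[j, shared] == "X")
      if (p > cap) { p <- cap; n_capped <- n_capped + 1L }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  if (n_capped > 0L && warn)
    warning(sprintf(
      "%d pairwise distance(s) saturated (p > %.2f); capped at -ln(%.2f)",
      n_capped, cap, 1 - cap), call. = FALSE)
  attr(d, "n_capped") <- n_capped
  d
}
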