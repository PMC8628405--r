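#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with Studier-Keppler distance updates.
#' Ties in the Q criterion are broken lexicographically on the pair of
#' node sort keys (a node's key is the smallest leaf label it
#' subtends), so the topology is deterministic even for degenerate
#' matrices.  Negative branch lengths are clamped to zero with the
#' deficit moved to the adjacent (sister) branch, preserving the joined
#' pair's distance.
#'
#' @param D Symmetric numeric matrix with zero diagonal and unique
#'   dimnames (at least 3 labels); substitutions/site.
#' @return An unrooted `ape::phylo` tree with branch lengths (basal
#'   trifurcation, as usual for NJ).
#' @examples
#' D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(D)
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || !is.numeric(D))
    stop("'D' must be a numeric matrix", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels) || anyDuplicated(labels))
    stop("'D' must have unique dimnames", call. = FALSE)
  if (nrow(D) < 3L)
    stop("neighbor joining needs at least 3 labels", call. = FALSE)
  if (any(!is.finite(D)))
    stop("'D' contains non-finite entries", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0))
    stop("'D' must be symmetric with zero diagonal", call. = FALSE)

  d <- unname(D)
  nodes <- vapply(labels, quote_newick_label, "")  # newick fragments
  keys <- labels                                   # smallest subtended leaf

  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      pair_key <- apply(cand, 1L, function(ij) {
        k <- sort(c(keys[ij[1L]], keys[ij[2L]]))
        paste(k, collapse = "\r")
      })
      cand <- cand[order(pair_key)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]

    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; li <- max(li, 0) }

    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_bl(li),
                        nodes[j], fmt_bl(lj))
    new_key <- min(keys[i], keys[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    keys <- c(keys[keep], new_key)
  }

  a <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  b <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  cc <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nodes[1L], fmt_bl(a), nodes[2L], fmt_bl(b),
                    nodes[3L], fmt_bl(cc))
  ape::read.tree(text = newick)
}

fmt_bl <- function(x) sprintf("%.12g", x)

quote_newick_label <- function(x) {
  if (grepl("[^A-Za-z0-9_.|-]", x)) paste0("'", gsub("'", "''", x), "'")
  else x
}

#' Read and write Newick trees
#'
#' Wrappers over ape keeping branch lengths to 10 significant digits so
#' trees round-trip losslessly through files.
#'
#' @param path File path.
#' @param tree An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path,
                          call. = FALSE)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
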