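# Independent oracles and fixture generators.  Everything here is
# deliberately written from first principles (no calls into the package
# code paths they are used to check).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 straight from Biostrings' shipped table (not via blosum62()).
oracle_blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62[AA20, AA20]
})

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                collapse = "")

# Score a gapped alignment under the affine model: substitution scores
# over residue columns, each maximal gap run of length k costing
# open + k * ext.
oracle_aln_score <- function(qa, ra, S = oracle_blosum62,
                             open = 11, ext = 1) {
  q <- strsplit(qa, "")[[1]]
  r <- strsplit(ra, "")[[1]]
  stopifnot(length(q) == length(r))
  score <- 0
  for (g in list(q == "-", r == "-")) {
    runs <- rle(g)
    score <- score - sum(open + runs$lengths[runs$values] * ext)
  }
  both <- q != "-" & r != "-"
  score + sum(S[cbind(q[both], r[both])])
}

# Exhaustive enumeration of every global alignment (three moves,
# affine gap accounting carried through the recursion); returns the
# optimum score.  Only feasible for short sequences.
oracle_best_score <- function(a, b, S = oracle_blosum62,
                              open = 11, ext = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, S[ac[i], bc[j]] + rec(i + 1L, j + 1L, 1L))
    if (j <= m)
      best <- max(best,
                  -(ext + if (last != 2L) open else 0) + rec(i, j + 1L, 2L))
    if (i <= n)
      best <- max(best,
                  -(ext + if (last != 3L) open else 0) + rec(i + 1L, j, 3L))
    best
  }
  rec(1L, 1L, 0L)
}

# Random tree with strictly positive branch lengths plus its exact
# additive (patristic) distance matrix.
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(ntaxa))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Clade of the query by brute force: root on the outgroup MRCA, list
# every rooted clade (tip set below each node), take the smallest one
# containing the query and any reference, and apply the only-references
# rule directly.
oracle_assign <- function(tree, cmap, query_id) {
  rooted <- ape::root(tree, outgroup = cmap$outgroup,
                      resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  refs <- unlist(cmap$clades, use.names = FALSE)
  clade_of <- stats::setNames(rep(names(cmap$clades),
                                  lengths(cmap$clades)), refs)
  clades <- lapply(seq_len(ntip + rooted$Nnode), function(nd) {
    if (nd <= ntip) rooted$tip.label[nd]
    else ape::extract.clade(rooted, nd)$tip.label
  })
  cand <- Filter(function(tips) query_id %in% tips &&
                   any(tips %in% refs), clades)
  sizes <- vapply(cand, length, 0L)
  tips <- cand[[which.min(sizes)]]
  members <- setdiff(tips, query_id)
  hit <- unique(clade_of[members[members %in% refs]])
  if (length(hit) == 1L && all(members %in% refs)) unname(hit)
  else "unassigned"
}

# Small helper used across test files: a deterministic toy msa.
toy_msa <- function() {
  msa(c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL", s3 = "ACDKFGHIKL",
        s4 = "AC-EFGH-KL"))
}
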