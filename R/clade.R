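#' Labeled reference clades for query placement
#'
#' A clade map lists, for each clade label, the reference leaf ids
#' belonging to it, plus a mandatory outgroup set used for rooting.
#' All sets must be pairwise disjoint.
#'
#' The TSV format is two columns (`leaf_id`, `clade_label`) with a
#' header row; the label `outgroup` is reserved for the outgroup set.
#'
#' @param clades Named list of character vectors (clade label ->
#'   reference leaf ids).
#' @param outgroup Character vector of outgroup leaf ids.
#' @return An object of class `clade_map`.
#' @export
clade_map <- function(clades, outgroup) {
  stopifnot(is.list(clades), length(clades) >= 1L,
            is.character(outgroup), length(outgroup) >= 1L)
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop("clades must be a named list", call. = FALSE)
  if ("outgroup" %in% names(clades))
    stop("'outgroup' is a reserved label; pass it via the outgroup argument",
         call. = FALSE)
  if (any(lengths(clades) == 0L))
    stop("every clade needs at least one reference leaf", call. = FALSE)
  all_ids <- c(unlist(clades, use.names = FALSE), outgroup)
  if (anyDuplicated(all_ids))
    stop("clade/outgroup sets overlap on: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  structure(list(clades = lapply(clades, as.character),
                 outgroup = as.character(outgroup)),
            class = "clade_map")
}

#' @rdname clade_map
#' @param path Two-column TSV with header `leaf_id<TAB>clade_label`.
#' @export
read_clade_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("leaf_id", "clade_label") %in% names(tab)))
    stop("clade TSV needs columns 'leaf_id' and 'clade_label'",
         call. = FALSE)
  og <- tab$leaf_id[tab$clade_label == "outgroup"]
  if (length(og) == 0L)
    stop("clade TSV has no 'outgroup' entries", call. = FALSE)
  rest <- tab[tab$clade_label != "outgroup", , drop = FALSE]
  clade_map(split(rest$leaf_id, rest$clade_label), og)
}

#' @rdname clade_map
#' @param x A `clade_map`.
#' @export
write_clade_map <- function(x, path) {
  df <- data.frame(
    leaf_id = c(unlist(x$clades, use.names = FALSE), x$outgroup),
    clade_label = c(rep(names(x$clades), lengths(x$clades)),
                    rep("outgroup", length(x$outgroup))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Root an unrooted tree on the outgroup.  If the outgroup is a clean
# split, this is the edge leading to its most recent common ancestor;
# on noisy bootstrap replicates where the outgroup is not monophyletic,
# the edge maximizing (outgroup leaves minus non-outgroup leaves) on
# the outgroup side is used, ties broken by the sorted label string of
# that side.
root_on_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  missing <- setdiff(outgroup, tips)
  if (length(missing))
    stop("outgroup leaves missing from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  below <- tips_below(tree)
  ntip <- length(tips)
  best <- NULL; best_score <- -Inf; best_key <- ""
  for (k in seq_len(nrow(tree$edge))) {
    child_tips <- tips[below[[tree$edge[k, 2L]]]]
    for (side in list(child_tips, setdiff(tips, child_tips))) {
      if (length(side) == 0L || length(side) == ntip) next
      score <- sum(side %in% outgroup) - sum(!(side %in% outgroup))
      key <- paste(sort(side), collapse = "\r")
      if (score > best_score ||
          (score == best_score && key < best_key)) {
        best <- side; best_score <- score; best_key <- key
      }
    }
  }
  ape::root(tree, outgroup = best, resolve.root = TRUE)
}

# Tip indices subtended by every node (tips included as themselves).
tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    res[[edge[k, 1L]]] <- c(res[[edge[k, 1L]]], res[[edge[k, 2L]]])
  res
}

#' Assign a query leaf to a labeled clade
#'
#' The tree is rooted on the outgroup, then the smallest rooted clade
#' containing the query and at least one reference leaf is inspected:
#' the query is assigned clade C iff that clade contains only
#' references of C besides the query itself.  Outgroup leaves or
#' references of a second clade inside it yield `"unassigned"`.
#'
#' @param tree Unrooted `ape::phylo` containing the query, every
#'   reference and at least one outgroup leaf.
#' @param cmap A [clade_map].
#' @param query_id Leaf id of the query.
#' @return A clade label or `"unassigned"`.
#' @export
assign_clade <- function(tree, cmap, query_id) {
  stopifnot(inherits(cmap, "clade_map"))
  tips <- tree$tip.label
  needed <- c(query_id, unlist(cmap$clades, use.names = FALSE),
              cmap$outgroup)
  missing <- setdiff(needed, tips)
  if (length(missing))
    stop("leaves missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)

  rooted <- root_on_outgroup(tree, cmap$outgroup)
  below <- tips_below(rooted)
  refs <- unlist(cmap$clades, use.names = FALSE)
  clade_of <- rep(names(cmap$clades), lengths(cmap$clades))
  names(clade_of) <- refs

  node <- which(rooted$tip.label == query_id)
  root_node <- length(rooted$tip.label) + 1L
  repeat {
    parent <- rooted$edge[rooted$edge[, 2L] == node, 1L]
    if (length(parent) == 0L) break
    members <- setdiff(rooted$tip.label[below[[parent]]], query_id)
    if (any(members %in% refs)) {
      hit <- unique(clade_of[members[members %in% refs]])
      only_refs <- all(members %in% refs)
      if (length(hit) == 1L && only_refs) return(unname(hit))
      return("unassigned")
    }
    if (parent == root_node) break
    node <- parent
  }
  "unassigned"
}

#' Bootstrap support for clade assignment
#'
#' Nonparametric bootstrap over alignment columns: each replicate
#' resamples columns with replacement, recomputes Poisson-corrected
#' distances and an NJ tree, and runs [assign_clade()] for every query.
#' The reported assignment is the modal label over successful
#' replicates (ties give `"unassigned"`) and the support is the modal
#' label's replicate fraction.  Replicates where some pair shares no
#' sampled residue column are recorded as failures and excluded.
#'
#' All queries share the same replicates, so a multi-query run is both
#' cheaper and internally consistent.
#'
#' @param x An [msa] containing references, outgroup and queries.
#' @param cmap A [clade_map].
#' @param query_ids Leaf ids to place; defaults to every row of `x`
#'   not listed in `cmap`.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed; required, so runs are reproducible.
#' @return A `data.frame` (class `clade_assignment`) with columns
#'   `query_id`, `assigned`, `support`, `n_successful_reps`, plus a
#'   `replicate_labels` attribute holding the per-replicate label
#'   matrix.
#' @export
bootstrap_clade_support <- function(x, cmap, query_ids = NULL,
                                    n_reps = 100L, seed) {
  stopifnot(inherits(x, "msa"), inherits(cmap, "clade_map"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the bootstrap", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  listed <- c(unlist(cmap$clades, use.names = FALSE), cmap$outgroup)
  if (is.null(query_ids))
    query_ids <- setdiff(names(x$rows), listed)
  if (length(query_ids) == 0L)
    stop("no query leaves to assign", call. = FALSE)
  missing_rows <- setdiff(c(query_ids, listed), names(x$rows))
  if (length(missing_rows))
    stop("rows missing from alignment: ",
         paste(missing_rows, collapse = ", "), call. = FALSE)

  m <- as_char_matrix(x$rows)[c(listed, query_ids), , drop = FALSE]
  labels <- matrix(NA_character_, n_reps, length(query_ids),
                   dimnames = list(NULL, query_ids))

  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      res <- tryCatch({
        d <- pdist_matrix_correct(m[, cols, drop = FALSE], warn = FALSE)
        tree <- neighbor_joining(d)
        vapply(query_ids, function(q) assign_clade(tree, cmap, q), "")
      }, error = function(e) NULL)
      if (!is.null(res)) labels[rep, ] <- res
    }
  })

  out <- do.call(rbind, lapply(query_ids, function(q) {
    lab <- labels[, q]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L)
      return(data.frame(query_id = q, assigned = "unassigned",
                        support = 0, n_successful_reps = 0L))
    tab <- sort(table(lab), decreasing = TRUE)
    top <- tab[tab == tab[1L]]
    assigned <- if (length(top) == 1L) names(top) else "unassigned"
    data.frame(query_id = q, assigned = assigned,
               support = unname(tab[1L]) / length(lab),
               n_successful_reps = length(lab))
  }))
  rownames(out) <- NULL
  attr(out, "replicate_labels") <- labels
  class(out) <- c("clade_assignment", class(out))
  out
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
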