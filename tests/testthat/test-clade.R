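cmap_12 <- function() {
  clade_map(list(retinochrome = c("ret1", "ret2", "ret3"),
                 RGR = c("rgr1", "rgr2", "rgr3"),
                 peropsin = c("per1", "per2", "per3")),
            outgroup = c("og1", "og2"))
}

tree_12 <- function(query_at = "retinochrome") {
  graft <- c(retinochrome = "(ret1:1,ret2:1,ret3:1,Q:1):1",
             RGR = "(rgr1:1,rgr2:1,rgr3:1,Q:1):1",
             peropsin = "(per1:1,per2:1,per3:1,Q:1):1",
             backbone = "Q:1")
  blocks <- c(retinochrome = "(ret1:1,ret2:1,ret3:1):1",
              RGR = "(rgr1:1,rgr2:1,rgr3:1):1",
              peropsin = "(per1:1,per2:1,per3:1):1")
  blocks[query_at] <- graft[query_at]
  extra <- if (query_at == "backbone") ",Q:1" else ""
  ape::read.tree(text = sprintf("((%s,%s,%s%s):1,(og1:1,og2:1):1);",
                                blocks[1], blocks[2], blocks[3], extra))
}

test_that("a query inside one clade's subtree is assigned that clade", {
  for (cl in c("retinochrome", "RGR", "peropsin")) {
    expect_identical(assign_clade(tree_12(cl), cmap_12(), "Q"), cl)
  }
})

test_that("a query on the backbone between clades is unassigned", {
  expect_identical(assign_clade(tree_12("backbone"), cmap_12(), "Q"),
                   "unassigned")
})

test_that("assignment agrees with brute-force clade enumeration on random trees", {
  cmap <- cmap_12()
  leaves <- c(unlist(cmap$clades, use.names = FALSE), cmap$outgroup, "Q")
  set.seed(2024)
  for (k in 1:25) {
    tr <- ape::rtree(length(leaves), tip.label = sample(leaves))
    # keep the outgroup a clean split so the oracle rooting is defined
    if (!ape::is.monophyletic(tr, cmap$outgroup)) next
    expect_identical(assign_clade(tr, cmap, "Q"),
                     oracle_assign(tr, cmap, "Q"))
  }
})

test_that("assignment is invariant to newick re-serialization", {
  tr <- tree_12("RGR")
  rt <- ape::read.tree(text = ape::write.tree(tr))
  expect_identical(assign_clade(tr, cmap_12(), "Q"),
                   assign_clade(rt, cmap_12(), "Q"))
})

test_that("missing leaves are reported by name", {
  tr <- tree_12()
  cmap <- clade_map(list(retinochrome = c("ret1", "nope")),
                    outgroup = "og1")
  expect_error(assign_clade(tr, cmap, "Q"), "nope")
})

test_that("clade maps round-trip through TSV and require an outgroup", {
  cmap <- cmap_12()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clade_map(cmap, path)
  back <- read_clade_map(path)
  expect_equal(back$clades[order(names(back$clades))],
               cmap$clades[order(names(cmap$clades))])
  expect_setequal(back$outgroup, cmap$outgroup)

  no_og <- data.frame(leaf_id = c("a", "b"), clade_label = c("x", "x"))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(no_og, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clade_map(path2), "outgroup")
})

boot_fixture <- function(n_sites = 300) {
  set.seed(404)
  anchor <- random_seq(n_sites)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- vapply(ch[idx], function(x) sample(setdiff(AA20, x), 1), "")
    paste(ch, collapse = "")
  }
  # three tight clusters radiating from a central ancestor, each with
  # its own stem mutations so every cluster is a genuine clade; the
  # query is identical to the near references, and distances stay well
  # below the saturation cap so the matrix is solidly tree-like
  near <- mutate(anchor, 40)
  far <- mutate(anchor, 60)
  og <- mutate(anchor, 90)
  rows <- c(ref1 = near, ref2 = near, Q = near,
            far1 = far, far2 = far, og1 = og, og2 = og)
  list(msa = msa(rows),
       cmap = clade_map(list(near = c("ref1", "ref2"),
                             far = c("far1", "far2")),
                        outgroup = c("og1", "og2")))
}

test_that("identical query and references get full bootstrap support", {
  fx <- boot_fixture()
  asg <- suppressWarnings(
    bootstrap_clade_support(fx$msa, fx$cmap, "Q", n_reps = 50, seed = 9))
  expect_identical(asg$assigned, "near")
  expect_equal(asg$support, 1.0)
  expect_equal(asg$n_successful_reps, 50L)
})

test_that("bootstrap is reproducible from the seed and needs one", {
  fx <- boot_fixture()
  a <- suppressWarnings(bootstrap_clade_support(fx$msa, fx$cmap, "Q",
                                                n_reps = 20, seed = 33))
  b <- suppressWarnings(bootstrap_clade_support(fx$msa, fx$cmap, "Q",
                                                n_reps = 20, seed = 33))
  expect_identical(a, b)
  expect_error(bootstrap_clade_support(fx$msa, fx$cmap, "Q", n_reps = 20),
               "seed")
})

test_that("bootstrap support is invariant to leaf order permutation", {
  fx <- boot_fixture()
  perm <- msa(fx$msa$rows[c(4, 2, 7, 1, 5, 3, 6)])
  a <- suppressWarnings(bootstrap_clade_support(fx$msa, fx$cmap, "Q",
                                                n_reps = 30, seed = 5))
  b <- suppressWarnings(bootstrap_clade_support(perm, fx$cmap, "Q",
                                                n_reps = 30, seed = 5))
  expect_identical(a$assigned, b$assigned)
  expect_equal(a$support, b$support)
})
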