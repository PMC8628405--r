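two_clade_cfg <- function(seed, L = 120, bl = 0.2,
                          sites = list()) {
  tpl <- sprintf(
    "(((A1:%g,A2:%g):%g,(B1:%g,B2:%g):%g):%g,(og1:%g,og2:%g):%g);",
    bl, bl, bl, bl, bl, bl, bl, bl, bl, bl)
  sim_config(tpl, L,
             c(A1 = "cladeA", A2 = "cladeA", B1 = "cladeB",
               B2 = "cladeB", og1 = "outgroup", og2 = "outgroup"),
             sites, seed = seed)
}

test_that("zero branch lengths copy the root to every leaf", {
  cfg <- two_clade_cfg(seed = 3, bl = 0)
  sim <- simulate_alignment(cfg)
  expect_true(all(sim$leaf_seqs == sim$root_seq))
  expect_identical(unname(sim$true_alignment$rows), unname(sim$leaf_seqs))
})

test_that("simulation is reproducible from the seed", {
  a <- simulate_alignment(two_clade_cfg(seed = 42))
  b <- simulate_alignment(two_clade_cfg(seed = 42))
  expect_identical(a$leaf_seqs, b$leaf_seqs)
  expect_identical(a$root_seq, b$root_seq)
  c <- simulate_alignment(two_clade_cfg(seed = 43))
  expect_false(identical(a$leaf_seqs, c$leaf_seqs))
})

test_that("constrained sites carry the planted residue in every clade leaf", {
  sites <- list("10" = c(root = "E", cladeA = "E", cladeB = "F"),
                "50" = c(cladeA = "W", outgroup = "C"))
  sim <- simulate_alignment(two_clade_cfg(seed = 8, sites = sites))
  at <- function(ids, p) substr(sim$leaf_seqs[ids], p, p)
  expect_true(all(at(c("A1", "A2"), 10) == "E"))
  expect_true(all(at(c("B1", "B2"), 10) == "F"))
  expect_true(all(at(c("A1", "A2"), 50) == "W"))
  expect_true(all(at(c("og1", "og2"), 50) == "C"))
  expect_identical(substr(sim$root_seq, 10, 10), "E")
})

test_that("malformed configs name the offending field", {
  expect_error(two_clade_cfg(seed = 1, L = 0), "root_seq_length")
  expect_error(two_clade_cfg(seed = 1,
                             sites = list("999" = c(cladeA = "E"))),
               "constrained_sites")
  expect_error(two_clade_cfg(seed = 1,
                             sites = list("5" = c(nope = "E"))),
               "unknown clade label")
  expect_error(sim_config("(A:1,B:1);", 10, c(A = "x"), seed = 1),
               "clade_annotation")
  expect_error(sim_config("(A:1,B:1);", 10, c(A = "x", B = "x")),
               "seed")
})

test_that("single-branch divergence matches the equal-rates closed form", {
  t <- 0.3
  cfg <- sim_config(sprintf("(A:%g,B:0);", t), 10000,
                    c(A = "x", B = "x"), seed = 19)
  sim <- simulate_alignment(cfg)
  p_obs <- pdistance(sim$leaf_seqs[["A"]], sim$leaf_seqs[["B"]])
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * t))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("planting k matching residues yields a score of exactly k", {
  # zero-length branches isolate the planting logic from the noise
  positions <- seq(10L, 100L, by = 10L)
  ref_res <- c("W", "Y", "F", "C", "M", "Q", "M", "V", "M", "W")
  for (k in c(0L, 3L, 7L, 10L)) {
    sites <- list()
    for (i in seq_along(positions)) {
      plant <- c(root = ref_res[i],
                 cladeA = if (i <= k) ref_res[i] else "A",
                 cladeB = ref_res[i])
      sites[[as.character(positions[i])]] <- plant
    }
    sim <- simulate_alignment(two_clade_cfg(seed = 100 + k, bl = 0,
                                            sites = sites))
    scheme <- opsintools:::scheme_from_root(sim$root_seq,
                                            counterion_pos = 110L,
                                            rlbp1_pos = positions)
    prof <- profile_sequences(sim$leaf_seqs["A1"], scheme)[[1]]
    expect_equal(prof$rlbp1_score, k)
    expect_equal(profile_sequences(sim$leaf_seqs["B1"],
                                   scheme)[[1]]$rlbp1_score, 10L)
  }
})

test_that("a two-trial recovery run recovers every planted truth", {
  res <- recovery_experiment(n_trials = 2, seed = 5151, n_reps = 25)
  expect_equal(res$counterion_accuracy, 1.0)
  expect_equal(res$rlbp1_exact_rate, 1.0)
  expect_gte(res$clade_accuracy, 0.75)
  expect_identical(nrow(res$detail), 8L)
})
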