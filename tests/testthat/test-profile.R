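opsin <- packaged_scheme("bovine_rhodopsin")
rlbp1 <- packaged_scheme("rlbp1_synthetic")

mutate_at <- function(seq, pos, res) {
  substr(seq, pos, pos) <- res
  seq
}

profile1 <- function(seq, scheme = opsin, id = "q") {
  profile_sequences(setNames(seq, id), scheme)[[1]]
}

test_that("profiling a scheme reference against itself is all-match", {
  p <- profile1(opsin$reference_seq)
  expect_true(all(p$site_calls$status == "match"))
  expect_identical(unique(unname(p$pair_status)), "intact")
  expect_identical(unname(p$motif_status), "intact")
  expect_equal(p$signaling_intact_count, 5L)
  expect_identical(p$counterion_state, "charged")
  expect_identical(p$stability_prediction, "monostable-like")

  r <- profile1(rlbp1$reference_seq, rlbp1)
  expect_equal(r$rlbp1_score, 10L)
})

test_that("site mapping survives terminal insertions and internal deletions", {
  # identity: query positions equal reference positions
  aln <- nw_align(opsin$reference_seq, opsin$reference_seq,
                  ref_id = "bovine_rhodopsin")
  calls <- map_sites(aln, opsin)
  expect_equal(calls$query_position, calls$ref_position)

  # 5-residue N-terminal insertion shifts every query position by 5
  ins <- paste0("GGGGG", opsin$reference_seq)
  calls <- map_sites(nw_align(ins, opsin$reference_seq), opsin)
  expect_true(all(calls$status == "match"))
  expect_equal(calls$query_position, calls$ref_position + 5L)

  # deleting residues 110-116 leaves E113 unaligned
  del <- paste0(substr(opsin$reference_seq, 1, 109),
                substr(opsin$reference_seq, 117, nchar(opsin$reference_seq)))
  calls <- map_sites(nw_align(del, opsin$reference_seq), opsin)
  e113 <- calls[calls$site_label == "E113", ]
  expect_identical(e113$status, "unaligned")
  expect_true(is.na(e113$query_position))
})

test_that("map_sites rejects an alignment against the wrong reference", {
  aln <- nw_align("ACDEF", "ACDEF")
  expect_error(map_sites(aln, opsin), "bovine_rhodopsin")
})

test_that("counterion state drives the bistability prediction", {
  # uncharged residue at 113, as in retinochromes and other bistable opsins
  p <- profile1(mutate_at(opsin$reference_seq, 113, "F"))
  expect_identical(p$counterion_state, "uncharged")
  expect_identical(p$stability_prediction, "bistable-like")

  # D also counts as a charged counterion
  p <- profile1(mutate_at(opsin$reference_seq, 113, "D"))
  expect_identical(p$counterion_state, "charged")

  # query gapped across 113 is indeterminate
  del <- paste0(substr(opsin$reference_seq, 1, 105),
                substr(opsin$reference_seq, 121, nchar(opsin$reference_seq)))
  p <- profile1(del)
  expect_identical(p$counterion_state, "indeterminate")
  expect_identical(p$stability_prediction, "indeterminate")

  expect_error(classify_counterion(
    map_sites(nw_align(rlbp1$reference_seq, rlbp1$reference_seq,
                       ref_id = "rlbp1_synthetic"), rlbp1)),
    "no counterion site")
})

test_that("an X at a site never counts as a match", {
  p <- profile1(mutate_at(opsin$reference_seq, 113, "X"))
  expect_identical(p$counterion_state, "indeterminate")
  x83 <- profile1(mutate_at(opsin$reference_seq, 83, "X"))
  expect_identical(
    x83$site_calls$status[x83$site_calls$site_label == "D83"], "mismatch")
})

test_that("breaking P303 breaks the motif but no pair", {
  p <- profile1(mutate_at(opsin$reference_seq, 303, "S"))
  expect_identical(unname(p$motif_status), "broken")
  expect_true(all(p$pair_status == "intact"))
  expect_equal(p$signaling_intact_count, 4L)
  expect_identical(p$deviations, "P303:S")
})

test_that("a missing pair member breaks the pair and is listed as absent", {
  # delete a block around E247 so the residue is completely missing
  del <- paste0(substr(opsin$reference_seq, 1, 243),
                substr(opsin$reference_seq, 252, nchar(opsin$reference_seq)))
  p <- profile1(del)
  expect_identical(unname(p$pair_status["K231/E247"]), "broken")
  expect_true("E247:absent" %in% p$deviations)
})

test_that("rlbp1 score drops by exactly one per broken critical residue", {
  base <- rlbp1$reference_seq
  crit <- rlbp1$sites
  p <- profile1(mutate_at(base, 166, "A"), rlbp1)
  expect_equal(p$rlbp1_score, 9L)
  # monotonicity: mutate each critical residue in turn, then revert
  seq <- base
  for (k in seq_len(nrow(crit))) {
    seq <- mutate_at(seq, crit$ref_position[k], "A")
    expect_equal(profile1(seq, rlbp1)$rlbp1_score, 10L - k)
  }
  expect_equal(profile1(base, rlbp1)$rlbp1_score, 10L)
})

test_that("score_rlbp1 demands exactly ten critical sites", {
  calls <- map_sites(nw_align(opsin$reference_seq, opsin$reference_seq,
                              ref_id = "bovine_rhodopsin"), opsin)
  expect_error(score_rlbp1(calls), "exactly 10")
})

test_that("profiles are deterministic and complete", {
  a <- profile1(mutate_at(opsin$reference_seq, 135, "Q"))
  b <- profile1(mutate_at(opsin$reference_seq, 135, "Q"))
  expect_identical(a, b)
  expect_equal(nrow(a$site_calls), nrow(opsin$sites))
  expect_identical(unname(a$pair_status["R135/Y223"]), "broken")
})

test_that("scheme configs are validated on read", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("scheme_id t", "reference ACDEF", "site bad=2:Z"), path)
  expect_error(read_scheme(path), "malformed site line")

  writeLines(c("scheme_id t", "reference ACDEF",
               "site A1=1:C:gprotein"), path)
  expect_error(read_scheme(path), "not in expected set")

  writeLines(c("scheme_id t", "reference ACDEF",
               "site A1=9:A:gprotein"), path)
  expect_error(read_scheme(path), "outside reference length")

  expect_error(packaged_scheme("no_such_scheme"), "unknown scheme")
})

test_that("profile reports are written as TSV and JSON", {
  profs <- profile_sequences(
    c(self = opsin$reference_seq,
      uncharged = mutate_at(opsin$reference_seq, 113, "F")), opsin)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_profile_tsv(profs, tsv)
  write_profile_json(profs, json)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$stability_prediction,
                   c("monostable-like", "bistable-like"))
  j <- jsonlite::read_json(json)
  expect_identical(j$self$counterion_state, "charged")
  expect_length(j$self$site_calls, nrow(opsin$sites))
})
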