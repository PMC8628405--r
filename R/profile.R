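#' Map reference-numbered sites onto an aligned query
#'
#' Walks the columns of a query-vs-reference pairwise alignment and
#' produces one call per scheme site: the query position aligned to the
#' reference position, the observed residue, and a status —
#' `match` (observed is in the site's expected set), `mismatch`, or
#' `unaligned` (gap in the query opposite the reference position).
#' The `X` wildcard never counts as a match.
#'
#' @param aln A [nw_align()] result whose reference row, degapped,
#'   equals the scheme's reference sequence.
#' @param scheme A [reference_scheme].
#' @return `data.frame` with columns `site_label`, `role`,
#'   `ref_position`, `query_position`, `observed`, `status` (one row
#'   per scheme site, in scheme order).
#' @export
map_sites <- function(aln, scheme) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(scheme, "reference_scheme"))
  if (degap(aln$aligned_ref) != scheme$reference_seq)
    stop(sprintf(
      "alignment reference does not match scheme '%s' reference sequence",
      scheme$scheme_id), call. = FALSE)

  qc <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  rc <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(rc != "-")
  qry_pos <- cumsum(qc != "-")
  # column index carrying each reference position
  col_of <- match(seq_len(max(ref_pos)), ref_pos)

  sites <- scheme$sites
  out <- lapply(seq_len(nrow(sites)), function(k) {
    col <- col_of[sites$ref_position[k]]
    obs <- qc[col]
    if (obs == "-") {
      data.frame(site_label = sites$label[k], role = sites$role[k],
                 ref_position = sites$ref_position[k],
                 query_position = NA_integer_, observed = NA_character_,
                 status = "unaligned")
    } else {
      exp_set <- strsplit(sites$expected[k], "", fixed = TRUE)[[1]]
      status <- if (obs != "X" && obs %in% exp_set) "match" else "mismatch"
      data.frame(site_label = sites$label[k], role = sites$role[k],
                 ref_position = sites$ref_position[k],
                 query_position = qry_pos[col], observed = obs,
                 status = status)
    }
  })
  do.call(rbind, out)
}

#' Classify the opsin counterion state and predicted photostability
#'
#' In monostable visual pigments a negatively charged residue at
#' position 113 (bovine rhodopsin numbering) acts as the counterion
#' stabilizing the protonated retinal Schiff base; bistable opsins
#' carry an uncharged residue there.  Observed E or D therefore yields
#' `charged`/`monostable-like`; any other residue `uncharged`/
#' `bistable-like`; an unaligned site (or an `X` ambiguity) is
#' `indeterminate`.
#'
#' @param calls Site calls from [map_sites()] containing a
#'   counterion-role site.
#' @return Named character vector with elements `counterion_state` and
#'   `stability_prediction`.
#' @export
classify_counterion <- function(calls) {
  ci <- calls[calls$role == "counterion", , drop = FALSE]
  if (nrow(ci) == 0L)
    stop("scheme defines no counterion site", call. = FALSE)
  ci <- ci[1L, ]
  if (ci$status == "unaligned" || identical(ci$observed, "X"))
    return(c(counterion_state = "indeterminate",
             stability_prediction = "indeterminate"))
  if (ci$observed %in% c("E", "D"))
    c(counterion_state = "charged", stability_prediction = "monostable-like")
  else
    c(counterion_state = "uncharged", stability_prediction = "bistable-like")
}

#' Profile G-protein-coupling residue pairs and the NPXXY motif
#'
#' A pair is `intact` iff both member sites match; `indeterminate` iff
#' both members are unaligned; otherwise `broken` (a mismatch, or one
#' member absent while the other is informative — the loss of a residue
#' is itself a deviation).  A motif is `intact` iff every anchor
#' matches, `indeterminate` iff all anchors are unaligned, otherwise
#' `broken`.  Deviations list every non-matching site as
#' `label:residue` or `label:absent`.
#'
#' @param calls Site calls from [map_sites()].
#' @param scheme The [reference_scheme] the calls came from; must
#'   define at least one pair or motif.
#' @return List with `pair_status` (named character), `motif_status`
#'   (named character), `signaling_intact_count` (pairs plus motifs
#'   intact), and `deviations` (character vector).
#' @export
profile_gprotein <- function(calls, scheme) {
  if (is.null(scheme$pairs) && is.null(scheme$motifs))
    stop(sprintf("scheme '%s' defines no pair or motif rules",
                 scheme$scheme_id), call. = FALSE)
  status_of <- setNames(calls$status, calls$site_label)
  by_pos <- setNames(calls$status, calls$ref_position)

  pair_status <- character(0)
  if (!is.null(scheme$pairs)) {
    pair_status <- vapply(seq_len(nrow(scheme$pairs)), function(k) {
      s <- status_of[c(scheme$pairs$member1[k], scheme$pairs$member2[k])]
      if (all(s == "match")) "intact"
      else if (all(s == "unaligned")) "indeterminate"
      else "broken"
    }, "")
    names(pair_status) <- scheme$pairs$label
  }

  motif_status <- character(0)
  for (mo in scheme$motifs) {
    s <- by_pos[names(mo$anchors)]
    motif_status[[mo$label]] <-
      if (all(s == "match")) "intact"
      else if (all(s == "unaligned")) "indeterminate"
      else "broken"
  }

  bad <- calls[calls$status != "match" &
                 calls$role %in% c("gprotein", "motif"), , drop = FALSE]
  deviations <- if (nrow(bad) == 0L) character(0) else
    paste0(bad$site_label, ":",
           ifelse(bad$status == "unaligned", "absent", bad$observed))

  list(pair_status = pair_status, motif_status = motif_status,
       signaling_intact_count =
         sum(pair_status == "intact") + sum(motif_status == "intact"),
       deviations = deviations)
}

#' Tally the ten RLBP1 residues critical for retinoid binding
#'
#' Counts matches among the ten `rlbp1_critical` sites (W166, Y180,
#' F198, C199, M209, Q211, M223, V224, M226, W245 in RLBP1 numbering);
#' an unaligned site counts as a non-match.
#'
#' @param calls Site calls from [map_sites()] against a scheme with
#'   exactly ten `rlbp1_critical` sites.
#' @return List with `score` (integer 0..10) and `breakdown` (the ten
#'   calls).
#' @export
score_rlbp1 <- function(calls) {
  crit <- calls[calls$role == "rlbp1_critical", , drop = FALSE]
  if (nrow(crit) != 10L)
    stop(sprintf("scheme defines %d rlbp1_critical sites; exactly 10 required",
                 nrow(crit)), call. = FALSE)
  list(score = sum(crit$status == "match"), breakdown = crit)
}

#' Profile query sequences against a reference scheme
#'
#' The top-level per-sequence classifier: each query is globally
#' aligned to the scheme reference ([nw_align()]), sites are mapped,
#' and every classification the scheme supports is computed — the
#' counterion/bistability call if the scheme has a counterion site,
#' pair/motif status and the signaling-intact count if it has pair or
#' motif rules, and the 10-site conservation score if it has
#' `rlbp1_critical` sites.
#'
#' @param seqs Named character vector of query sequences.
#' @param scheme A [reference_scheme].
#' @inheritParams nw_align
#' @return A list of `functional_profile` objects (class
#'   `functional_profiles`), one per query, each with fields `seq_id`,
#'   `counterion_state`, `stability_prediction`, `pair_status`,
#'   `motif_status`, `signaling_intact_count`, `rlbp1_score`,
#'   `deviations`, `site_calls`, `alignment_score`.
#' @export
profile_sequences <- function(seqs, scheme, sm = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            inherits(scheme, "reference_scheme"))
  out <- lapply(names(seqs), function(id) {
    aln <- nw_align(seqs[[id]], scheme$reference_seq, sm, gap_open,
                    gap_extend, query_id = id, ref_id = scheme$scheme_id)
    calls <- map_sites(aln, scheme)
    prof <- list(seq_id = id, scheme_id = scheme$scheme_id,
                 counterion_state = NA_character_,
                 stability_prediction = NA_character_,
                 pair_status = NULL, motif_status = NULL,
                 signaling_intact_count = NA_integer_,
                 rlbp1_score = NA_integer_,
                 deviations = character(0),
                 site_calls = calls, alignment_score = aln$score)
    if (any(calls$role == "counterion")) {
      cc <- classify_counterion(calls)
      prof$counterion_state <- cc[["counterion_state"]]
      prof$stability_prediction <- cc[["stability_prediction"]]
    }
    if (!is.null(scheme$pairs) || !is.null(scheme$motifs)) {
      gp <- profile_gprotein(calls, scheme)
      prof$pair_status <- gp$pair_status
      prof$motif_status <- gp$motif_status
      prof$signaling_intact_count <- gp$signaling_intact_count
      prof$deviations <- gp$deviations
    }
    if (any(calls$role == "rlbp1_critical"))
      prof$rlbp1_score <- score_rlbp1(calls)$score
    structure(prof, class = "functional_profile")
  })
  names(out) <- names(seqs)
  structure(out, class = "functional_profiles")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("Functional profile of '%s' (scheme %s)\n", x$seq_id,
              x$scheme_id))
  if (!is.na(x$counterion_state))
    cat(sprintf("  counterion: %s -> %s\n", x$counterion_state,
                x$stability_prediction))
  if (!is.null(x$pair_status))
    cat(sprintf("  pairs: %s\n",
                paste(names(x$pair_status), x$pair_status, sep = "=",
                      collapse = ", ")))
  if (!is.null(x$motif_status))
    cat(sprintf("  motifs: %s; signaling intact %d/5\n",
                paste(names(x$motif_status), x$motif_status, sep = "=",
                      collapse = ", "), x$signaling_intact_count))
  if (!is.na(x$rlbp1_score))
    cat(sprintf("  rlbp1 critical residues: %d/10\n", x$rlbp1_score))
  if (length(x$deviations))
    cat(sprintf("  deviations: %s\n", paste(x$deviations, collapse = ", ")))
  invisible(x)
}

#' Write functional profiles as TSV and JSON reports
#'
#' The TSV has one row per sequence: states, counts and one column per
#' site status; missing values are written as `.`.  The JSON mirrors
#' the full per-site detail losslessly.
#'
#' @param profiles A `functional_profiles` list from
#'   [profile_sequences()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    site_stat <- setNames(p$site_calls$status,
                          paste0("site_", p$site_calls$site_label))
    base <- c(seq_id = p$seq_id, scheme_id = p$scheme_id,
              counterion_state = p$counterion_state,
              stability_prediction = p$stability_prediction,
              if (!is.null(p$pair_status))
                setNames(p$pair_status, paste0("pair_", names(p$pair_status))),
              if (!is.null(p$motif_status))
                setNames(p$motif_status,
                         paste0("motif_", names(p$motif_status))),
              signaling_intact_count = p$signaling_intact_count,
              rlbp1_score = p$rlbp1_score,
              deviations = paste(p$deviations, collapse = ","))
    c(base, site_stat)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df[is.na(df) | df == ""] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
write_profile_json <- function(profiles, path) {
  jsonlite::write_json(unclass(lapply(profiles, unclass)), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
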