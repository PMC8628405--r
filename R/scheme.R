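#' Reference numbering schemes for functional-site profiling
#'
#' A reference scheme bundles a reference protein sequence with named
#' functional sites (1-based positions in that sequence), pair rules
#' (residue pairs whose joint conservation signals G-protein-coupling
#' competence) and motif rules (anchored residues with wildcard
#' positions, e.g. NPXXY).  Two schemes ship with the package:
#'
#' * `bovine_rhodopsin` — Bos taurus rhodopsin (UniProt P02699, 348 aa),
#'   the literature numbering standard for opsins: counterion E113, the
#'   pairs D83/N302, R135/Y223, K231/E247, Y306/F313 and the NPXXY
#'   motif (302-306).
#' * `rlbp1_synthetic` — the ten residues critical for retinoid binding
#'   in RLBP1/CRALBP (W166, Y180, F198, C199, M209, Q211, M223, V224,
#'   M226, W245) at their literature positions, embedded in a synthetic
#'   317-aa background.  To reproduce literature numbering on real data
#'   supply a scheme built on the genuine human RLBP1 (UniProt P12271).
#'
#' @param scheme_id Unique scheme label.
#' @param reference_seq Ungapped reference residue string.
#' @param sites `data.frame` with columns `label`, `ref_position`,
#'   `expected` (string of accepted residues, e.g. `"ED"`), `role`
#'   (one of `counterion`, `gprotein`, `rlbp1_critical`, `motif`).
#' @param pairs Optional `data.frame` with columns `label`, `member1`,
#'   `member2` (site labels).
#' @param motifs Optional list of motif rules, each
#'   `list(label =, anchors = c("302" = "N", ...), wildcards = c(304, 305))`.
#' @return An object of class `reference_scheme`.
#' @export
reference_scheme <- function(scheme_id, reference_seq, sites,
                             pairs = NULL, motifs = NULL) {
  stopifnot(is.character(scheme_id), length(scheme_id) == 1L,
            is.character(reference_seq), length(reference_seq) == 1L,
            is.data.frame(sites))
  encode_residues(reference_seq, sprintf("reference of scheme '%s'",
                                         scheme_id))
  need <- c("label", "ref_position", "expected", "role")
  if (!all(need %in% names(sites)))
    stop("sites need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sites$label))
    stop("duplicate site labels", call. = FALSE)
  roles <- c("counterion", "gprotein", "rlbp1_critical", "motif")
  if (!all(sites$role %in% roles))
    stop("site roles must be one of: ", paste(roles, collapse = ", "),
         call. = FALSE)
  L <- nchar(reference_seq)
  if (any(sites$ref_position < 1L | sites$ref_position > L))
    stop(sprintf("site position outside reference length %d", L),
         call. = FALSE)
  ref_chars <- strsplit(reference_seq, "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(sites))) {
    exp_set <- strsplit(sites$expected[k], "", fixed = TRUE)[[1]]
    if (length(exp_set) == 0L)
      stop("empty expected-residue set for site ", sites$label[k],
           call. = FALSE)
    if (!(ref_chars[sites$ref_position[k]] %in% exp_set))
      stop(sprintf(
        "reference residue %s at position %d is not in expected set '%s' (site %s)",
        ref_chars[sites$ref_position[k]], sites$ref_position[k],
        sites$expected[k], sites$label[k]), call. = FALSE)
  }
  if (!is.null(pairs)) {
    stopifnot(is.data.frame(pairs),
              all(c("label", "member1", "member2") %in% names(pairs)))
    bad <- setdiff(c(pairs$member1, pairs$member2), sites$label)
    if (length(bad))
      stop("pair members not defined as sites: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(motifs)) {
    for (mo in motifs) {
      pos <- sort(c(as.integer(names(mo$anchors)), as.integer(mo$wildcards)))
      if (!all(diff(pos) == 1L))
        stop(sprintf("motif %s positions are not contiguous", mo$label),
             call. = FALSE)
      for (p in names(mo$anchors)) {
        hit <- sites$ref_position == as.integer(p)
        if (!any(hit))
          stop(sprintf("motif %s anchor position %s has no site entry",
                       mo$label, p), call. = FALSE)
        if (!grepl(mo$anchors[[p]], sites$expected[hit][1L], fixed = TRUE))
          stop(sprintf(
            "motif %s expects %s at %s but the site there accepts '%s'",
            mo$label, mo$anchors[[p]], p, sites$expected[hit][1L]),
            call. = FALSE)
      }
    }
  }
  structure(list(scheme_id = scheme_id, reference_seq = reference_seq,
                 sites = sites, pairs = pairs, motifs = motifs),
            class = "reference_scheme")
}

#' @export
print.reference_scheme <- function(x, ...) {
  cat(sprintf("Reference scheme '%s': %d aa, %d sites, %d pairs, %d motifs\n",
              x$scheme_id, nchar(x$reference_seq), nrow(x$sites),
              if (is.null(x$pairs)) 0L else nrow(x$pairs),
              length(x$motifs)))
  invisible(x)
}

#' Read a reference scheme from its plain-text config
#'
#' The format is line-oriented, `#` comments allowed:
#' \preformatted{
#' scheme_id   bovine_rhodopsin
#' reference   MNGTEG...
#' site        E113=113:E:counterion
#' pair        D83/N302=D83,N302
#' motif       NPXXY=302:N,303:P,306:Y;wild=304,305
#' }
#'
#' @param path Config file path.
#' @return A [reference_scheme].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path))
    stop("scheme config not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")

  take1 <- function(key) {
    v <- vals[keys == key]
    if (length(v) != 1L)
      stop(sprintf("scheme config needs exactly one '%s' line", key),
           call. = FALSE)
    v
  }
  sites <- do.call(rbind, lapply(vals[keys == "site"], function(v) {
    m <- regmatches(v, regexec("^([^=]+)=(\\d+):([A-Z]+):(\\w+)$", v))[[1]]
    if (length(m) != 5L)
      stop("malformed site line: ", v, call. = FALSE)
    data.frame(label = m[2L], ref_position = as.integer(m[3L]),
               expected = m[4L], role = m[5L])
  }))
  if (is.null(sites))
    stop("scheme config defines no sites", call. = FALSE)
  pairs <- NULL
  if (any(keys == "pair")) {
    pairs <- do.call(rbind, lapply(vals[keys == "pair"], function(v) {
      m <- regmatches(v, regexec("^([^=]+)=([^,]+),(.+)$", v))[[1]]
      if (length(m) != 4L)
        stop("malformed pair line: ", v, call. = FALSE)
      data.frame(label = m[2L], member1 = m[3L], member2 = m[4L])
    }))
  }
  motifs <- NULL
  if (any(keys == "motif")) {
    motifs <- lapply(vals[keys == "motif"], function(v) {
      m <- regmatches(v, regexec("^([^=]+)=([^;]+)(;wild=(.+))?$", v))[[1]]
      if (length(m) < 3L || !nzchar(m[3L]))
        stop("malformed motif line: ", v, call. = FALSE)
      anchors <- strsplit(strsplit(m[3L], ",", fixed = TRUE)[[1]], ":",
                          fixed = TRUE)
      wild <- if (length(m) >= 5L && nzchar(m[5L]))
        as.integer(strsplit(m[5L], ",", fixed = TRUE)[[1]]) else integer()
      list(label = m[2L],
           anchors = setNames(vapply(anchors, `[`, "", 2L),
                              vapply(anchors, `[`, "", 1L)),
           wildcards = wild)
    })
  }
  reference_scheme(take1("scheme_id"), take1("reference"),
                   sites, pairs, motifs)
}

#' Load one of the packaged reference schemes
#'
#' @param id `"bovine_rhodopsin"` or `"rlbp1_synthetic"`; anything else
#'   is treated as a path to a scheme config file.
#' @return A [reference_scheme].
#' @export
packaged_scheme <- function(id) {
  file <- system.file("extdata", paste0("scheme_", id, ".txt"),
                      package = "opsintools")
  if (nzchar(file)) return(read_scheme(file))
  if (file.exists(id)) return(read_scheme(id))
  stop(sprintf(
    "unknown scheme '%s' (packaged: bovine_rhodopsin, rlbp1_synthetic; or give a config path)",
    id), call. = FALSE)
}
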