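#' Scan a read region for repeat-unit copies
#'
#' Finds placements of the repeat unit inside the inter-anchor region of a
#' read (extended by one band width of slack on each side) by exact k-mer
#' seeding, diagonal clustering with expected period about one unit length,
#' and banded local alignment. Hits aligning at least `min_span_frac` of the
#' unit at sufficient identity are *accepted* (countable copies); hits
#' spanning between `partial_span_frac` and `min_span_frac` are flagged
#' *partial*; anything shorter or below identity is discarded.
#'
#' @param read_seq Read sequence.
#' @param region Integer pair: 0-based half-open inter-anchor interval on the
#'   read (from [classify_reads()]).
#' @param unit_seq Repeat-unit sequence.
#' @param params A [unit_params()].
#' @param strand Strand of the template on the read (`"+"` or `"-"`); on
#'   `"-"` the reverse complement of the unit is scanned.
#' @return Data frame of hits sorted by read position: `read_start`,
#'   `read_end` (0-based half-open), `strand`, `identity`, `span_frac`,
#'   `score`, `status` (`accepted`/`partial`). Zero rows when none.
#' @export
scan_units <- function(read_seq, region, unit_seq, params = unit_params(),
                       strand = "+") {
  stopifnot(length(region) == 2L, region[1L] <= region[2L],
            region[1L] >= 0L, region[2L] <= nchar(read_seq))
  qseq <- if (strand == "-") revcomp(unit_seq) else unit_seq
  qlen <- nchar(qseq)
  if (qlen < params$kmer_size) stop("unit shorter than kmer_size", call. = FALSE)
  band <- params$band_width
  rs <- max(0L, as.integer(region[1L]) - band)
  re <- min(nchar(read_seq), as.integer(region[2L]) + band)
  empty <- data.frame(read_start = integer(0), read_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      span_frac = numeric(0), score = numeric(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (re - rs < params$kmer_size) return(empty)
  sub_str <- substr(read_seq, rs + 1L, re)

  # exact occurrences of the whole unit are optimal placements; skip the DP
  exact <- .exact_occurrences(qseq, sub_str)
  idx <- query_index(qseq, params$kmer_size)
  cand <- cluster_diags(seed_diags(idx, sub_str), band)
  diags <- cand$diag
  if (length(exact))
    diags <- c(exact, diags[vapply(diags, function(d)
      all(abs(d - exact) > band), logical(1))])
  if (!length(diags)) return(empty)
  diags <- sort(diags)

  hits <- lapply(diags, function(d) {
    if (length(exact) && any(d == exact)) {
      data.frame(read_start = rs + d, read_end = rs + d + qlen,
                 identity = 1, span_frac = 1,
                 score = ALN_MATCH * qlen)
    } else {
      h <- verify_candidate(qseq, qlen, read_seq, rs + d, band)
      if (is.null(h)) return(NULL)
      h[, c("read_start", "read_end", "identity", "span_frac", "score")]
    }
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits$strand <- strand
  hits <- hits[hits$identity >= params$min_identity &
               hits$span_frac >= params$partial_span_frac, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits$status <- ifelse(hits$span_frac >= params$min_span_frac,
                        "accepted", "partial")
  hits <- hits[!duplicated(hits[, c("read_start", "read_end")]), , drop = FALSE]
  hits <- hits[order(hits$read_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("read_start", "read_end", "strand", "identity", "span_frac",
           "score", "status")]
}

#' Derive a per-read copy-number call from unit hits
#'
#' Accepted hits are selected greedily by descending alignment score (ties
#' broken by leftmost read position), discarding any hit overlapping an
#' already selected one; the copy number is the number of selected hits.
#' Partial hits are never counted, but their presence marks the read
#' `has_partial` so it can be excluded from headline distributions.
#'
#' @param hits Hit data frame from [scan_units()] (one read).
#' @param read_id Optional read id to carry through.
#' @return One-row data frame: `read_id`, `copy_number`, `partial_count`,
#'   `qc` (`clean` / `has_partial`).
#' @export
count_copies <- function(hits, read_id = NA_character_) {
  acc <- hits[hits$status == "accepted", , drop = FALSE]
  sel <- logical(nrow(acc))
  if (nrow(acc)) {
    ord <- order(-acc$score, acc$read_start)
    for (i in ord) {
      ok <- TRUE
      for (j in which(sel)) {
        if (acc$read_start[i] < acc$read_end[j] &&
            acc$read_start[j] < acc$read_end[i]) { ok <- FALSE; break }
      }
      sel[i] <- ok
    }
  }
  n_partial <- sum(hits$status == "partial")
  data.frame(read_id = read_id, copy_number = sum(sel),
             partial_count = n_partial,
             qc = if (n_partial > 0L) "has_partial" else "clean",
             stringsAsFactors = FALSE)
}

#' Count repeat units on every target read
#'
#' Runs [scan_units()] + [count_copies()] over all reads classified as
#' target.
#'
#' @param seqs Named character vector of read sequences.
#' @param classes Classification data frame from [classify_reads()].
#' @param map A [plasmid_map()].
#' @param params A [unit_params()].
#' @param keep_hits Also return the per-read hit tables?
#' @return Data frame of copy calls (one row per target read); when
#'   `keep_hits` is `TRUE`, the hit tables are attached as attribute `hits`
#'   (a named list).
#' @export
call_copies <- function(seqs, classes, map, params = unit_params(),
                        keep_hits = FALSE) {
  tgt <- classes[classes$call == "target", , drop = FALSE]
  if (!nrow(tgt))
    return(data.frame(read_id = character(0), copy_number = integer(0),
                      partial_count = integer(0), qc = character(0),
                      stringsAsFactors = FALSE))
  calls <- vector("list", nrow(tgt))
  hit_list <- if (keep_hits) vector("list", nrow(tgt)) else NULL
  for (i in seq_len(nrow(tgt))) {
    id <- tgt$read_id[i]
    hits <- scan_units(seqs[[id]],
                       c(tgt$region_start[i], tgt$region_end[i]),
                       map$repeat_unit_seq, params, strand = tgt$strand[i])
    calls[[i]] <- count_copies(hits, read_id = id)
    if (keep_hits) hit_list[[i]] <- hits
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  if (keep_hits) {
    names(hit_list) <- tgt$read_id
    attr(out, "hits") <- hit_list
  }
  out
}

#' Exhaustive reference count of repeat units in a region
#'
#' Reference implementation used to validate the seeded scanner: iterated
#' full local alignment of the unit against the region with
#' \pkg{Biostrings}' `pairwiseAlignment` (no seeding, no banding). The best
#' local alignment is accepted when its identity and aligned unit fraction
#' clear the thresholds, the matched stretch is masked by splitting the
#' region around it, and the search repeats on both remainders until no
#' acceptable hit is left. Both unit orientations are tried at every step.
#' Intended for small inputs (tens of kb).
#'
#' @param read_seq Read sequence.
#' @param region 0-based half-open interval on the read.
#' @param unit_seq Repeat-unit sequence.
#' @param min_identity Identity threshold.
#' @param min_span_frac Minimum aligned unit fraction of an accepted hit.
#' @return Integer count of accepted unit copies.
#' @export
oracle_scan <- function(read_seq, region, unit_seq, min_identity = 0.80,
                        min_span_frac = 0.90) {
  qs <- c(unit_seq, revcomp(unit_seq))
  qlen <- nchar(unit_seq)
  mat <- nucleotideSubstitutionMatrix(match = ALN_MATCH,
                                      mismatch = ALN_MISMATCH,
                                      baseOnly = TRUE)
  count_in <- function(seg) {
    if (nchar(seg) < min_span_frac * qlen) return(0L)
    best <- NULL
    for (q in qs) {
      al <- pairwiseAlignment(DNAString(q), DNAString(seg), type = "local",
                              substitutionMatrix = mat,
                              gapOpening = 0, gapExtension = ALN_GAP)
      if (is.null(best) || score(al) > score(best)) best <- al
    }
    pat <- pattern(best)
    ncols <- nchar(as.character(pat))
    idy <- nmatch(best) / ncols
    span <- (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) / qlen
    if (idy < min_identity || span < min_span_frac) return(0L)
    sub <- subject(best)
    s0 <- BiocGenerics::start(sub); s1 <- BiocGenerics::end(sub)
    1L + count_in(substr(seg, 1L, s0 - 1L)) +
      count_in(substr(seg, s1 + 1L, nchar(seg)))
  }
  count_in(substr(read_seq, region[1L] + 1L, region[2L]))
}
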