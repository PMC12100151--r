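#' Anchor detection parameters
#'
#' Anchors are the innermost stretches of the two vector flanks, immediately
#' adjacent to the array; a read spanning both anchors must have traversed
#' the whole array, so its unit count cannot be biased by end clipping.
#'
#' @param anchor_len Bases taken from each flank next to the array.
#' @param kmer_size Seed length for the k-mer scan.
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns, indels counting as non-matches) for an anchor hit.
#' @param band_width Half-width in bases of the banded alignment around a
#'   seeded diagonal.
#' @return An object of class `anchor_params`.
#' @export
anchor_params <- function(anchor_len = 500L, kmer_size = 15L,
                          min_identity = 0.80, band_width = 100L) {
  if (kmer_size > anchor_len) stop("kmer_size must be <= anchor_len", call. = FALSE)
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0,1]", call. = FALSE)
  structure(list(anchor_len = as.integer(anchor_len),
                 kmer_size = as.integer(kmer_size),
                 min_identity = min_identity,
                 band_width = as.integer(band_width)),
            class = "anchor_params")
}

#' Repeat-unit scan parameters
#'
#' @param kmer_size Seed length.
#' @param min_identity Minimum alignment identity for any hit.
#' @param min_span_frac Minimum aligned fraction of the unit for an
#'   *accepted* hit (a countable copy).
#' @param partial_span_frac Minimum aligned fraction for flagging a
#'   *partial* hit; shorter matches are discarded.
#' @param band_width Alignment band half-width in bases.
#' @return An object of class `unit_params`.
#' @export
unit_params <- function(kmer_size = 15L, min_identity = 0.80,
                        min_span_frac = 0.90, partial_span_frac = 0.30,
                        band_width = 150L) {
  if (!(partial_span_frac > 0 && partial_span_frac < min_span_frac &&
        min_span_frac <= 1))
    stop("need 0 < partial_span_frac < min_span_frac <= 1", call. = FALSE)
  structure(list(kmer_size = as.integer(kmer_size),
                 min_identity = min_identity,
                 min_span_frac = min_span_frac,
                 partial_span_frac = partial_span_frac,
                 band_width = as.integer(band_width)),
            class = "unit_params")
}

# alignment scoring shared by the banded implementation and, mirrored as an
# affine scheme with zero opening cost, by the exhaustive oracle
ALN_MATCH <- 2L
ALN_MISMATCH <- -3L
ALN_GAP <- 4L

# K-mer seed index over a query sequence (k-mers sampled every kmer_size
# bases; exact matching done in C++).
query_index <- function(qseq, kmer_size) {
  list(qseq = qseq, qlen = nchar(qseq), k = as.integer(kmer_size))
}

# Seeded diagonals of the query in the subject: 0-based offsets of the query
# start implied by each exact k-mer match.
seed_diags <- function(index, subject_str) {
  .seed_diags(index$qseq, subject_str, index$k, index$k)
}

# Group seeded diagonals into candidate placements: diagonals within
# `band` of each other belong to one placement (indel drift), gaps larger
# than `band` separate placements (e.g. successive tandem copies).
cluster_diags <- function(diags, band, min_seeds = 3L) {
  if (!length(diags)) return(data.frame(diag = integer(0), count = integer(0)))
  d <- sort(diags)
  grp <- cumsum(c(1L, diff(d) > band))
  agg <- vapply(split(d, grp), function(x)
    c(as.integer(round(stats::median(x))), length(x)), integer(2))
  out <- data.frame(diag = agg[1L, ], count = agg[2L, ])
  out[out$count >= min_seeds, , drop = FALSE]
}

# Verify one candidate placement by banded local alignment of the query
# against a window of the subject around the seeded diagonal.
verify_candidate <- function(qseq, qlen, subject_str, diag, band) {
  slen <- nchar(subject_str)
  ws <- max(0L, diag - band)                       # 0-based window start
  we <- min(slen, diag + qlen + band)              # 0-based exclusive end
  if (we - ws < 1L) return(NULL)
  window <- substr(subject_str, ws + 1L, we)
  r <- .banded_local_align(qseq, window, diag - ws, band,
                           ALN_MATCH, ALN_MISMATCH, ALN_GAP)
  if (r[1L] <= 0L) return(NULL)
  data.frame(read_start = ws + r[4L], read_end = ws + r[5L],
             q_start = r[2L], q_end = r[3L],
             identity = r[6L] / r[7L],
             span_frac = (r[3L] - r[2L]) / qlen,
             score = r[1L])
}

#' Locate a flank anchor on a read
#'
#' Finds the best placement of a flank anchor on either strand of a read by
#' exact k-mer seeding, diagonal clustering and banded local alignment. The
#' best-scoring placement with identity at or above the threshold is
#' returned; ties are broken by the leftmost read position.
#'
#' @param read_seq Read sequence.
#' @param arm_seq Anchor sequence (one flank's innermost stretch).
#' @param params An [anchor_params()].
#' @return A one-row data frame (`read_start`, `read_end` 0-based half-open,
#'   `strand`, `identity`, `score`) or `NULL` when no acceptable placement
#'   exists (including reads shorter than the seed length).
#' @export
find_anchor <- function(read_seq, arm_seq, params = anchor_params()) {
  idx <- list("+" = query_index(arm_seq, params$kmer_size),
              "-" = query_index(revcomp(arm_seq), params$kmer_size))
  find_anchor_indexed(read_seq, idx, params)
}

find_anchor_indexed <- function(read_seq, idx, params) {
  if (nchar(read_seq) < params$kmer_size) return(NULL)
  best <- NULL
  for (std in c("+", "-")) {
    ix <- idx[[std]]
    # fast path: an exact occurrence of the whole arm is always optimal
    ex <- .exact_occurrences(ix$qseq, read_seq)
    if (length(ex)) {
      s <- ex[1L]
      hit <- data.frame(read_start = s, read_end = s + ix$qlen,
                        strand = std, identity = 1,
                        score = ALN_MATCH * ix$qlen)
    } else {
      cand <- cluster_diags(seed_diags(ix, read_seq), params$band_width)
      if (!nrow(cand)) next
      cand <- cand[order(-cand$count), , drop = FALSE]
      cand <- head(cand, 4L)
      hit <- NULL
      for (d in cand$diag) {
        h <- verify_candidate(ix$qseq, ix$qlen, read_seq, d, params$band_width)
        if (is.null(h) || h$identity < params$min_identity) next
        h$strand <- std
        if (is.null(hit) || h$score > hit$score ||
            (h$score == hit$score && h$read_start < hit$read_start)) hit <- h
      }
      if (is.null(hit)) next
      hit <- hit[, c("read_start", "read_end", "strand", "identity", "score")]
    }
    if (is.null(best) || hit$score > best$score ||
        (hit$score == best$score && hit$read_start < best$read_start))
      best <- hit
  }
  best
}
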