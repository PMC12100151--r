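#' Classify reads as target / non-target / ambiguous
#'
#' A read is a *target* when both flank anchors are found on the same strand
#' in the orientation the linear template dictates (left anchor before right
#' anchor after strand canonicalization) without overlapping each other; the
#' stretch between the anchors' inner edges is the array region used for unit
#' counting. Reads with one or zero anchors, or inconsistent anchor geometry,
#' are *non-target*; reads whose anchors overlap are *ambiguous* and are
#' excluded from copy-number statistics.
#'
#' @param seqs Named character vector of read sequences (names = read ids),
#'   e.g. from [read_fastq_seqs()] or a `sim_batch`'s reads.
#' @param map A [plasmid_map()].
#' @param params An [anchor_params()].
#' @return Data frame with one row per read: `read_id`, `call`, `strand`,
#'   anchor intervals and identities (0-based half-open; `NA` when absent),
#'   and the inter-anchor `region_start`/`region_end`.
#' @export
classify_reads <- function(seqs, map, params = anchor_params()) {
  if (!length(seqs)) stop("no reads to classify", call. = FALSE)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("read_%06d", seq_along(seqs))
  arms <- anchor_arms(map, params$anchor_len)
  idx <- list(
    left  = list("+" = query_index(arms$left, params$kmer_size),
                 "-" = query_index(revcomp(arms$left), params$kmer_size)),
    right = list("+" = query_index(arms$right, params$kmer_size),
                 "-" = query_index(revcomp(arms$right), params$kmer_size))
  )
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    lh <- find_anchor_indexed(s, idx$left, params)
    rh <- find_anchor_indexed(s, idx$right, params)
    rows[[i]] <- classify_one(names(seqs)[i], lh, rh)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname classify_reads
#' @param read_seq A single read sequence.
#' @export
classify_read <- function(read_seq, map, params = anchor_params()) {
  classify_reads(setNames(read_seq, "read"), map, params)
}

# innermost anchor_len bases of each flank, adjacent to the array
anchor_arms <- function(map, anchor_len) {
  tpl <- build_template(map, 0L)
  lf <- tpl$left_flank; rf <- tpl$right_flank
  al_l <- min(anchor_len, nchar(lf)); al_r <- min(anchor_len, nchar(rf))
  if (al_l < 1L || al_r < 1L)
    stop("both vector flanks must be non-empty to define anchors", call. = FALSE)
  list(left = substr(lf, nchar(lf) - al_l + 1L, nchar(lf)),
       right = substr(rf, 1L, al_r))
}

classify_one <- function(read_id, lh, rh) {
  na_row <- function(call) data.frame(
    read_id = read_id, call = call, strand = NA_character_,
    left_start = NA_integer_, left_end = NA_integer_, left_identity = NA_real_,
    right_start = NA_integer_, right_end = NA_integer_,
    right_identity = NA_real_,
    region_start = NA_integer_, region_end = NA_integer_,
    stringsAsFactors = FALSE)
  if (is.null(lh) || is.null(rh)) return(na_row("non_target"))
  if (lh$strand != rh$strand) return(na_row("non_target"))
  overlap <- lh$read_start < rh$read_end && rh$read_start < lh$read_end
  region <- if (lh$strand == "+") {
    if (overlap) NULL
    else if (lh$read_end <= rh$read_start) c(lh$read_end, rh$read_start)
    else NA
  } else {
    if (overlap) NULL
    else if (rh$read_end <= lh$read_start) c(rh$read_end, lh$read_start)
    else NA
  }
  call <- if (is.null(region)) "ambiguous"
          else if (all(is.na(region))) "non_target" else "target"
  data.frame(
    read_id = read_id, call = call, strand = lh$strand,
    left_start = lh$read_start, left_end = lh$read_end,
    left_identity = lh$identity,
    right_start = rh$read_start, right_end = rh$read_end,
    right_identity = rh$identity,
    region_start = if (call == "target") region[1L] else NA_integer_,
    region_end = if (call == "target") region[2L] else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Summarize a set of read classifications
#'
#' @param classes Classification data frame from [classify_reads()].
#' @return List with `n_total`, `n_target`, `n_non_target`, `n_ambiguous` and
#'   `target_fraction` (= targets / total reads).
#' @export
summarize_selection <- function(classes) {
  if (is.null(classes) || nrow(classes) == 0L)
    stop("empty classification", call. = FALSE)
  n <- nrow(classes)
  nt <- sum(classes$call == "target")
  list(n_total = n,
       n_target = nt,
       n_non_target = sum(classes$call == "non_target"),
       n_ambiguous = sum(classes$call == "ambiguous"),
       target_fraction = nt / n)
}
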