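#' Accumulate per-base coverage from alignment intervals
#'
#' @param intervals Data frame (or 2-column matrix) of 0-based half-open
#'   reference intervals with columns `start`, `end`.
#' @param ref_len Reference length in bases.
#' @return Integer vector of length `ref_len`; element `i` is the number of
#'   intervals covering base `i - 1`.
#' @export
accumulate_coverage <- function(intervals, ref_len) {
  intervals <- as.data.frame(intervals)
  ref_len <- as.integer(ref_len)
  if (nrow(intervals) == 0L) return(integer(ref_len))
  s <- as.integer(intervals$start); e <- as.integer(intervals$end)
  if (any(s < 0L) || any(e > ref_len) || any(s > e))
    stop("interval out of reference bounds", call. = FALSE)
  keep <- e > s
  as.integer(coverage(IRanges(s[keep] + 1L, e[keep]), width = ref_len))
}

#' Normalize a raw coverage vector
#'
#' `mean` mode divides by the mean per-base count (so the genome-wide average
#' becomes 1); `total` mode divides by the total number of aligned bases.
#'
#' @param counts Integer vector of raw per-base counts.
#' @param mode `"mean"` or `"total"`.
#' @return Numeric vector of normalized values.
#' @export
normalize_coverage <- function(counts, mode = c("mean", "total")) {
  mode <- match.arg(mode)
  tot <- sum(as.numeric(counts))
  if (mode == "mean") {
    if (tot == 0) stop("all-zero track cannot be mean-normalized", call. = FALSE)
    counts / (tot / length(counts))
  } else {
    if (tot == 0) stop("all-zero track cannot be total-normalized", call. = FALSE)
    counts / tot
  }
}

#' Assemble a coverage track
#'
#' @param ref_name Reference (chromosome) name used in bedGraph output.
#' @param counts Raw per-base counts.
#' @param mode Normalization mode, see [normalize_coverage()].
#' @return An object of class `coverage_track` with `ref_name`, `raw`,
#'   `norm`.
#' @export
coverage_track <- function(ref_name, counts, mode = "mean") {
  structure(list(ref_name = ref_name, raw = as.integer(counts),
                 norm = normalize_coverage(counts, mode), mode = mode),
            class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' Emits 0-based half-open intervals with adjacent equal-value runs merged
#' (zero runs included, so the written track covers the whole reference).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param header Optional `#`-prefixed header lines.
#' @param values Which values to write: normalized (default) or raw.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path, header = NULL,
                           values = c("norm", "raw")) {
  values <- match.arg(values)
  v <- track[[values]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines("track type=bedGraph", con)
  writeLines(sprintf("%s\t%d\t%d\t%s", track$ref_name, starts, ends,
                     format(r$values, trim = TRUE, scientific = FALSE,
                            digits = 15)), con)
  invisible(path)
}

#' Read a bedGraph file back into per-base values
#'
#' @param path bedGraph path written by [write_bedgraph()].
#' @return List with `ref_name` and `values` (numeric per-base vector).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^track", lines)]
  parts <- strsplit(lines, "\t")
  ref <- parts[[1L]][1L]
  starts <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  ends <- vapply(parts, function(p) as.integer(p[3L]), integer(1))
  vals <- vapply(parts, function(p) as.numeric(p[4L]), numeric(1))
  values <- numeric(max(ends))
  for (i in seq_along(starts)) values[(starts[i] + 1L):ends[i]] <- vals[i]
  list(ref_name = ref, values = values)
}

#' Reference intervals of target reads on a template
#'
#' Maps each target read onto the chosen linear reference template using the
#' anchor placements and the copy-number call: a read is taken to cover the
#' template from the start of its left-anchor match through its array (capped
#' at the reference copy number) to the end of its right-anchor match. This
#' reuses the alignments already computed instead of invoking a mapper, which
#' is adequate for coverage sanity plots of the plasmid itself.
#'
#' @param classes Classification data frame ([classify_reads()]).
#' @param calls Copy-call data frame ([call_copies()]).
#' @param map A [plasmid_map()].
#' @param ref_copies Copy number of the reference template (default 2).
#' @return List with `intervals` (data frame `start`, `end`) and `ref_len`.
#' @export
reference_intervals <- function(classes, calls, map, ref_copies = 2L) {
  tpl <- build_template(map, ref_copies)
  lf <- nchar(tpl$left_flank); ul <- tpl$unit_len
  ref_len <- nchar(tpl$full_seq)
  tgt <- classes[classes$call == "target", , drop = FALSE]
  m <- merge(tgt, calls, by = "read_id")
  lw <- m$left_end - m$left_start
  rw <- m$right_end - m$right_start
  start <- pmax(0L, lf - lw)
  end <- pmin(ref_len, lf + pmin(m$copy_number, ref_copies) * ul + rw)
  list(intervals = data.frame(start = start, end = end), ref_len = ref_len)
}
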