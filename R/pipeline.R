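#' Run the full profiling pipeline on one sample
#'
#' Classification (anchor selection), unit counting, selection summary,
#' copy-number distribution and template coverage, end to end.
#'
#' @param seqs Named character vector of read sequences, a `sim_batch`, or a
#'   FASTQ path.
#' @param map A [plasmid_map()].
#' @param aparams An [anchor_params()].
#' @param uparams A [unit_params()].
#' @param sample_id,group Labels for the summary.
#' @param include_partial Include `has_partial` reads in the distribution?
#' @param ref_copies Copy number of the coverage reference template.
#' @param norm_mode Coverage normalization mode (`"mean"` or `"total"`).
#' @return List of class `sample_profile`: `classes`, `calls`, `selection`,
#'   `summary`, `coverage` (a [coverage_track()], `NULL` when no target
#'   reads).
#' @export
profile_sample <- function(seqs, map, aparams = anchor_params(),
                           uparams = unit_params(),
                           sample_id = "sample", group = NA_character_,
                           include_partial = FALSE, ref_copies = 2L,
                           norm_mode = "mean") {
  if (is(seqs, "sim_batch")) seqs <- setNames(seqs$reads$seq, seqs$reads$read_id)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fastq_seqs(seqs)
  if (!length(seqs)) stop("no reads supplied", call. = FALSE)
  classes <- classify_reads(seqs, map, aparams)
  calls <- call_copies(seqs, classes, map, uparams)
  selection <- summarize_selection(classes)
  summary <- if (nrow(calls)) {
    copy_distribution(calls, sample_id = sample_id, group = group,
                      include_partial = include_partial)
  } else NULL
  cover <- if (nrow(calls)) {
    ri <- reference_intervals(classes, calls, map, ref_copies = ref_copies)
    coverage_track(paste0(sample_id, "_template"),
                   accumulate_coverage(ri$intervals, ri$ref_len),
                   mode = norm_mode)
  } else NULL
  structure(list(sample_id = sample_id, group = group, classes = classes,
                 calls = calls, selection = selection, summary = summary,
                 coverage = cover),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s: %d reads, %d target (%.1f%%)\n",
              x$sample_id, x$selection$n_total, x$selection$n_target,
              100 * x$selection$target_fraction))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `group`, `fastq_path`.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "group", "fastq_path")
  if (!all(need %in% names(x)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}
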