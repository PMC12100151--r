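#' Per-sample copy-number distribution
#'
#' Turns per-read copy calls into the empirical copy-number distribution of a
#' replicate. Reads flagged `has_partial` are excluded by default: a partial
#' unit between the anchors means the read violates the clean tandem-array
#' model and its integer count is not trustworthy.
#'
#' @param calls Copy-call data frame from [call_copies()].
#' @param sample_id,group Optional labels carried into the summary.
#' @param include_partial Include `has_partial` reads?
#' @return An object of class `sample_summary`: `sample_id`, `group`,
#'   `n_target_reads`, `n_excluded`, `proportions` (named, copy number ->
#'   fraction), `pct_one_copy`, `pct_two_copy`, `pct_three_copy`.
#' @export
copy_distribution <- function(calls, sample_id = NA_character_,
                              group = NA_character_,
                              include_partial = FALSE) {
  keep <- if (include_partial) calls else
    calls[calls$qc == "clean", , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no usable copy calls (all empty or has_partial)", call. = FALSE)
  tab <- table(factor(keep$copy_number, levels = 0:max(keep$copy_number, 3L)))
  props <- as.numeric(tab) / nrow(keep)
  names(props) <- names(tab)
  pct <- function(k) 100 * if (as.character(k) %in% names(props))
    props[[as.character(k)]] else 0
  structure(list(sample_id = sample_id, group = group,
                 n_target_reads = nrow(keep),
                 n_excluded = nrow(calls) - nrow(keep),
                 proportions = props,
                 pct_one_copy = pct(1), pct_two_copy = pct(2),
                 pct_three_copy = pct(3)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> %s (%s): %d reads; 1-copy %.2f%%, 2-copy %.2f%%, 3-copy %.2f%%\n",
              x$sample_id, x$group, x$n_target_reads,
              x$pct_one_copy, x$pct_two_copy, x$pct_three_copy))
  invisible(x)
}

#' Welch's two-sample t-test on replicate values
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom), the
#' robust default for the small replicate groups (n = 2-6) this assay
#' produces. When both groups are constant: equal means give `t = 0, p = 1`;
#' unequal means give `t = +/-Inf, p = 0`.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each), e.g.
#'   per-replicate contraction percentages of two groups.
#' @param pooled Use Student's pooled-variance variant instead?
#' @return List: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `df`, `p`.
#' @export
welch_t <- function(values_a, values_b, pooled = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  base <- list(mean_a = mean(values_a), mean_b = mean(values_b),
               sd_a = sd(values_a), sd_b = sd(values_b))
  if (var(values_a) == 0 && var(values_b) == 0) {
    if (base$mean_a == base$mean_b)
      return(c(base, list(t = 0, df = length(values_a) + length(values_b) - 2,
                          p = 1)))
    return(c(base, list(t = sign(base$mean_a - base$mean_b) * Inf,
                        df = length(values_a) + length(values_b) - 2, p = 0)))
  }
  tt <- t.test(values_a, values_b, var.equal = pooled)
  c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value))
}

#' Estimate the mass of target molecules in a sample
#'
#' Given a sample's total DNA mass and the fraction of reads that are target
#' (a proxy for the molar fraction of target molecules when fragment lengths
#' are comparable), estimates the mass of target plasmid. The displayed value
#' is truncated (not rounded) to three decimals; full precision is kept in
#' `target_mass`.
#'
#' @param total_mass Total DNA mass in ng.
#' @param target_fraction Fraction of target reads (0..1).
#' @return List: `total_mass`, `target_fraction`, `target_mass` (full
#'   precision), `display` (truncated to 3 decimals).
#' @export
estimate_target_mass <- function(total_mass, target_fraction) {
  if (total_mass < 0 || target_fraction < 0)
    stop("inputs must be non-negative", call. = FALSE)
  if (target_fraction > 1) stop("target_fraction must be <= 1", call. = FALSE)
  m <- total_mass * target_fraction
  list(total_mass = total_mass, target_fraction = target_fraction,
       target_mass = m, display = floor(m * 1000 + 1e-9) / 1000)
}

#' Yield reduction between two protocols
#'
#' @param mass_ref Reference-protocol target mass (ng), must be > 0.
#' @param mass_alt Alternative-protocol target mass (ng).
#' @return Percentage reduction, `100 * (1 - mass_alt / mass_ref)`.
#' @export
yield_reduction <- function(mass_ref, mass_alt) {
  if (mass_ref <= 0) stop("mass_ref must be > 0", call. = FALSE)
  100 * (1 - mass_alt / mass_ref)
}

#' Compare a distribution metric between two replicate groups
#'
#' @param summaries List of `sample_summary` objects.
#' @param group_a,group_b Group labels to compare.
#' @param metric Field to compare (default `pct_one_copy`, the contraction
#'   percentage).
#' @param pooled Use pooled-variance t-test?
#' @return List with the two groups' values and the [welch_t()] result.
#' @export
group_compare <- function(summaries, group_a, group_b,
                          metric = "pct_one_copy", pooled = FALSE) {
  val <- function(g) vapply(Filter(function(s) identical(s$group, g),
                                   summaries),
                            function(s) s[[metric]], numeric(1))
  a <- val(group_a); b <- val(group_b)
  c(list(metric = metric, group_a = group_a, group_b = group_b,
         values_a = a, values_b = b),
    welch_t(a, b, pooled = pooled))
}

#' Write distribution tables and a human-readable report
#'
#' @param summaries List of `sample_summary` objects.
#' @param dir Output directory (created if needed).
#' @param comparisons Optional list of [group_compare()] results.
#' @param selection Optional list of [summarize_selection()] results, named
#'   by sample.
#' @param enrichment Optional list of [estimate_target_mass()] /
#'   [yield_reduction()] output to echo.
#' @param header Optional `#`-prefixed header lines for the TSV outputs.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(summaries, dir, comparisons = NULL,
                          selection = NULL, enrichment = NULL,
                          header = NULL) {
  if (!length(summaries)) stop("at least one sample summary required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dist_rows <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(sample_id = s$sample_id, group = s$group,
               copy_number = as.integer(names(s$proportions)),
               proportion = as.numeric(s$proportions),
               n_target_reads = s$n_target_reads,
               stringsAsFactors = FALSE)
  }))
  dist_path <- file.path(dir, "copy_distributions.tsv")
  con <- file(dist_path, "w")
  if (!is.null(header)) writeLines(header, con)
  write.table(dist_rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  json_path <- file.path(dir, "report.json")
  payload <- list(
    samples = lapply(summaries, function(s)
      list(sample_id = s$sample_id, group = s$group,
           n_target_reads = s$n_target_reads, n_excluded = s$n_excluded,
           proportions = as.list(s$proportions),
           pct_one_copy = s$pct_one_copy, pct_two_copy = s$pct_two_copy,
           pct_three_copy = s$pct_three_copy)),
    comparisons = comparisons, selection = selection,
    enrichment = enrichment)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  txt_path <- file.path(dir, "report.txt")
  txt <- c(header, "Copy-number distributions", "")
  for (s in summaries) {
    txt <- c(txt, sprintf("%s (%s): n = %d target reads (%d excluded)",
                          s$sample_id, s$group, s$n_target_reads, s$n_excluded),
             sprintf("  copy %s: %.4f", names(s$proportions), s$proportions),
             sprintf("  contraction (1-copy): %.2f%%  two-copy: %.2f%%  expansion (3-copy): %.2f%%",
                     s$pct_one_copy, s$pct_two_copy, s$pct_three_copy), "")
  }
  for (cmp in comparisons) {
    txt <- c(txt, sprintf("%s, %s vs %s: t = %.4g, df = %.3g, p = %.4g",
                          cmp$metric, cmp$group_a, cmp$group_b,
                          cmp$t, cmp$df, cmp$p))
  }
  writeLines(txt, txt_path)
  invisible(c(dist_path, json_path, txt_path))
}
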