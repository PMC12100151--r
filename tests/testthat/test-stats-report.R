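mk_calls <- function(copies, qc = "clean") {
  n <- length(copies)
  qc <- rep_len(qc, n)
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             copy_number = copies,
             partial_count = as.integer(qc == "has_partial"),
             qc = qc, stringsAsFactors = FALSE)
}

test_that("copy distributions report normalized proportions", {
  s <- copy_distribution(mk_calls(c(1, 2, 2, 2)), "s1", "g1")
  expect_equal(unname(s$proportions[c("1", "2")]), c(0.25, 0.75))
  expect_equal(sum(s$proportions), 1, tolerance = 1e-9)
  expect_equal(s$pct_one_copy, 25)
  expect_equal(s$pct_two_copy, 75)
  expect_equal(s$pct_three_copy, 0)   # zero-frequency class reported as 0

  s2 <- copy_distribution(mk_calls(rep(2, 10)))
  expect_equal(unname(s2$proportions[["2"]]), 1)
  expect_error(copy_distribution(mk_calls(integer(0))), "no usable")

  # has_partial reads excluded unless requested
  calls <- mk_calls(c(2, 2, 5), qc = c("clean", "clean", "has_partial"))
  expect_equal(copy_distribution(calls)$n_target_reads, 2)
  expect_equal(copy_distribution(calls, include_partial = TRUE)$n_target_reads, 3)
})

test_that("sampled distributions recover mixture proportions", {
  set.seed(51)
  probs <- c("1" = 0.0732, "2" = 0.9232, "3" = 0.0036)
  copies <- sample(as.integer(names(probs)), 10000, TRUE, probs)
  s <- copy_distribution(mk_calls(copies))
  for (k in names(probs)) {
    se <- sqrt(probs[[k]] * (1 - probs[[k]]) / 10000)
    expect_lt(abs(s$proportions[[k]] - probs[[k]]), 3 * se)
  }
})

test_that("welch_t matches the closed-form computation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  res <- welch_t(a, b)
  # independent closed form (Welch-Satterthwaite)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_exp <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_exp <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_exp <- 2 * stats::pt(-abs(t_exp), df_exp)
  expect_equal(res$t, t_exp, tolerance = 1e-6)
  expect_equal(res$df, df_exp, tolerance = 1e-6)
  expect_equal(res$p, p_exp, tolerance = 1e-6)
})

test_that("welch_t honours symmetry and degenerate conventions", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  r1 <- welch_t(a, b); r2 <- welch_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  zv <- welch_t(c(0, 0), c(1, 1))
  expect_true(is.infinite(zv$t) && zv$t < 0)
  expect_equal(zv$p, 0)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("enrichment-mass arithmetic reproduces protocol bookkeeping", {
  e1 <- estimate_target_mass(1.73, 0.056)
  expect_equal(e1$display, 0.096)              # truncation, not rounding
  expect_equal(e1$target_mass, 1.73 * 0.056)
  e2 <- estimate_target_mass(0.09, 0.403)
  expect_equal(e2$display, 0.036)
  expect_equal(estimate_target_mass(5, 0)$target_mass, 0)
  expect_error(estimate_target_mass(1, 1.2), "<= 1")

  expect_equal(yield_reduction(0.096, 0.036), 62.5)
  expect_equal(yield_reduction(3, 3), 0)
  expect_equal(yield_reduction(3, 0), 100)
  expect_error(yield_reduction(0, 1), "mass_ref")
})

test_that("group comparison and report rendering work end to end", {
  summaries <- list(
    copy_distribution(mk_calls(c(1, 2, 2, 2)), "a1", "ctrl"),
    copy_distribution(mk_calls(c(1, 1, 2, 2)), "a2", "ctrl"),
    copy_distribution(mk_calls(c(2, 2, 2, 2)), "b1", "yeast"),
    copy_distribution(mk_calls(c(1, 2, 2, 2)), "b2", "yeast"))
  cmp <- group_compare(summaries, "ctrl", "yeast")
  expect_length(cmp$values_a, 2)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  d <- withr::local_tempdir()
  paths <- render_report(summaries, d, comparisons = list(cmp),
                         header = "# hdr")
  expect_true(all(file.exists(paths)))
  tsv <- read.delim(file.path(d, "copy_distributions.tsv"), comment.char = "#")
  expect_equal(sum(tsv$proportion[tsv$sample_id == "a1"]), 1)
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$samples[[1]]$pct_one_copy, 25)
})

test_that("the pipeline recovers contraction percentages without bias", {
  map <- fx_map()
  mix <- target_mix(c("1" = 0.1, "2" = 0.9))
  diffs <- vapply(1:5, function(sd) {
    b <- simulate_sample(map, mix, error_model(0.005, 0.0025, 0.0025),
                         clip_model(0, 0), 150, seed = 500 + sd)
    seqs <- seqs_of(b)
    cls <- classify_reads(seqs, map)
    calls <- call_copies(seqs, cls, map)
    s <- copy_distribution(calls)
    truth_pct <- 100 * mean(b$truth$copy_number == 1)
    s$pct_one_copy - truth_pct
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lte(abs(mean(diffs)), max(3 * se, 1e-9))
})
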