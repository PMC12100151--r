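test_that("anchors are located exactly on either strand", {
  map <- fx_map()
  arm <- substr(fx_template(0)$left_flank,
                nchar(fx_template(0)$left_flank) - 499, 1e9)
  h <- find_anchor(arm, arm)
  expect_equal(h$read_start, 0)
  expect_equal(h$read_end, 500)
  expect_identical(h$strand, "+")
  expect_equal(h$identity, 1)
  hrc <- find_anchor(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(arm))), arm)
  expect_identical(hrc$strand, "-")
  expect_equal(hrc$identity, 1)
  expect_null(find_anchor("ACGT", arm))   # shorter than the seed
})

test_that("noisy embedded anchors are recovered at the right position", {
  map <- fx_map()
  tpl0 <- fx_template(0)
  arm <- substr(tpl0$left_flank, nchar(tpl0$left_flank) - 499, 1e9)
  model <- error_model(0.01, 0.005, 0.005)   # 2% total
  set.seed(31)
  ok <- 0L
  for (i in 1:100) {
    pre <- rand_seq(4000); post <- rand_seq(5500)
    read <- mutate_seq(paste0(pre, arm, post), model, seed = 4000 + i)
    h <- find_anchor(read, arm)
    if (!is.null(h) && h$strand == "+" &&
        min(h$read_end, 4500) - max(h$read_start, 4000) >= 250) ok <- ok + 1L
  }
  expect_gte(ok, 90)
})

test_that("error-free template reads classify as target with exact geometry", {
  map <- fx_map()
  tpl <- fx_template(2)
  cl <- classify_read(tpl$full_seq, map)
  expect_identical(cl$call, "target")
  expect_identical(cl$region_end - cl$region_start, 2L * tpl$unit_len)
  # reverse complement: still target, minus strand, same region length
  rc <- classify_read(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tpl$full_seq))), map)
  expect_identical(rc$call, "target")
  expect_identical(rc$strand, "-")
  expect_identical(rc$region_end - rc$region_start, 2L * tpl$unit_len)
})

test_that("clipped and background reads are non-target", {
  map <- fx_map()
  tpl <- fx_template(2)
  # right flank clipped off entirely
  clipped <- substr(tpl$full_seq, 1, nchar(tpl$left_flank) + 2 * tpl$unit_len)
  expect_identical(classify_read(clipped, map)$call, "non_target")
  # background molecule
  expect_identical(classify_read(fx_pool()$seq[1], map)$call, "non_target")
})

test_that("selection summaries count calls and fractions", {
  mk <- function(calls) data.frame(read_id = seq_along(calls), call = calls)
  s <- summarize_selection(mk(rep(c("target", "non_target"), c(40, 60))))
  expect_equal(s$target_fraction, 0.40)
  expect_equal(s$n_target, 40)
  expect_equal(summarize_selection(mk(rep("ambiguous", 5)))$target_fraction, 0)
  expect_error(summarize_selection(mk(character(0))), "empty")
})

test_that("with no error, clip or background every read is target", {
  map <- fx_map()
  b <- simulate_sample(map, target_mix(c("2" = 1)), error_model(0, 0, 0),
                       clip_model(0, 0), 60, seed = 8)
  cls <- classify_reads(seqs_of(b), map)
  expect_equal(summarize_selection(cls)$target_fraction, 1)
})

test_that("classification is invariant under reverse complement", {
  map <- fx_map()
  mix <- mixture_spec(c("1" = 0.3, "2" = 0.7), 0.3, fx_pool())
  b <- simulate_sample(map, mix, error_model(0.0125, 0.005, 0.0075),
                       clip_model(0.2, 300), 60, seed = 14)
  seqs <- seqs_of(b)
  rc <- vapply(seqs, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), character(1))
  cls <- classify_reads(seqs, map)
  cls_rc <- classify_reads(rc, map)
  expect_identical(cls$call, cls_rc$call)
  # strands flip on target reads
  tgt <- cls$call == "target"
  expect_true(all(cls$strand[tgt] != cls_rc$strand[tgt]))
  # region lengths are preserved
  expect_identical(cls$region_end[tgt] - cls$region_start[tgt],
                   cls_rc$region_end[tgt] - cls_rc$region_start[tgt])
})

test_that("heavier clipping never raises the target fraction", {
  map <- fx_map()
  fr <- vapply(c(0, 0.4, 0.8), function(cp) {
    b <- simulate_sample(map, target_mix(c("2" = 1)), error_model(0, 0, 0),
                         clip_model(cp, 1500), 150, seed = 77)
    summarize_selection(classify_reads(seqs_of(b), map))$target_fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0.02))
  expect_lt(fr[3], fr[1])   # strong clipping visibly removes targets
})
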