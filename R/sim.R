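#' Nanopore-like error model
#'
#' Per-base substitution, insertion and deletion probabilities plus a constant
#' Phred quality for emitted reads. The defaults (1% substitution, 0.5%
#' insertion, 1% deletion) are a deliberately crude stand-in for modern
#' nanopore chemistry with high-accuracy basecalling; they are meant to be
#' overridden when calibrated rates are available.
#'
#' @param sub_rate,ins_rate,del_rate Per-base event probabilities, each in
#'   `[0, 0.5)` and summing to less than 1.
#' @param qual_mean Phred value used for every base of the quality string.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.01,
                        qual_mean = 20L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 0.5) || sum(rates) >= 1)
    stop("rates must lie in [0, 0.5) and sum to < 1", call. = FALSE)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, qual_mean = as.integer(qual_mean)),
            class = "error_model")
}

#' Read-end clipping model
#'
#' Each read end is independently truncated with probability `clip_prob`; the
#' number of clipped bases is geometric with mean `clip_len_mean`. Clipping is
#' applied to the template before errors are introduced, modelling incomplete
#' capture of the molecule.
#'
#' @param clip_prob Probability that a given read end is clipped.
#' @param clip_len_mean Mean clip length in bases.
#' @return An object of class `clip_model`.
#' @export
clip_model <- function(clip_prob = 0, clip_len_mean = 0) {
  if (clip_prob < 0 || clip_prob > 1) stop("clip_prob must be in [0,1]", call. = FALSE)
  if (clip_len_mean < 0) stop("clip_len_mean must be >= 0", call. = FALSE)
  structure(list(clip_prob = clip_prob, clip_len_mean = clip_len_mean),
            class = "clip_model")
}

#' Molecule mixture for a simulated sample
#'
#' @param proportions Named numeric vector mapping copy number to probability
#'   (e.g. `c("1" = 0.0732, "2" = 0.9232, "3" = 0.0036)`); must sum to 1.
#' @param background_fraction Probability that a read derives from a
#'   background molecule rather than the test plasmid.
#' @param background_pool Data frame (`label`, `seq`, `circular`) of
#'   background molecules, e.g. [example_background_pool()].
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(proportions, background_fraction = 0,
                         background_pool = NULL) {
  if (is.null(names(proportions)))
    stop("proportions must be named by copy number", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("copy-number proportions must sum to 1", call. = FALSE)
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must be in [0,1]", call. = FALSE)
  if (background_fraction > 0 &&
      (is.null(background_pool) || nrow(background_pool) == 0L))
    stop("background_fraction > 0 requires a non-empty background_pool",
         call. = FALSE)
  structure(list(proportions = proportions,
                 background_fraction = background_fraction,
                 background_pool = background_pool),
            class = "mixture_spec")
}

#' Introduce sequencing errors into a sequence
#'
#' Applies independent per-base substitutions, deletions and (post-base)
#' insertions at the model's rates. The expected edit distance from the input
#' is approximately `(sub_rate + ins_rate + del_rate) * nchar(seq)`.
#'
#' @param seq Nucleotide string.
#' @param model An [error_model()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_sample()]).
#' @return The mutated sequence.
#' @export
mutate_seq <- function(seq, model, seed = NULL) {
  stopifnot(is(model, "error_model"))
  if (!is.null(seed)) return(with_seed(seed, mutate_seq(seq, model)))
  n <- nchar(seq)
  if (n == 0L) return(seq)
  b <- strsplit(seq, "")[[1]]
  u <- runif(n)
  is_sub <- u < model$sub_rate
  is_del <- u >= model$sub_rate & u < model$sub_rate + model$del_rate
  if (any(is_sub)) {
    alts <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                   nrow = 3L,
                   dimnames = list(NULL, c("A","C","G","T")))
    idx <- which(is_sub)
    pick <- sample.int(3L, length(idx), replace = TRUE)
    b[idx] <- alts[cbind(pick, match(b[idx], colnames(alts)))]
  }
  ins_at <- which(runif(n) < model$ins_rate)
  if (length(ins_at)) {
    ins_base <- sample(c("A","C","G","T"), length(ins_at), replace = TRUE)
    pieces <- character(n)
    pieces[!is_del] <- b[!is_del]
    pieces[ins_at] <- paste0(pieces[ins_at], ins_base)
    paste(pieces, collapse = "")
  } else {
    paste(b[!is_del], collapse = "")
  }
}

#' Simulate a long-read sample with a truth table
#'
#' Draws each read from the molecule mixture: target reads are built from the
#' linear template of a drawn copy number, background reads from the pool
#' (circular molecules are linearized at a uniform random position). Every
#' read gets a uniform strand, end clipping, then errors. The truth table
#' records origin, true copy number, strand and applied clip lengths per read.
#'
#' Reproducibility: read `k` is generated from a stream derived from
#' `(seed, k)` only, so the first `k` reads are identical for any
#' `n_reads >= k`, and the whole batch is byte-identical across runs.
#'
#' @param map A [plasmid_map()].
#' @param mix A [mixture_spec()].
#' @param err An [error_model()].
#' @param clip A [clip_model()].
#' @param n_reads Number of reads to simulate.
#' @param seed Master integer seed.
#' @return An object of class `sim_batch`: list with `reads` (data frame
#'   `read_id`, `seq`, `qual`) and `truth` (data frame `read_id`, `origin`,
#'   `copy_number`, `strand`, `left_clip`, `right_clip`).
#' @export
simulate_sample <- function(map, mix, err, clip, n_reads, seed) {
  stopifnot(is(map, "plasmid_map"), is(mix, "mixture_spec"),
            is(err, "error_model"), is(clip, "clip_model"))
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)

  copies <- as.integer(names(mix$proportions))
  templates <- lapply(copies, function(k) build_template(map, k)$full_seq)
  names(templates) <- names(mix$proportions)
  qchar <- rawToChar(as.raw(err$qual_mean + 33L))

  seqs <- character(n_reads); quals <- character(n_reads)
  origin <- character(n_reads); copy_number <- rep(NA_integer_, n_reads)
  strand <- character(n_reads)
  left_clip <- integer(n_reads); right_clip <- integer(n_reads)

  for (k in seq_len(n_reads)) {
    rk <- with_seed(derive_seed(seed, k), {
      if (runif(1) < mix$background_fraction) {
        i <- sample.int(nrow(mix$background_pool), 1L)
        tmpl <- mix$background_pool$seq[i]
        if (mix$background_pool$circular[i])
          tmpl <- rotate_seq(tmpl, sample.int(nchar(tmpl), 1L) - 1L)
        org <- mix$background_pool$label[i]; cp <- NA_integer_
      } else {
        j <- sample.int(length(templates), 1L, prob = mix$proportions)
        tmpl <- templates[[j]]; org <- "target"; cp <- copies[j]
      }
      std <- if (runif(1) < 0.5) "+" else "-"
      if (std == "-") tmpl <- revcomp(tmpl)
      len <- nchar(tmpl)
      lc <- if (runif(1) < clip$clip_prob && clip$clip_len_mean > 0)
        rgeom(1L, 1 / (1 + clip$clip_len_mean)) else 0L
      rc <- if (runif(1) < clip$clip_prob && clip$clip_len_mean > 0)
        rgeom(1L, 1 / (1 + clip$clip_len_mean)) else 0L
      lc <- min(lc, len - 1L)
      rc <- min(rc, len - lc - 1L)
      s <- substr(tmpl, lc + 1L, len - rc)
      s <- mutate_seq(s, err)
      list(seq = s, origin = org, copy = cp, strand = std,
           lc = as.integer(lc), rc = as.integer(rc))
    })
    seqs[k] <- rk$seq
    quals[k] <- strrep(qchar, nchar(rk$seq))
    origin[k] <- rk$origin; copy_number[k] <- rk$copy
    strand[k] <- rk$strand
    left_clip[k] <- rk$lc; right_clip[k] <- rk$rc
  }

  ids <- sprintf("read_%06d", seq_len(n_reads))
  structure(list(
    reads = data.frame(read_id = ids, seq = seqs, qual = quals,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, origin = origin,
                       copy_number = copy_number, strand = strand,
                       left_clip = left_clip, right_clip = right_clip,
                       stringsAsFactors = FALSE),
    seed = seed
  ), class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  cat(sprintf("<sim_batch> %d reads (%.1f%% target), seed %d\n",
              nrow(x$reads), 100 * mean(x$truth$origin == "target"), x$seed))
  invisible(x)
}

#' Write a simulated batch to FASTQ and truth TSV
#'
#' @param batch A `sim_batch` from [simulate_sample()].
#' @param fastq_path Output FASTQ path (`.gz` suffix for gzip).
#' @param truth_path Optional truth-table TSV path.
#' @param header Optional character vector of `#`-prefixed header lines for
#'   the truth table.
#' @return Invisibly, the FASTQ path.
#' @export
write_sim_batch <- function(batch, fastq_path, truth_path = NULL,
                            header = NULL) {
  write_fastq(batch$reads, fastq_path)
  if (!is.null(truth_path)) {
    con <- file(truth_path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(header, con)
    write.table(batch$truth, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fastq_path)
}

write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id),
                             reads$seq, "+", reads$qual)), con)
  invisible(path)
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ path (gzip transparent).
#' @return Named character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
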