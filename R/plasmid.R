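#' Describe the carrier plasmid
#'
#' The carrier construct is a circular vector backbone with a tandem array of
#' identical repeat units inserted at one position. The linearization enzyme
#' must cut the backbone exactly once and the repeat unit never, so that every
#' molecule opens into a linear template with the array flanked by two defined
#' vector arms.
#'
#' @param vector_seq Circular backbone sequence (ACGTN), excluding the array.
#' @param array_insert_pos 0-based position in `vector_seq` where the array is
#'   inserted.
#' @param repeat_unit_seq Sequence of one repeat unit (ACGTN).
#' @param linearization_enzyme A [restriction_enzyme()]; default PmlI.
#' @return An object of class `plasmid_map`.
#' @export
plasmid_map <- function(vector_seq, array_insert_pos, repeat_unit_seq,
                        linearization_enzyme = default_enzymes()$PmlI) {
  vector_seq <- toupper(vector_seq)
  repeat_unit_seq <- toupper(repeat_unit_seq)
  for (s in list(vector_seq, repeat_unit_seq))
    if (grepl("[^ACGTN]", s))
      stop("sequences must contain only A/C/G/T/N", call. = FALSE)
  array_insert_pos <- as.integer(array_insert_pos)
  if (array_insert_pos < 0L || array_insert_pos > nchar(vector_seq))
    stop("array_insert_pos out of range", call. = FALSE)
  n_vec  <- length(find_sites(vector_seq, linearization_enzyme, circular = TRUE))
  n_unit <- length(find_sites(repeat_unit_seq, linearization_enzyme))
  if (n_vec != 1L || n_unit != 0L)
    stop(sprintf(paste0("linearization enzyme %s must have exactly one site in ",
                        "the vector (found %d) and none in the repeat unit ",
                        "(found %d)"),
                 linearization_enzyme$name, n_vec, n_unit), call. = FALSE)
  structure(list(vector_seq = vector_seq,
                 array_insert_pos = array_insert_pos,
                 repeat_unit_seq = repeat_unit_seq,
                 linearization_enzyme = linearization_enzyme),
            class = "plasmid_map")
}

#' @export
print.plasmid_map <- function(x, ...) {
  cat(sprintf(paste0("<plasmid_map> vector %d bp, unit %d bp, array inserted ",
                     "at %d, linearized with %s\n"),
              nchar(x$vector_seq), nchar(x$repeat_unit_seq),
              x$array_insert_pos, x$linearization_enzyme$name))
  invisible(x)
}

#' Build the linear template for a given copy number
#'
#' Assembles the circular plasmid (vector with `copy_number` repeat units
#' inserted at the array position), verifies the linearization enzyme still
#' cuts exactly once, and opens the circle at that cut. The flank lengths are
#' independent of the copy number — only the array stretch varies.
#'
#' @param map A [plasmid_map()].
#' @param copy_number Non-negative integer number of repeat units.
#' @return An object of class `linear_template` with fields `left_flank`,
#'   `right_flank`, `copy_number`, `unit_len` and `full_seq`.
#' @export
build_template <- function(map, copy_number) {
  stopifnot(is(map, "plasmid_map"))
  copy_number <- as.integer(copy_number)
  if (copy_number < 0L) stop("copy_number must be >= 0", call. = FALSE)
  V <- map$vector_seq; U <- map$repeat_unit_seq
  p <- map$array_insert_pos
  ul <- nchar(U); lv <- nchar(V)
  array_seq <- strrep(U, copy_number)
  circle <- paste0(substr(V, 1L, p), array_seq, substr(V, p + 1L, lv))
  sites <- find_sites(circle, map$linearization_enzyme, circular = TRUE)
  if (length(sites) != 1L)
    stop(sprintf("assembled circle has %d linearization sites (need exactly 1)",
                 length(sites)), call. = FALSE)
  x <- (sites[1L] + map$linearization_enzyme$cut_offset) %% nchar(circle)
  a0 <- p; a1 <- p + copy_number * ul            # array interval in circle
  if (x >= a0 && x < a1)
    stop("linearization cut falls inside the array", call. = FALSE)
  n <- nchar(circle)
  span <- function(from, to) {                   # 0-based half-open, wrapping
    if (from <= to) substr(circle, from + 1L, to)
    else paste0(substr(circle, from + 1L, n), substr(circle, 1L, to))
  }
  left_flank  <- if (x == a0) "" else span(x, a0)
  right_flank <- span(a1 %% n, x)
  if (a1 == n && x == 0L) right_flank <- ""
  full_seq <- paste0(left_flank, array_seq, right_flank)
  stopifnot(nchar(full_seq) == lv + copy_number * ul)
  structure(list(left_flank = left_flank, right_flank = right_flank,
                 copy_number = copy_number, unit_len = ul,
                 full_seq = full_seq),
            class = "linear_template")
}

#' @export
print.linear_template <- function(x, ...) {
  cat(sprintf(paste0("<linear_template> %d x %d bp unit, flanks %d/%d bp, ",
                     "%d bp total\n"),
              x$copy_number, x$unit_len, nchar(x$left_flank),
              nchar(x$right_flank), nchar(x$full_seq)))
  invisible(x)
}

#' Synthetic example construct
#'
#' Generates a deterministic synthetic stand-in for a centromeric test plasmid
#' carrying a two-unit tandem array: a 5.5 kb backbone with a single PmlI site
#' and a 2 kb repeat unit free of PmlI sites. The sequences are random DNA at
#' yeast-like GC content — they reproduce the *architecture* of the construct
#' (unique cut site, array between two long flanks), not any real sequence.
#'
#' @param seed Integer seed controlling the synthetic sequences.
#' @param vector_len,unit_len Lengths of the backbone and repeat unit.
#' @return A [plasmid_map()].
#' @export
example_plasmid_map <- function(seed = 101L, vector_len = 5500L,
                                unit_len = 2000L) {
  enz <- default_enzymes()$PmlI
  with_seed(seed, {
    vec <- scrub_sites(random_dna(vector_len), enz$recognition)
    vec <- paste0(substr(vec, 1L, 1000L), "CACGTG",
                  substr(vec, 1007L, vector_len))
    unit <- scrub_sites(random_dna(unit_len), enz$recognition)
    plasmid_map(vec, array_insert_pos = 3000L, repeat_unit_seq = unit,
                linearization_enzyme = enz)
  })
}

#' Synthetic background molecule pool
#'
#' Background molecules co-purified with the test plasmid: a 2-micron-like
#' high-copy circle (carrying a BsoBI-type site but no PmlI site), an
#' rDNA-like and a mitochondrial-like linear fragment, and a small uncut
#' circle with no site for any default enzyme. All sequences are synthetic
#' random DNA; they model molecule *classes* (circular vs linear, cuttable vs
#' not), not real genomes.
#'
#' @param seed Integer seed.
#' @return A data frame with columns `label`, `seq`, `circular`, usable as the
#'   `background_pool` of [mixture_spec()].
#' @export
example_background_pool <- function(seed = 202L) {
  enzymes <- default_enzymes()
  with_seed(seed, {
    two_micron <- scrub_sites(random_dna(6300L),
                              c("CACGTG", "CYCGRG", "GCATGC"))
    two_micron <- paste0(substr(two_micron, 1L, 2000L), "CCCGGG",
                         substr(two_micron, 2007L, 6300L))
    rdna <- scrub_sites(random_dna(9100L), "CACGTG")
    mito <- scrub_sites(random_dna(7300L), "CACGTG")
    leftover <- scrub_sites(random_dna(3000L),
                            c("CACGTG", "CYCGRG", "GCATGC"))
    data.frame(
      label = c("two_micron_like", "rdna_like", "mito_like", "uncut_circle"),
      seq = c(two_micron, rdna, mito, leftover),
      circular = c(TRUE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# Remove every (degenerate) occurrence of the given recognition patterns by
# toggling the middle base until none remain.
scrub_sites <- function(seq, patterns) {
  repeat {
    hit <- FALSE
    for (p in patterns) {
      m <- matchPattern(p, DNAString(seq), fixed = FALSE)
      if (length(m)) {
        hit <- TRUE
        pos <- BiocGenerics::start(m)[1L] + nchar(p) %/% 2L
        old <- substr(seq, pos, pos)
        new <- setdiff(c("A", "C", "G", "T"), old)[1L]
        substr(seq, pos, pos) <- new
      }
    }
    if (!hit) return(seq)
  }
}

#' Model the second purification protocol on a background pool
#'
#' The second protocol linearizes the 2-micron plasmid with BsoBI and SphI and
#' then degrades all linear DNA with exonuclease V before the final PmlI
#' digestion. Its computational consequence is purely compositional: every
#' molecule that is linear, or circular but cut by the digestion enzymes, is
#' removed from the pool.
#'
#' @param pool Background pool data frame (`label`, `seq`, `circular`).
#' @param enzymes Enzymes of the pre-digestion (default BsoBI + SphI).
#' @return The filtered pool (possibly zero rows).
#' @export
apply_second_protocol <- function(pool,
                                  enzymes = default_enzymes()[c("BsoBI", "SphI")]) {
  keep <- vapply(seq_len(nrow(pool)), function(i) {
    if (!pool$circular[i]) return(FALSE)
    digest_circular(pool$seq[i], enzymes)$circular
  }, logical(1))
  pool[keep, , drop = FALSE]
}
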