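IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition sequence (IUPAC
#' nucleotide codes allowed, e.g. `CYCGRG` for BsoBI) and the 0-based offset
#' of the top-strand cut within the recognition site. When `cut_offset` is
#' omitted it defaults to the blunt midpoint of the site, which is correct for
#' PmlI and a harmless convention for the others (only cut positions, not
#' overhang chemistry, matter downstream).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (IUPAC codes).
#' @param cut_offset 0-based cut position on the top strand,
#'   `0 <= cut_offset <= nchar(recognition)`. Default: blunt midpoint.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("PmlI", "CACGTG")
#' @export
restriction_enzyme <- function(name, recognition, cut_offset = NULL) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition))
    stop("recognition sequence must be non-empty", call. = FALSE)
  bad <- setdiff(strsplit(recognition, "")[[1]], IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code(s) in recognition sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (is.null(cut_offset)) cut_offset <- nchar(recognition) %/% 2L
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within [0, length(recognition)]", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (cut at +%d)\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

#' Default enzyme set
#'
#' The three enzymes of the two plasmid-processing protocols: PmlI linearizes
#' the test plasmid; BsoBI and SphI linearize the endogenous 2-micron plasmid
#' ahead of exonuclease treatment. Recognition sequences are the standard
#' ones; override by constructing your own [restriction_enzyme()].
#'
#' @return Named list of `restriction_enzyme` objects.
#' @export
default_enzymes <- function() {
  list(
    PmlI  = restriction_enzyme("PmlI",  "CACGTG", 3L),
    SphI  = restriction_enzyme("SphI",  "GCATGC", 5L),
    BsoBI = restriction_enzyme("BsoBI", "CYCGRG", 1L)
  )
}

#' Find restriction sites in a sequence
#'
#' Scans for the enzyme's recognition sequence with IUPAC degeneracy (Y
#' matches C/T, R matches A/G, ...). For circular sequences, sites spanning
#' the origin are found and reported modulo the sequence length.
#'
#' @param seq Nucleotide string.
#' @param enzyme A [restriction_enzyme()].
#' @param circular Treat `seq` as circular?
#' @return Sorted integer vector of 0-based site start positions.
#' @examples
#' find_sites("AAACACGTGAAA", restriction_enzyme("PmlI", "CACGTG"))
#' @export
find_sites <- function(seq, enzyme, circular = FALSE) {
  stopifnot(is(enzyme, "restriction_enzyme"))
  if (!nzchar(seq)) stop("seq must be non-empty", call. = FALSE)
  w <- nchar(enzyme$recognition)
  len <- nchar(seq)
  subject <- if (circular && len > 1L) {
    paste0(seq, substr(seq, 1L, min(w - 1L, len)))
  } else seq
  m <- matchPattern(enzyme$recognition, DNAString(subject), fixed = FALSE)
  starts <- BiocGenerics::start(m) - 1L            # to 0-based
  if (circular) starts <- starts %% len
  sort(unique(starts[starts < len]))
}

#' Digest a circular sequence with one or more enzymes
#'
#' Cuts a circular molecule at every recognition site of every enzyme. With
#' k >= 1 total cuts the result is k fragments whose concatenation, starting
#' from the first cut, is a rotation of the input; with no cuts the molecule
#' remains circular and no fragments are produced.
#'
#' @param seq Nucleotide string, treated as circular.
#' @param enzymes A `restriction_enzyme` or list of them.
#' @return List with `fragments` (character vector) and `circular` (logical,
#'   `TRUE` iff no site was found).
#' @export
digest_circular <- function(seq, enzymes) {
  if (is(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  len <- nchar(seq)
  cuts <- integer(0)
  for (e in enzymes) {
    sites <- find_sites(seq, e, circular = TRUE)
    cuts <- c(cuts, (sites + e$cut_offset) %% len)
  }
  cuts <- sort(unique(cuts))
  if (!length(cuts)) return(list(fragments = character(0), circular = TRUE))
  rot <- rotate_seq(seq, cuts[1L])
  bounds <- c(cuts - cuts[1L], len)            # 0-based starts in rotated seq
  frags <- substring(rot, bounds[-length(bounds)] + 1L, bounds[-1L])
  list(fragments = frags, circular = FALSE)
}

# rotate so that 0-based position `at` becomes the first base
rotate_seq <- function(seq, at) {
  if (at == 0L) return(seq)
  paste0(substr(seq, at + 1L, nchar(seq)), substr(seq, 1L, at))
}
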