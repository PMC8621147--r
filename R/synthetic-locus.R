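# Synthetic locus assembly: genes separated by scrubbed random spacers.
#
# Spacer model: i.i.d. bases at a target GC fraction.  Every ATG (and CAT,
# its reverse-strand image) is rewritten with a GC-preserving substitution so
# spacers contain no start codon on either strand, and each spacer is capped
# at both ends by the cassette CTAGCTAGCTAG, which carries stop codons in all
# three reading frames on both strands (it is its own reverse complement), so
# no open stretch can run across a spacer.

SPACER_CASSETTE <- "CTAGCTAGCTAG"

scrub_starts <- function(x) {
  # ATG -> ATC and CAT -> CTT preserve GC content and cannot create new
  # ATG/CAT occurrences; iterate until clean.
  repeat {
    y <- gsub("ATG", "ATC", x, fixed = TRUE)
    y <- gsub("CAT", "CTT", y, fixed = TRUE)
    if (identical(y, x)) return(y)
    x <- y
  }
}

make_spacer <- function(len, gc = 0.45) {
  len <- as.integer(len)
  if (len <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  core_len <- len - 2L * nchar(SPACER_CASSETTE)
  if (core_len < 0L) {
    return(substr(strrep(SPACER_CASSETTE, len %/% nchar(SPACER_CASSETTE) + 1L),
                  1L, len))
  }
  core <- scrub_starts(paste(
    sample(names(p), core_len, replace = TRUE, prob = p), collapse = ""))
  paste0(SPACER_CASSETTE, core, SPACER_CASSETTE)
}

#' Assemble synthetic genes into a genomic locus
#'
#' Places genes in order, non-overlapping, separated (and flanked) by random
#' spacers that are guaranteed free of start codons on either strand and
#' carry stop codons in every reading frame at their ends, so an ORF scanner
#' recovers exactly the planted genes.
#'
#' @param genes List of [build_gamma_gene()] objects (>= 1).
#' @param spacer_range Length range (bp) from which each spacer length is
#'   drawn uniformly.
#' @param spacer_gc Spacer GC fraction in (0, 1).
#' @param strands Character vector of "+"/"-" per gene (recycled); genes on
#'   "-" are placed reverse-complemented.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_locus`: `sequence` (the genomic
#'   string) and `truth`, a tibble with one row per gene (`id`, `start`,
#'   `end`, 1-based inclusive on the forward axis, `strand`, `length_bp`,
#'   `status`), plus `genes` (the input objects, in placement order).
#' @export
build_locus <- function(genes, spacer_range = c(200, 400), spacer_gc = 0.45,
                        strands = "+", seed = 1) {
  if (inherits(genes, "synthetic_gene")) genes <- list(genes)
  if (!length(genes)) abort("need at least one gene")
  if (!all(vapply(genes, inherits, logical(1), "synthetic_gene"))) {
    abort("genes must be synthetic_gene objects")
  }
  if (any(spacer_range < 0)) abort("spacer lengths must be >= 0")
  strands <- rep_len(strands, length(genes))
  if (!all(strands %in% c("+", "-"))) abort('strands must be "+" or "-"')

  with_local_seed(seed, {
    n <- length(genes)
    spacer_lens <- sample(seq(spacer_range[1], spacer_range[2]), n + 1L,
                          replace = TRUE)
    parts <- character(0)
    rows <- vector("list", n)
    pos <- 0L
    for (i in seq_len(n)) {
      sp <- make_spacer(spacer_lens[i], spacer_gc)
      parts <- c(parts, sp)
      pos <- pos + nchar(sp)
      g <- genes[[i]]
      placed <- if (strands[i] == "-") reverse_complement(g$dna) else g$dna
      parts <- c(parts, placed)
      rows[[i]] <- tibble(
        id = g$id,
        start = pos + 1L,
        end = pos + nchar(placed),
        strand = strands[i],
        length_bp = nchar(placed),
        status = if (!is.null(g$pseudogene_stop) || isTRUE(g$truncated))
          "pseudogene" else "full_length"
      )
      pos <- pos + nchar(placed)
    }
    parts <- c(parts, make_spacer(spacer_lens[n + 1L], spacer_gc))
    structure(
      list(sequence = paste(parts, collapse = ""),
           truth = bind_rows(rows),
           genes = genes),
      class = "synthetic_locus"
    )
  })
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("<synthetic_locus> ", nchar(x$sequence), " bp, ",
      nrow(x$truth), " gene(s)\n", sep = "")
  print(x$truth)
  invisible(x)
}
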