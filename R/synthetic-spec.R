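#' Specify a synthetic gamma-gliadin-like gene
#'
#' A `gene_spec` describes the architecture of one synthetic gamma-gliadin
#' gene: a signal peptide, a unique N-terminal region (domain I), a repetitive
#' domain II tiled by PQQPFPQ-family heptapeptide units with optional embedded
#' 9-mer celiac epitopes, a cysteine-rich domain III, a poly-glutamine domain
#' IV encoded by CAA codons with optional single-base-mutant interruptions,
#' and a C-terminal domain V.  [build_gamma_gene()] turns the spec into an
#' intronless ORF together with the exact ground truth of every planted
#' feature.
#'
#' @param n_repeats Number of canonical PQQPFPQ heptapeptide units in
#'   domain II (>= 0).
#' @param epitopes Named integer vector of embedded epitope copy numbers; the
#'   names are the 9-mer amino-acid sequences.  Copies are interleaved
#'   one-per-slot between consecutive heptapeptide units, so
#'   `sum(epitopes)` must be at most `n_repeats - 1`.
#' @param polyq_length Length of the domain-IV poly-Q tract, in codons (>= 0;
#'   tracts shorter than 5 are not recoverable by [find_polyq()] and are
#'   refused).
#' @param polyq_interruptions Data frame with columns `offset` (1-based codon
#'   offset within the tract, strictly inside it) and `codon` (one of CAG,
#'   GAA, CTA, each a single-base mutant of CAA).  `NULL` for none.
#' @param cysteine_layout Named integer vector of per-domain cysteine counts;
#'   recognised names are "II", "III" and "V".  Default is the conserved
#'   gamma-gliadin skeleton: six in domain III and two in domain V.
#' @param signal_length Signal-peptide length in residues (default 19).
#' @param domain1_length,domain3_length,domain5_length Lengths (residues) of
#'   the filler regions for domains I, III and V.
#' @param seed Integer RNG seed; generation is fully deterministic given the
#'   spec.
#'
#' @return An object of class `gene_spec`.
#' @seealso [build_gamma_gene()], [pseudogenize()], [build_locus()]
#' @export
#' @examples
#' spec <- gene_spec(n_repeats = 4, epitopes = c(QQPQQPFPQ = 3),
#'                   polyq_length = 20, seed = 1)
#' gene <- build_gamma_gene(spec)
#' nchar(gene$protein)
gene_spec <- function(n_repeats = 5,
                      epitopes = c(QQPQQPFPQ = 3),
                      polyq_length = 25,
                      polyq_interruptions = NULL,
                      cysteine_layout = c(III = 6, V = 2),
                      signal_length = 19,
                      domain1_length = 25,
                      domain3_length = 100,
                      domain5_length = 60,
                      seed = 1) {
  n_repeats <- as.integer(n_repeats)
  polyq_length <- as.integer(polyq_length)
  if (n_repeats < 0L) abort("n_repeats must be >= 0")
  if (polyq_length < 0L) abort("polyq_length must be >= 0")
  if (polyq_length > 0L && polyq_length < 5L) {
    abort("polyq_length must be 0 or >= 5 (shorter tracts are not recoverable)")
  }
  if (signal_length < 1L) abort("signal_length must be >= 1 (the initiator Met)")
  if (domain1_length < 1L || domain3_length < 1L || domain5_length < 1L) {
    abort("domain filler lengths must be >= 1")
  }

  if (length(epitopes)) {
    if (is.null(names(epitopes)) || any(!nzchar(names(epitopes)))) {
      abort("epitopes must be a named vector (names are the 9-mer sequences)")
    }
    names(epitopes) <- toupper(names(epitopes))
    if (any(nchar(names(epitopes)) != 9L)) {
      abort("embedded epitopes must be 9-mers")
    }
    for (e in names(epitopes)) check_aa(e, allow_x = FALSE)
    epitopes <- epitopes[epitopes > 0]
    storage.mode(epitopes) <- "integer"
    if (sum(epitopes) > max(0L, n_repeats - 1L)) {
      abort(paste0(
        "contradictory spec: ", sum(epitopes), " epitope copies cannot fit ",
        "between ", n_repeats, " heptapeptide units (at most one copy per ",
        "inter-unit slot, so at most ", max(0L, n_repeats - 1L), ")"
      ))
    }
  } else {
    epitopes <- integer(0)
  }

  if (!is.null(polyq_interruptions)) {
    polyq_interruptions <- as_tibble(polyq_interruptions)
    if (!all(c("offset", "codon") %in% names(polyq_interruptions))) {
      abort("polyq_interruptions needs columns `offset` and `codon`")
    }
    polyq_interruptions$codon <- toupper(polyq_interruptions$codon)
    polyq_interruptions$offset <- as.integer(polyq_interruptions$offset)
    bad_codon <- setdiff(polyq_interruptions$codon, names(POLYQ_INTERRUPTIONS))
    if (length(bad_codon)) {
      abort(paste0("interruption codons must be single-base mutants of CAA (",
                   paste(names(POLYQ_INTERRUPTIONS), collapse = ", "),
                   "), not: ", paste(bad_codon, collapse = ", ")))
    }
    off <- polyq_interruptions$offset
    if (any(off <= 1L | off >= polyq_length)) {
      abort("interruption offsets must lie strictly inside the poly-Q tract")
    }
    if (anyDuplicated(off)) abort("duplicated interruption offsets")
    if (any(diff(sort(off)) == 1L)) {
      abort("two consecutive interruptions would split the tract; offsets must not be adjacent")
    }
    if (polyq_length - length(off) < ceiling(0.6 * polyq_length)) {
      abort("too many interruptions: the tract must stay >= 60% CAA to be recoverable")
    }
    polyq_interruptions <- dplyr::arrange(polyq_interruptions, .data$offset)
  } else {
    polyq_interruptions <- tibble(offset = integer(0), codon = character(0))
  }

  cysteine_layout <- cysteine_layout[cysteine_layout > 0]
  if (length(cysteine_layout)) {
    bad <- setdiff(names(cysteine_layout), c("II", "III", "V"))
    if (length(bad)) {
      abort(paste0("cysteine_layout supports domains II, III and V, not: ",
                   paste(bad, collapse = ", ")))
    }
    storage.mode(cysteine_layout) <- "integer"
    if (any(cysteine_layout < 0L)) abort("cysteine counts must be >= 0")
  }
  n2 <- vec_get(cysteine_layout, "II")
  if (n2 > n_repeats) {
    abort("domain-II cysteines are planted one per heptapeptide unit; count exceeds n_repeats")
  }
  if (vec_get(cysteine_layout, "III") > domain3_length) {
    abort("more domain-III cysteines than domain-III residues")
  }
  if (vec_get(cysteine_layout, "V") > domain5_length - 1L) {
    abort("more domain-V cysteines than available domain-V positions")
  }

  structure(
    list(
      n_repeats = n_repeats,
      epitopes = epitopes,
      polyq_length = polyq_length,
      polyq_interruptions = polyq_interruptions,
      cysteine_layout = cysteine_layout,
      signal_length = as.integer(signal_length),
      domain1_length = as.integer(domain1_length),
      domain3_length = as.integer(domain3_length),
      domain5_length = as.integer(domain5_length),
      seed = as.integer(seed)
    ),
    class = "gene_spec"
  )
}

#' @export
print.gene_spec <- function(x, ...) {
  cat("<gene_spec>\n")
  cat("  heptapeptide units:", x$n_repeats, "\n")
  if (length(x$epitopes)) {
    cat("  embedded epitopes: ",
        paste0(names(x$epitopes), " x", x$epitopes, collapse = ", "), "\n")
  }
  cat("  poly-Q tract:", x$polyq_length, "codons,",
      nrow(x$polyq_interruptions), "interruption(s)\n")
  cat("  cysteines:", paste0(names(x$cysteine_layout), ":",
                             x$cysteine_layout, collapse = " "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
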