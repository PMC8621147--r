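# Synthetic gamma-gliadin gene construction.
#
# Recoverability is engineered at the codon level: outside the planted
# poly-Q tract glutamine is encoded CAG-only and glutamate/leucine avoid
# GAA/CTA, so no CAA single-base mutant run can form outside domain IV;
# the filler alphabets exclude Met/Ile so the only in-frame or frame-shifted
# plus-strand ATG in a gene is the initiator codon, and minus-strand starts
# can only arise early in the protein, too close to the gene edge to reach an
# ORF-scanner-sized open stretch.

FILLER_AA <- c(Q = 0.22, P = 0.16, L = 0.11, V = 0.09, S = 0.09,
               T = 0.07, A = 0.08, N = 0.06, H = 0.05, Y = 0.07)
SIGNAL_AA <- c(L = 0.30, V = 0.20, A = 0.15, F = 0.10, T = 0.15, S = 0.10)

sample_filler <- function(n, alphabet = FILLER_AA) {
  paste(sample(names(alphabet), n, replace = TRUE, prob = alphabet),
        collapse = "")
}

encode_protein <- function(protein) {
  res <- split_chars(protein)
  bad <- setdiff(res, names(GEN_CODONS))
  if (length(bad)) {
    abort(paste0("no generator codon for residue(s): ", paste(bad, collapse = ", ")))
  }
  vapply(res, function(r) {
    cods <- GEN_CODONS[[r]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# near-match start positions of the heptapeptide unit (<= max_mismatch)
unit_matches <- function(protein, motif = HEPTAPEPTIDE_MOTIF, max_mismatch = 1L) {
  k <- nchar(motif)
  n <- nchar(protein)
  if (n < k) return(integer(0))
  res <- split_chars(protein)
  mot <- split_chars(motif)
  starts <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (sum(res[i:(i + k - 1L)] != mot) <= max_mismatch) starts <- c(starts, i)
  }
  starts
}

#' Build a synthetic gamma-gliadin gene with known ground truth
#'
#' Emits an intronless open reading frame (ATG ... stop) realizing the
#' architecture in `spec`, together with the exact coordinates of every
#' planted feature: domain boundaries, embedded epitope copies, cysteine
#' positions and the poly-Q tract.  The truth fields are recomputed from the
#' emitted sequence by exhaustive search, so they describe the sequence
#' verbatim; a spec whose planted epitopes collide with the surrounding
#' sequence (extra accidental copies) is rejected.
#'
#' @param spec A [gene_spec()].
#' @param id Gene identifier carried into downstream tables.
#' @return An object of class `synthetic_gene`: a list with elements
#'   `id`, `dna`, `protein` (full preprotein, no stop), `domains` (tibble of
#'   1-based inclusive protein intervals for S, I, II, III, IV, V; empty
#'   domains have NA bounds), `epitopes` (tibble `name`, `start`),
#'   `cysteine_positions`, `polyq` (codon-level tract description),
#'   `pseudogene_stop` (NULL here; see [pseudogenize()]), `truncated`, and
#'   the originating `spec`.
#' @export
build_gamma_gene <- function(spec, id = "synth_gene") {
  stopifnot(inherits(spec, "gene_spec"))
  for (attempt in 0:24) {
    gene <- with_local_seed(spec$seed + attempt * 1000003L,
                            build_gamma_gene_once(spec, id))
    if (!is.null(gene)) return(gene)
  }
  abort(paste0(
    "contradictory spec: could not realize the requested gene without ",
    "accidental copies of a planted feature (epitope, heptapeptide unit or ",
    "poly-Q run) outside its domain"
  ))
}

build_gamma_gene_once <- function(spec, id) {
  # -- protein-level assembly -------------------------------------------------
  signal <- paste0("M", sample_filler(spec$signal_length - 1L, SIGNAL_AA))
  d1 <- sample_filler(spec$domain1_length)

  # domain II: heptapeptide units with at most one epitope per inter-unit slot
  n_units <- spec$n_repeats
  units <- rep(HEPTAPEPTIDE_MOTIF, n_units)
  n_cys2 <- vec_get(spec$cysteine_layout, "II")
  if (n_cys2 > 0L) {
    # extra cysteine(s) carried inside a unit as a single-residue variant
    # (mimicking the TCC/TAC -> TGC point mutation)
    idx <- sample(seq_len(n_units), n_cys2)
    for (i in idx) substr(units[i], 5L, 5L) <- "C"
  }
  copies <- rep(names(spec$epitopes), spec$epitopes)
  slot_of <- integer(0)
  if (length(copies)) {
    slot_of <- sort(sample(seq_len(n_units - 1L), length(copies)))
    copies <- sample(copies)  # shuffle which epitope lands in which slot
  }
  assemble_d2 <- function(sep) {
    parts <- character(0)
    for (u in seq_len(n_units)) {
      parts <- c(parts, units[u])
      here <- which(slot_of == u)
      if (length(here)) parts <- c(parts, paste0(copies[here], sep))
    }
    paste(parts, collapse = "")
  }
  d2 <- assemble_d2("")
  if (length(copies)) {
    # an epitope junction can accidentally spell an extra copy of a planted
    # epitope (e.g. a ...QQ tail followed by PQQPFPQ reads QQPQQPFPQ); a
    # proline spacer after each embedded epitope breaks such junctions
    extra <- vapply(names(spec$epitopes), function(e)
      length(find_all_starts(d2, e)) > spec$epitopes[[e]], logical(1))
    if (any(extra)) d2 <- assemble_d2("P")
  }

  d3 <- sample_filler(spec$domain3_length)
  n_cys3 <- vec_get(spec$cysteine_layout, "III")
  if (n_cys3 > 0L) {
    pos3 <- sort(sample(seq_len(spec$domain3_length - 1L), n_cys3))
    for (p in pos3) substr(d3, p, p) <- "C"
  }
  # residue flanking the tract must not be glutamine (a CAG next to the tract
  # would extend the recoverable run)
  if (spec$polyq_length > 0L && substr(d3, nchar(d3), nchar(d3)) %in% c("Q", "C")) {
    substr(d3, nchar(d3), nchar(d3)) <- "P"
  }

  # domain IV: poly-Q tract at codon resolution
  tract_codons <- rep(POLYQ_CANONICAL, spec$polyq_length)
  if (nrow(spec$polyq_interruptions)) {
    tract_codons[spec$polyq_interruptions$offset] <- spec$polyq_interruptions$codon
  }
  d4 <- paste(vapply(tract_codons, function(cd) {
    if (cd == POLYQ_CANONICAL) "Q" else POLYQ_INTERRUPTIONS[[cd]]
  }, character(1)), collapse = "")

  d5 <- sample_filler(spec$domain5_length)
  n_cys5 <- vec_get(spec$cysteine_layout, "V")
  if (n_cys5 > 0L) {
    # never at position 1: the codon after the tract must not start TG (a
    # trailing CAA would otherwise spell a frame-shifted ATG)
    pos5 <- sort(sample(2:spec$domain5_length, n_cys5))
    for (p in pos5) substr(d5, p, p) <- "C"
  }
  if (spec$polyq_length > 0L && substr(d5, 1L, 1L) == "Q") substr(d5, 1L, 1L) <- "P"

  protein <- paste0(signal, d1, d2, d3, d4, d5)

  # -- ground-truth coordinates ----------------------------------------------
  lens <- c(S = nchar(signal), I = nchar(d1), II = nchar(d2),
            III = nchar(d3), IV = nchar(d4), V = nchar(d5))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  domains <- tibble(
    domain = names(lens),
    start = unname(ifelse(lens > 0L, as.integer(starts), NA_integer_)),
    end = unname(ifelse(lens > 0L, as.integer(ends), NA_integer_))
  )
  # merge boundaries the segmenter cannot resolve (see segment_domains):
  # without a repetitive domain II the I/III boundary is unknowable; without a
  # poly-Q tract the III/V boundary is unknowable.
  if (lens[["II"]] == 0L && lens[["IV"]] > 0L) {
    domains$start[domains$domain == "I"] <- as.integer(starts[["I"]])
    domains$end[domains$domain == "I"] <- as.integer(ends[["III"]])
    domains[domains$domain == "III", c("start", "end")] <- NA_integer_
  }
  if (lens[["IV"]] == 0L && lens[["II"]] > 0L) {
    domains$start[domains$domain == "III"] <- as.integer(starts[["III"]])
    domains$end[domains$domain == "III"] <- as.integer(ends[["V"]])
    domains[domains$domain == "V", c("start", "end")] <- NA_integer_
  }
  if (lens[["II"]] == 0L && lens[["IV"]] == 0L) {
    domains$start[domains$domain == "I"] <- as.integer(starts[["I"]])
    domains$end[domains$domain == "I"] <- as.integer(ends[["V"]])
    domains[domains$domain %in% c("III", "V"), c("start", "end")] <- NA_integer_
  }

  ii <- c(starts[["II"]], ends[["II"]])

  # -- encode and validate ----------------------------------------------------
  codons <- encode_protein(protein)
  if (spec$polyq_length > 0L) {
    codons[(starts[["IV"]]):(ends[["IV"]])] <- tract_codons
  }
  dna <- paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1L))

  # truth epitopes: exhaustive scan must reproduce exactly the planted copies
  epitopes <- tibble(name = character(0), start = integer(0))
  if (length(spec$epitopes)) {
    ok <- TRUE
    rows <- list()
    for (e in names(spec$epitopes)) {
      st <- find_all_starts(protein, e)
      if (length(st) != spec$epitopes[[e]]) ok <- FALSE
      rows[[e]] <- tibble(name = e, start = st)
    }
    if (!ok) return(NULL)  # accidental extra copy: retry with fresh fillers
    epitopes <- bind_rows(rows)
  }

  # heptapeptide-family matches must all lie inside domain II and span it
  um <- unit_matches(protein)
  if (lens[["II"]] > 0L) {
    if (!length(um) || min(um) != ii[1] || max(um) + 6L != ii[2] ||
        any(um < ii[1] | um + 6L > ii[2])) {
      return(NULL)
    }
  } else if (length(um)) {
    return(NULL)
  }

  # poly-Q truth must be what find_polyq() recovers
  pq <- find_polyq(dna)
  if (spec$polyq_length > 0L) {
    if (pq$length != spec$polyq_length || pq$start_codon != starts[["IV"]]) {
      return(NULL)
    }
  } else if (pq$length != 0L) {
    return(NULL)
  }

  cys <- find_all_starts(protein, "C")

  structure(
    list(
      id = id,
      dna = dna,
      protein = protein,
      domains = domains,
      epitopes = epitopes,
      cysteine_positions = as.integer(cys),
      polyq = pq,
      pseudogene_stop = NULL,
      truncated = FALSE,
      spec = spec
    ),
    class = "synthetic_gene"
  )
}

#' @export
print.synthetic_gene <- function(x, ...) {
  cat("<synthetic_gene> ", x$id, ": ", nchar(x$dna), " bp, ",
      nchar(x$protein), " aa", sep = "")
  if (!is.null(x$pseudogene_stop)) {
    cat(" [pseudogene: ", x$pseudogene_stop$stop_codon, " at bp ",
        x$pseudogene_stop$bp, "]", sep = "")
  }
  if (isTRUE(x$truncated)) cat(" [truncated]")
  cat("\n")
  invisible(x)
}

#' Pseudogenize a synthetic gene by a C-to-T transition in a glutamine codon
#'
#' Applies the mutational mechanism that inactivates prolamin genes: the first
#' base of a glutamine codon (CAA or CAG) is substituted C -> T, turning it
#' into a premature TAA or TAG stop codon.  Exactly one base changes.
#'
#' @param gene A `synthetic_gene`.
#' @param codon_index 1-based codon index (from the ATG); the codon there must
#'   be CAA or CAG.
#' @return The modified `synthetic_gene`; `pseudogene_stop` records the stop's
#'   1-based bp position from the first base of the ATG
#'   (`3 * (codon_index - 1) + 1`), the new stop codon and the ancestral
#'   glutamine codon.  The `protein` field becomes the readthrough product
#'   with `*` at the mutated residue.
#' @export
pseudogenize <- function(gene, codon_index) {
  stopifnot(inherits(gene, "synthetic_gene"))
  codon_index <- as.integer(codon_index)
  codons <- split_codons(gene$dna)
  if (codon_index < 1L || codon_index > length(codons)) {
    abort("codon_index outside the ORF")
  }
  ancestral <- codons[codon_index]
  if (!ancestral %in% c("CAA", "CAG")) {
    abort(paste0(
      "codon ", codon_index, " is ", ancestral, ", not a glutamine codon; ",
      "the C->T pseudogenization mechanism applies only to CAA/CAG"
    ))
  }
  new_stop <- sub("^C", "T", ancestral)
  codons[codon_index] <- new_stop
  gene$dna <- paste(codons, collapse = "")
  gene$pseudogene_stop <- tibble(
    bp = 3L * (codon_index - 1L) + 1L,
    stop_codon = new_stop,
    ancestral_codon = ancestral,
    codon_index = codon_index
  )
  p <- gene$protein
  substr(p, codon_index, codon_index) <- "*"
  gene$protein <- p
  gene
}

#' Truncate a synthetic gene at a base position
#'
#' Produces a truncation variant: the ORF is cut after `at_bp` bases and
#' carries no terminal stop codon (the pattern of a pseudogene truncated by
#' assembly or rearrangement).
#'
#' @param gene A `synthetic_gene`.
#' @param at_bp Last retained base (1-based from the ATG); must be < the full
#'   ORF length.
#' @return The truncated `synthetic_gene` (`truncated = TRUE`).
#' @export
truncate_gene <- function(gene, at_bp) {
  stopifnot(inherits(gene, "synthetic_gene"))
  at_bp <- as.integer(at_bp)
  if (at_bp < 3L || at_bp >= nchar(gene$dna)) {
    abort("at_bp must lie inside the ORF")
  }
  gene$dna <- substr(gene$dna, 1L, at_bp)
  gene$truncated <- TRUE
  keep_aa <- at_bp %/% 3L
  gene$protein <- substr(gene$protein, 1L, keep_aa)
  gene
}
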