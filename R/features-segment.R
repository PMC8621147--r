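# Six-domain segmentation of gamma-gliadin proteins and the repeat /
# poly-Q / cysteine feature extractors behind it.

#' Count a repeat motif in a protein
#'
#' Exact substring matching.  `overlapping` reports all start positions;
#' `non_overlapping` counts greedily left to right.
#'
#' @param protein Amino-acid sequence.
#' @param motif Peptide motif (default the gamma-gliadin heptapeptide
#'   PQQPFPQ).
#' @param mode Counting convention.
#' @return List with `count` and integer `starts` (1-based).
#' @export
count_repeat_motif <- function(protein, motif = HEPTAPEPTIDE_MOTIF,
                               mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  protein <- toupper(protein)
  motif <- toupper(motif)
  if (nchar(motif) == 0L) abort("motif must be non-empty")
  if (nchar(motif) > nchar(protein)) return(list(count = 0L, starts = integer(0)))
  starts <- find_all_starts(protein, motif)
  if (mode == "non_overlapping" && length(starts) > 1L) {
    keep <- starts[1L]
    for (s in starts[-1L]) {
      if (s >= keep[length(keep)] + nchar(motif)) keep <- c(keep, s)
    }
    starts <- keep
  }
  list(count = length(starts), starts = as.integer(starts))
}

#' Locate the poly-glutamine tract in an ORF
#'
#' Finds the longest codon run in which every codon is CAA or one of its
#' accepted single-base mutants (CAG, GAA, CTA), subject to: at least
#' `ceiling(0.6 * run)` CAA codons and no two consecutive non-CAA codons.
#' Runs shorter than 5 codons are not reported.  Ties go to the leftmost run.
#'
#' @param orf Nucleotide ORF (length divisible by 3).
#' @return List of class `polyq_tract`: `start_codon`, `end_codon` (1-based
#'   codon indices; NA when empty), `length`, `caa_count`, and
#'   `interruptions`, a tibble of `offset` (within the tract), `codon` and
#'   `residue`.
#' @export
find_polyq <- function(orf) {
  orf <- check_nt(orf, allow_n = FALSE)
  codons <- split_codons(orf)
  ok_codon <- codons == POLYQ_CANONICAL | codons %in% names(POLYQ_INTERRUPTIONS)
  is_caa <- codons == POLYQ_CANONICAL

  best <- NULL
  r <- rle(ok_codon)
  stretch_end <- cumsum(r$lengths)
  stretch_start <- stretch_end - r$lengths + 1L
  for (k in which(r$values)) {
    lo <- stretch_start[k]; hi <- stretch_end[k]
    # longest valid subrun within [lo, hi]
    for (i in lo:hi) {
      for (j in hi:i) {
        len <- j - i + 1L
        if (!is.null(best) && len <= best$length) break
        caa <- sum(is_caa[i:j])
        if (caa < ceiling(0.6 * len)) next
        non <- which(!is_caa[i:j])
        if (length(non) > 1L && any(diff(non) == 1L)) next
        if (len >= 5L) best <- list(start = i, end = j, length = len, caa = caa)
        break  # for this i, longer j already tried first
      }
    }
  }

  if (is.null(best)) {
    out <- list(start_codon = NA_integer_, end_codon = NA_integer_,
                length = 0L, caa_count = 0L,
                interruptions = tibble(offset = integer(0), codon = character(0),
                                       residue = character(0)))
  } else {
    idx <- best$start:best$end
    non <- idx[!is_caa[idx]]
    out <- list(
      start_codon = best$start, end_codon = best$end,
      length = best$length, caa_count = best$caa,
      interruptions = tibble(
        offset = non - best$start + 1L,
        codon = codons[non],
        residue = unname(POLYQ_INTERRUPTIONS[codons[non]])
      )
    )
  }
  structure(out, class = "polyq_tract")
}

#' @export
print.polyq_tract <- function(x, ...) {
  if (x$length == 0L) {
    cat("<polyq_tract> none found\n")
  } else {
    cat("<polyq_tract> codons ", x$start_codon, "-", x$end_codon,
        " (", x$length, " codons, ", x$caa_count, " CAA, ",
        nrow(x$interruptions), " interruption(s))\n", sep = "")
  }
  invisible(x)
}

# protein-level poly-Q run used when no nucleotide sequence is available:
# same run rules with Q in place of CAA and any single non-Q residue as an
# interruption.
find_polyq_protein <- function(protein, from = 1L) {
  res <- split_chars(protein)
  n <- length(res)
  if (from > n) return(c(NA_integer_, NA_integer_))
  is_q <- res == "Q"
  best <- NULL
  i <- from
  while (i <= n) {
    if (!is_q[i]) { i <- i + 1L; next }
    j <- i
    repeat {
      # extend: next position may be non-Q only if followed by Q
      if (j + 1L <= n && is_q[j + 1L]) j <- j + 1L
      else if (j + 2L <= n && !is_q[j + 1L] && is_q[j + 2L]) j <- j + 2L
      else break
    }
    len <- j - i + 1L
    qn <- sum(is_q[i:j])
    if (len >= 5L && qn >= ceiling(0.6 * len) &&
        (is.null(best) || len > best[2] - best[1] + 1L)) {
      best <- c(i, j)
    }
    i <- j + 1L
  }
  if (is.null(best)) c(NA_integer_, NA_integer_) else best
}

#' Segment a gamma-gliadin protein into its six domains
#'
#' Partitions the preprotein into signal peptide (S), unique N-terminal
#' region (I), the repetitive heptapeptide domain (II), the first
#' non-repetitive cysteine-rich region (III), the poly-glutamine repetitive
#' domain (IV) and the C-terminal region (V).  Domain II is the span of the
#' densest chain of heptapeptide-family units (<= `max_mismatch` mismatches
#' per unit, at least `min_units` units, inter-unit gaps of at most
#' `max_gap` residues, which accommodates an embedded 9-mer epitope
#' plus a one-residue junction spacer).  Domain
#' IV is the protein projection of the poly-Q tract, taken from the
#' nucleotide ORF when supplied ([find_polyq()]) or from a protein-level run
#' otherwise.  Boundaries that the sequence cannot define are merged: with no
#' repetitive domain II the I/III boundary is unknowable and the span is
#' reported as domain I; with no poly-Q tract the III/V boundary is
#' unknowable and the span is reported as domain III.
#'
#' @param protein Amino-acid sequence without `*` (segment readthrough
#'   products explicitly on the cleaned sequence if desired).
#' @param orf Optional nucleotide ORF matching `protein` (same codon
#'   numbering) for codon-level poly-Q detection.
#' @param signal_length Signal peptide length in residues (default 19; the
#'   boundary is a configuration, not a prediction).
#' @param motif,max_mismatch,min_units,max_gap Domain-II chaining parameters.
#' @return Tibble of class `domain_segmentation` with columns `domain`
#'   (S, I, II, III, IV, V), `start`, `end` (1-based inclusive; NA for empty
#'   domains), and attribute `protein_length`.
#' @export
segment_domains <- function(protein, orf = NULL, signal_length = 19,
                            motif = HEPTAPEPTIDE_MOTIF, max_mismatch = 1,
                            min_units = 2, max_gap = 10) {
  protein <- check_aa(protein, allow_stop = FALSE)
  n <- nchar(protein)
  if (n == 0L) abort("empty protein")
  s_end <- max(0L, min(as.integer(signal_length), n))

  # domain II: densest chain of near-units
  um <- unit_matches(protein, motif, max_mismatch)
  um <- um[um > s_end]
  ii <- c(NA_integer_, NA_integer_)
  if (length(um) >= min_units) {
    gap_break <- which(diff(um) > nchar(motif) + max_gap)
    chain_id <- cumsum(c(1L, seq_along(um)[-1] %in% (gap_break + 1L)))
    chains <- split(um, chain_id)
    sizes <- lengths(chains)
    spans <- vapply(chains, function(s) max(s) + nchar(motif) - 1L - min(s),
                    numeric(1))
    ok <- sizes >= min_units
    if (any(ok)) {
      cand <- which(ok)
      pick <- cand[order(-sizes[cand], -spans[cand])][1L]
      ch <- chains[[pick]]
      ii <- c(min(ch), max(ch) + nchar(motif) - 1L)
    }
  }

  # domain IV: poly-Q projection, searched after domain II
  after <- if (!is.na(ii[1])) ii[2] + 1L else s_end + 1L
  if (!is.null(orf)) {
    pq <- find_polyq(orf)
    iv <- if (pq$length > 0L && pq$start_codon >= after) {
      c(pq$start_codon, pq$end_codon)
    } else c(NA_integer_, NA_integer_)
  } else {
    iv <- find_polyq_protein(protein, from = after)
  }

  empty <- c(NA_integer_, NA_integer_)
  if (is.na(ii[1]) && is.na(iv[1])) {
    warn("non-gliadin-like architecture: no heptapeptide window and no poly-Q tract")
    seg <- list(S = if (s_end >= 1L) c(1L, s_end) else empty,
                I = if (s_end < n) c(s_end + 1L, n) else empty,
                II = empty, III = empty, IV = empty, V = empty)
  } else if (is.na(ii[1])) {
    seg <- list(
      S = if (s_end >= 1L) c(1L, s_end) else empty,
      I = if (iv[1] > s_end + 1L) c(s_end + 1L, iv[1] - 1L) else empty,
      II = empty, III = empty, IV = iv,
      V = if (iv[2] < n) c(iv[2] + 1L, n) else empty
    )
  } else if (is.na(iv[1])) {
    seg <- list(
      S = if (s_end >= 1L) c(1L, s_end) else empty,
      I = if (ii[1] > s_end + 1L) c(s_end + 1L, ii[1] - 1L) else empty,
      II = ii,
      III = if (ii[2] < n) c(ii[2] + 1L, n) else empty,
      IV = empty, V = empty
    )
  } else {
    seg <- list(
      S = if (s_end >= 1L) c(1L, s_end) else empty,
      I = if (ii[1] > s_end + 1L) c(s_end + 1L, ii[1] - 1L) else empty,
      II = ii,
      III = if (iv[1] > ii[2] + 1L) c(ii[2] + 1L, iv[1] - 1L) else empty,
      IV = iv,
      V = if (iv[2] < n) c(iv[2] + 1L, n) else empty
    )
  }

  out <- tibble(
    domain = names(seg),
    start = unname(vapply(seg, `[`, integer(1), 1L)),
    end = unname(vapply(seg, `[`, integer(1), 2L))
  )
  attr(out, "protein_length") <- n
  class(out) <- c("domain_segmentation", class(out))
  out
}

domain_of_position <- function(segmentation, pos) {
  hit <- with(segmentation, domain[!is.na(start) & pos >= start & pos <= end])
  if (length(hit)) hit[1] else NA_character_
}

#' Profile the cysteine skeleton of a gamma-gliadin protein
#'
#' Reports all cysteine positions, per-domain counts, whether the protein
#' carries the conserved gamma-gliadin skeleton (exactly six cysteines in
#' domain III, two in domain V, eight total), any cysteines outside that
#' layout, and a configurable adjacency check between two of the domain-III
#' cysteines (reported separately; not part of the canonical flag).
#'
#' @param protein Amino-acid sequence.
#' @param segmentation A [segment_domains()] result for the same protein.
#' @param adjacency_pair Ranks (within domain III) of the cysteine pair whose
#'   adjacency is reported; default the 4th and 6th.
#' @return List of class `cysteine_profile`: `total`, `positions`,
#'   `per_domain` (tibble), `canonical` (logical), `extra_positions`,
#'   `adjacent_pair` (logical or NA).
#' @export
cysteine_profile <- function(protein, segmentation, adjacency_pair = c(4, 6)) {
  protein <- toupper(protein)
  if (attr(segmentation, "protein_length") != nchar(protein)) {
    abort("segmentation does not belong to this protein")
  }
  pos <- find_all_starts(protein, "C")
  dom <- vapply(pos, function(p) domain_of_position(segmentation, p),
                character(1))
  per_domain <- tibble(domain = c("S", "I", "II", "III", "IV", "V")) |>
    left_join(tibble(domain = dom) |> count(domain), by = "domain") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  n3 <- per_domain$n[per_domain$domain == "III"]
  n5 <- per_domain$n[per_domain$domain == "V"]
  canonical <- length(pos) == 8L && n3 == 6L && n5 == 2L
  extra <- pos[!dom %in% c("III", "V")]

  adjacent <- NA
  in3 <- pos[dom %in% "III"]
  if (length(in3) >= max(adjacency_pair)) {
    adjacent <- (in3[adjacency_pair[2]] - in3[adjacency_pair[1]]) == 1L ||
      abs(diff(in3[adjacency_pair])) == 1L
  }

  structure(
    list(total = length(pos), positions = as.integer(pos),
         per_domain = per_domain, canonical = canonical,
         extra_positions = as.integer(extra), adjacent_pair = adjacent),
    class = "cysteine_profile"
  )
}

#' @export
print.cysteine_profile <- function(x, ...) {
  cat("<cysteine_profile> ", x$total, " cysteine(s); canonical skeleton: ",
      x$canonical, "\n", sep = "")
  counts <- setNames(x$per_domain$n, x$per_domain$domain)
  cat("  per domain:", paste0(names(counts), ":", counts, collapse = " "), "\n")
  if (length(x$extra_positions)) {
    cat("  outside III/V at:", paste(x$extra_positions, collapse = ", "), "\n")
  }
  invisible(x)
}
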