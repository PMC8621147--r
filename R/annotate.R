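# Intronless ORF discovery and gene/pseudogene classification.

#' Find intronless open reading frames in genomic sequence
#'
#' Scans the requested strands in all three frames for maximal
#' ATG-to-first-in-frame-stop stretches of at least `min_len` bp (the stop
#' codon is included in the ORF and its length).  Nested ORFs sharing a stop
#' codon are reported once, from the 5'-most ATG.  Coordinates are 1-based
#' inclusive on the forward axis regardless of strand; the reported
#' `sequence` is always the sense-strand reading (ATG ... stop).
#'
#' @param genomic Genomic nucleotide string (A/C/G/T/N; other characters are
#'   rejected).  Candidate ORFs containing N are skipped with a warning.
#' @param min_len Minimum ORF length in bp (>= 6, divisible by 3).  The
#'   default 450 sits below the shortest prolamin family member while
#'   suppressing spurious short ORFs.
#' @param strands `"both"` (default) or `"forward"`.
#' @return Tibble with columns `id`, `start`, `end`, `strand`, `length_bp`,
#'   `sequence`, ordered by genomic start.
#' @export
find_orfs <- function(genomic, min_len = 450, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  min_len <- as.integer(min_len)
  if (min_len < 6L || min_len %% 3L != 0L) {
    abort("min_len must be >= 6 and divisible by 3")
  }
  genomic <- check_nt(genomic, allow_n = TRUE)
  L <- nchar(genomic)

  res <- scan_orf_stretches(genomic, strands, min_len = min_len)
  if (!nrow(res)) {
    return(tibble(id = character(0), start = integer(0), end = integer(0),
                  strand = character(0), length_bp = integer(0),
                  sequence = character(0)))
  }
  res <- arrange(res, .data$start, .data$end)
  mutate(res, id = paste0("orf_", row_number()), .before = 1)
}

# Shared frame scanner.  mode "orf": maximal ATG-to-first-in-frame-stop
# stretches >= min_len (the spec of find_orfs).  mode "pseudogene": rescue of
# ancestral pseudogene ORFs — from a 5'-most ATG whose first-stop stretch is
# shorter than range[1], extend through successive in-frame stops; accept the
# first landing inside [range[1], range[2]] (such a region necessarily
# contains internal stop codons).
scan_orf_stretches <- function(genomic, strands, min_len = NULL,
                               mode = c("orf", "pseudogene"),
                               range = NULL) {
  mode <- match.arg(mode)
  L <- nchar(genomic)

  scan_strand <- function(seq, strand) {
    out <- list()
    for (frame in 0:2) {
      n_codons <- (nchar(seq) - frame) %/% 3L
      if (n_codons < 2L) next
      cods <- substring(seq,
                        frame + 1L + 3L * (seq_len(n_codons) - 1L),
                        frame + 3L * seq_len(n_codons))
      is_stop <- cods %in% STOP_CODONS
      is_atg <- cods == "ATG"
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (si in seq_along(stop_idx)) {
        s <- stop_idx[si]
        cand <- which(is_atg[(prev_stop + 1L):(s - 1L)])
        if (length(cand)) {
          a <- prev_stop + cand[1L]           # 5'-most ATG after previous stop
          len_bp <- (s - a + 1L) * 3L
          keep <- FALSE
          end_codon <- s
          if (mode == "orf") {
            keep <- len_bp >= min_len
          } else if (len_bp < range[1]) {
            for (sj in stop_idx[stop_idx > s]) {
              ext <- (sj - a + 1L) * 3L
              if (ext >= range[1]) {
                if (ext <= range[2]) { keep <- TRUE; end_codon <- sj }
                break
              }
            }
          }
          if (keep) {
            orf_seq <- paste(cods[a:end_codon], collapse = "")
            len_bp <- (end_codon - a + 1L) * 3L
            if (grepl("N", orf_seq, fixed = TRUE)) {
              warn(paste0("skipping candidate ORF containing N (frame ",
                          frame, ", strand ", strand, ")"))
            } else {
              st <- frame + 1L + 3L * (a - 1L)
              out[[length(out) + 1L]] <- tibble(
                start = st, end = st + len_bp - 1L,
                strand = strand, length_bp = len_bp, sequence = orf_seq
              )
            }
          }
        }
        prev_stop <- s
      }
    }
    bind_rows(out)
  }

  res <- scan_strand(genomic, "+")
  if (strands == "both") {
    rc <- scan_strand(reverse_complement(genomic), "-")
    if (nrow(rc)) {
      # map reverse-complement coordinates back onto the forward axis
      rc <- mutate(rc,
                   new_start = L - .data$end + 1L,
                   end = L - .data$start + 1L,
                   start = .data$new_start) |>
        select(-"new_start")
    }
    res <- bind_rows(res, rc)
  }
  res
}

#' Classify an ORF as a full-length gene or a pseudogene
#'
#' Scans internal codons (2 ... n-1) for in-frame stop codons.  Each internal
#' stop is recorded at the 1-based position of its first base counted from
#' the first base of the ATG (`3 * (codon_index - 1) + 1`); the putative
#' ancestral codon is inferred from the C->T glutamine-codon mechanism (TAA
#' <- CAA, TAG <- CAG) and reported as `"unknown"` for TGA.  An ORF without a
#' terminal stop codon that is shorter than `expected_len_range` is a
#' truncated pseudogene.
#'
#' @param sequence ORF nucleotide sequence, sense strand, starting ATG.
#' @param id Identifier carried into the result.
#' @param expected_len_range Length range (bp) of intact family members;
#'   default 858-996.
#' @param family_class Optional label (e.g. from [classify_family()]).
#' @return One-row tibble (class `gene_model`): `id`, `length_bp`,
#'   `family_class`, `status` ("full_length"/"pseudogene"), `truncated`,
#'   `note` (Table-style annotation such as "TAG at bp 115"), and the
#'   list-column `premature_stops` (tibble `bp`, `stop_codon`,
#'   `ancestral_codon`, `codon_index`).
#' @export
classify_orf <- function(sequence, id = "orf", expected_len_range = c(858, 996),
                         family_class = NA_character_) {
  sequence <- check_nt(sequence, allow_n = FALSE)
  if (!startsWith(sequence, "ATG")) abort("ORF must begin with ATG")
  n_bp <- nchar(sequence)
  trailing <- n_bp %% 3L
  codons <- split_codons(substr(sequence, 1L, n_bp - trailing))
  n <- length(codons)
  has_terminal_stop <- trailing == 0L && codons[n] %in% STOP_CODONS

  internal <- if (has_terminal_stop) seq_len(n - 1L)[-1L] else seq_len(n)[-1L]
  stop_at <- internal[codons[internal] %in% STOP_CODONS]
  premature <- tibble(
    bp = 3L * (stop_at - 1L) + 1L,
    stop_codon = codons[stop_at],
    ancestral_codon = dplyr::case_match(codons[stop_at],
                                        "TAA" ~ "CAA",
                                        "TAG" ~ "CAG",
                                        .default = "unknown"),
    codon_index = stop_at
  )

  truncated <- !has_terminal_stop && n_bp < expected_len_range[1]
  if (!has_terminal_stop && !truncated) {
    warn(paste0(id, ": no terminal stop codon but length within the expected ",
                "range; flagging as truncated anyway"))
    truncated <- TRUE
  }
  status <- if (nrow(premature) > 0L || truncated) "pseudogene" else "full_length"

  notes <- character(0)
  if (nrow(premature)) {
    notes <- paste0(premature$stop_codon, " at bp ", premature$bp)
  }
  if (truncated) notes <- c(notes, paste0("Truncated at bp ", n_bp))

  out <- tibble(
    id = id,
    length_bp = n_bp,
    family_class = family_class,
    status = status,
    truncated = truncated,
    note = paste(notes, collapse = "; "),
    premature_stops = list(premature)
  )
  class(out) <- c("gene_model", class(out))
  out
}

#' Translate an ORF with the standard genetic code
#'
#' The terminal stop codon is dropped.  With `readthrough = FALSE` (default)
#' translation ends at the first stop codon; with `readthrough = TRUE`
#' internal stops are rendered as `*` and translation continues to the
#' terminal stop (the convention used to display pseudogene products).
#' Codons containing N translate to `X` with a warning.  A trailing partial
#' codon (truncated ORFs) is dropped.
#'
#' @param sequence ORF nucleotide sequence (sense strand).
#' @param readthrough Logical.
#' @return Amino-acid string.
#' @export
translate_orf <- function(sequence, readthrough = FALSE) {
  sequence <- check_nt(sequence, allow_n = TRUE)
  n_bp <- nchar(sequence)
  sequence <- substr(sequence, 1L, n_bp - n_bp %% 3L)
  if (nchar(sequence) == 0L) return("")
  if (grepl("N", sequence, fixed = TRUE)) {
    warn("ambiguous codon(s) containing N translated as X")
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(sequence),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  # drop the terminal stop, if present
  aa <- sub("\\*$", "", aa)
  if (!readthrough) {
    aa <- sub("\\*.*$", "", aa)
  }
  aa
}

#' Heuristic prolamin family classification from protein features
#'
#' Assigns a configuration-driven family label from downstream sequence
#' features rather than homology search: proteins tiled by at least
#' `min_units` heptapeptide-family units are gamma-gliadins; prolamin-sized
#' glutamine-rich proteins without the repeat are labelled delta-gliadin-like;
#' shorter ones avenin-like.
#'
#' @param protein Amino-acid sequence (readthrough `*` allowed; ignored).
#' @param min_units Minimum heptapeptide-family units for the gamma call.
#' @param delta_min_len Minimum length (aa) separating delta-gliadin-like
#'   from avenin-like proteins.
#' @param avenin_min_len Minimum length for the avenin-like call.
#' @return One of "gamma_gliadin", "delta_gliadin", "avenin_like", "other".
#' @export
classify_family <- function(protein, min_units = 2, delta_min_len = 250,
                            avenin_min_len = 120) {
  clean <- gsub("*", "", protein, fixed = TRUE)
  units <- unit_matches(clean)
  q_frac <- str_count(clean, "Q") / nchar(clean)
  if (length(units) >= min_units) return("gamma_gliadin")
  if (nchar(clean) >= delta_min_len && q_frac >= 0.15) return("delta_gliadin")
  if (nchar(clean) >= avenin_min_len) return("avenin_like")
  "other"
}

#' Annotate all genes in a genomic sequence
#'
#' Convenience wrapper chaining [find_orfs()], [classify_orf()],
#' [classify_family()] and [translate_orf()] into one annotation table.
#'
#' In addition to plain ORFs, ancestral pseudogene ORFs are rescued: an
#' ATG-to-first-stop stretch shorter than `expected_len_range[1]` is extended
#' through successive in-frame stop codons, and accepted as a pseudogene
#' region when the extension lands inside `expected_len_range` (its internal
#' stops then become the premature-stop records, as in published family
#' tables where a pseudogene's printed size spans ATG to the ancestral
#' terminal stop).
#'
#' @inheritParams find_orfs
#' @param expected_len_range Passed to [classify_orf()] and used for
#'   pseudogene rescue.
#' @param readthrough Also produce readthrough products for pseudogenes.
#' @return Tibble with one row per gene region: coordinates, family class,
#'   status, note, premature-stop list-column and the deduced `protein` (NA
#'   for pseudogenes unless `readthrough`).
#' @export
annotate_genes <- function(genomic, min_len = 450, strands = "both",
                           expected_len_range = c(858, 996),
                           readthrough = FALSE) {
  orfs <- find_orfs(genomic, min_len = min_len, strands = strands)
  rescued <- scan_orf_stretches(check_nt(genomic), strands,
                                mode = "pseudogene",
                                range = expected_len_range)
  if (nrow(rescued)) {
    # one region per ATG; a rescued pseudogene supersedes the short leading
    # ORF sharing its start codon
    atg_of <- function(df) ifelse(df$strand == "+", df$start, df$end)
    if (nrow(orfs)) orfs <- orfs[!atg_of(orfs) %in% atg_of(rescued), ]
    rescued$id <- paste0("pseudo_", seq_len(nrow(rescued)))
    orfs <- bind_rows(orfs, rescued) |> arrange(.data$start, .data$end)
    orfs$id <- paste0("orf_", seq_len(nrow(orfs)))
  }
  if (!nrow(orfs)) {
    inform("no ORFs found")
    return(orfs)
  }
  models <- purrr::pmap(orfs, function(id, sequence, ...) {
    m <- classify_orf(sequence, id = id,
                      expected_len_range = expected_len_range)
    prot <- translate_orf(sequence, readthrough = TRUE)
    m$family_class <- classify_family(prot)
    m$protein <- if (m$status == "full_length" || readthrough) prot else NA_character_
    m
  })
  models <- bind_rows(models)
  out <- left_join(orfs, models, by = "id") |>
    select("id", "start", "end", "strand", "length_bp" = "length_bp.x",
           "family_class", "status", "truncated", "note",
           "premature_stops", "sequence", "protein")
  class(out) <- c("gene_annotation", class(out))
  out
}

#' Check ORF length versus protein length consistency
#'
#' For a full-length intronless gene, protein length must equal
#' `length_bp / 3 - 1` (the stop codon is included in the printed gene size).
#' Rows violating the identity are surfaced as a warning, not silently
#' corrected: published tables occasionally disagree with their own gene
#' sizes.
#'
#' @param lengths_bp Integer vector of gene sizes (bp, including the stop).
#' @param lengths_aa Integer vector of protein lengths (aa).
#' @param ids Optional labels for messages.
#' @return Logical vector, TRUE where consistent, invisibly.
#' @export
validate_length_consistency <- function(lengths_bp, lengths_aa, ids = NULL) {
  ok <- lengths_aa == lengths_bp / 3 - 1
  if (any(!ok)) {
    lab <- if (is.null(ids)) which(!ok) else ids[!ok]
    warn(paste0("ORF/protein length mismatch (aa != bp/3 - 1) for: ",
                paste(lab, collapse = ", ")))
  }
  invisible(ok)
}
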