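# Celiac-disease epitope database handling and exact-match scanning.

#' Load a celiac-disease epitope database
#'
#' Reads a TSV with columns `name`, `hla`, `sequence` and optionally
#' `deamidation_mask` (carried as metadata only; matching is always on the
#' native glutamine-form sequence).  The bundled default database holds the
#' ten 9-mer T-cell epitope cores identified in wheat gamma-gliadins,
#' including the duplicated 9-mer QQPQQPFPQ listed under both its DQ2.5 and
#' DQ8 restrictions.  Duplicate sequences are allowed; duplicate names are
#' rejected.  Rows with a sequence that is not nine standard residues are
#' rejected with their line number.
#'
#' @param path TSV path, or `NULL` for the bundled database.
#' @return Tibble of class `epitope_db` with columns `name`, `hla`,
#'   `sequence`, `deamidation_mask`.
#' @export
load_epitope_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cd_epitopes.tsv", package = "gliadinr")
  }
  if (!file.exists(path)) abort(paste0("epitope database not found: ", path))
  db <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", fill = TRUE)
  db <- as_tibble(db)
  need <- c("name", "hla", "sequence")
  if (!all(need %in% names(db))) {
    abort(paste0("epitope database must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (!"deamidation_mask" %in% names(db)) db$deamidation_mask <- NA_character_
  db$sequence <- toupper(db$sequence)

  line_no <- seq_len(nrow(db)) + 1L  # header is line 1
  bad_len <- nchar(db$sequence) != 9L
  bad_res <- grepl(paste0("[^", paste(names(AA_AVG_MASS), collapse = ""), "]"),
                   db$sequence)
  if (any(bad_len | bad_res)) {
    bad <- which(bad_len | bad_res)
    abort(paste0(
      "invalid epitope row(s) at line ", paste(line_no[bad], collapse = ", "),
      ": sequences must be 9-mers over the 20 standard residues"
    ))
  }
  dup <- duplicated(db$name)
  if (any(dup)) {
    abort(paste0("duplicate epitope name(s): ",
                 paste(unique(db$name[dup]), collapse = ", ")))
  }
  out <- db[, c("name", "hla", "sequence", "deamidation_mask")]
  class(out) <- c("epitope_db", class(out))
  out
}

#' Scan proteins for exact epitope matches
#'
#' Reports every exact-match start position of every database epitope in
#' every protein.  Only exact matches are considered; the default counting
#' convention is overlapping (all start positions).  Results are independent
#' of database row order.
#'
#' @param proteins Named character vector of amino-acid sequences (or a
#'   single unnamed sequence, reported as `protein_1`), or a data frame with
#'   columns `id` and `protein`.
#' @param db An [load_epitope_db()] tibble (default: the bundled database).
#' @param mode `"overlapping"` (all start positions) or `"non_overlapping"`
#'   (greedy left-to-right).
#' @return Tibble with columns `protein_id`, `epitope`, `hla`, `sequence`,
#'   `start` (1-based), one row per hit, ordered by protein, epitope name
#'   and position.
#' @export
scan_epitopes <- function(proteins, db = load_epitope_db(),
                          mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  proteins <- as_protein_vector(proteins)
  rows <- list()
  for (pid in names(proteins)) {
    p <- toupper(proteins[[pid]])
    if (nchar(p) == 0L) abort(paste0("empty protein: ", pid))
    for (k in seq_len(nrow(db))) {
      hit <- count_repeat_motif(p, db$sequence[k], mode = mode)
      if (hit$count > 0L) {
        rows[[length(rows) + 1L]] <- tibble(
          protein_id = pid, epitope = db$name[k], hla = db$hla[k],
          sequence = db$sequence[k], start = hit$starts
        )
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(protein_id = character(0), epitope = character(0),
           hla = character(0), sequence = character(0), start = integer(0))
  }
  arrange(out, .data$protein_id, .data$epitope, .data$start)
}

as_protein_vector <- function(proteins) {
  if (is.data.frame(proteins)) {
    if (!all(c("id", "protein") %in% names(proteins))) {
      abort("protein data frame needs columns `id` and `protein`")
    }
    return(setNames(proteins$protein, proteins$id))
  }
  if (is.null(names(proteins))) {
    names(proteins) <- paste0("protein_", seq_along(proteins))
  }
  proteins
}

#' Summarize epitope hits for one protein
#'
#' Aggregates per-epitope copy counts, computes the clustering fraction
#' (hits starting inside domain II over all hits) and counts the B-cell
#' 7-mer QPQQPFP with the same overlapping convention, and builds a
#' positional map of the hits on protein coordinates.
#'
#' @param hits A [scan_epitopes()] tibble for a single protein.
#' @param segmentation The protein's [segment_domains()] result.
#' @param protein The protein sequence itself (for the B-cell motif count).
#' @return List of class `epitope_summary`: `counts` (tibble `epitope`,
#'   `hla`, `sequence`, `count`), `total_hits`, `clustering_fraction` (0
#'   with `no_hits = TRUE` when there are no hits), `bcell_7mer_count`, and
#'   `map`, a BED-like tibble (`protein_id`, `start`, `end`, `epitope`;
#'   1-based inclusive, overlaps preserved).
#' @export
epitope_summary <- function(hits, segmentation, protein) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (length(unique(hits$protein_id)) > 1L) {
    abort("epitope_summary() summarizes one protein at a time")
  }
  if (nrow(hits) && any(hits$start < 1L | hits$start + nchar(hits$sequence) - 1L > n)) {
    abort("hit position outside the protein")
  }
  counts <- hits |>
    group_by(.data$epitope, .data$hla, .data$sequence) |>
    summarise(count = dplyr::n(), .groups = "drop") |>
    arrange(.data$epitope)
  total <- nrow(hits)

  ii <- segmentation[segmentation$domain == "II", ]
  no_hits <- total == 0L
  clustering <- if (no_hits) {
    0
  } else if (is.na(ii$start)) {
    0
  } else {
    sum(hits$start >= ii$start & hits$start <= ii$end) / total
  }

  bcell <- count_repeat_motif(protein, BCELL_MOTIF, mode = "overlapping")$count

  map <- if (total) {
    tibble(protein_id = hits$protein_id,
           start = hits$start,
           end = hits$start + nchar(hits$sequence) - 1L,
           epitope = hits$epitope)
  } else {
    tibble(protein_id = character(0), start = integer(0), end = integer(0),
           epitope = character(0))
  }

  structure(
    list(counts = counts, total_hits = total,
         clustering_fraction = clustering, no_hits = no_hits,
         bcell_7mer_count = bcell, map = map,
         protein_length = n),
    class = "epitope_summary"
  )
}

#' @export
print.epitope_summary <- function(x, ...) {
  cat("<epitope_summary> ", x$total_hits, " hit(s), clustering fraction ",
      sprintf("%.2f", x$clustering_fraction),
      if (x$no_hits) " (no hits)" else "", ", B-cell 7-mer x",
      x$bcell_7mer_count, "\n", sep = "")
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Epitope copy-number matrix across proteins
#'
#' The epitopes-by-proteins count table: one row per database epitope, one
#' count column per protein (zero where absent).
#'
#' @inheritParams scan_epitopes
#' @return Tibble with columns `hla`, `epitope`, `sequence` and one integer
#'   column per protein.
#' @export
epitope_count_matrix <- function(proteins, db = load_epitope_db(),
                                 mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  proteins <- as_protein_vector(proteins)
  hits <- scan_epitopes(proteins, db, mode = mode)
  counts <- hits |> count(.data$protein_id, .data$epitope, name = "count")
  grid <- tidyr::expand_grid(epitope = db$name, protein_id = names(proteins)) |>
    left_join(counts, by = c("epitope", "protein_id")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    tidyr::pivot_wider(names_from = "protein_id", values_from = "count")
  db |>
    select("hla", "epitope" = "name", "sequence") |>
    left_join(grid, by = "epitope")
}
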