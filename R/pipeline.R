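# End-to-end orchestration: genomic FASTA in, annotation / features /
# epitope / identity / tree reports out.

#' Run the full gamma-gliadin characterization pipeline
#'
#' Chains ORF discovery ([find_orfs()]), gene/pseudogene classification
#' ([classify_orf()]), translation, domain segmentation, protein feature and
#' physicochemical profiling, epitope scanning, the dual identity matrix and
#' the neighbor-joining tree, and writes every report to `output_dir`:
#'
#' * `annotation.tsv` / `annotation.gff3` — gene table with coordinates,
#'   status and stop-codon notes ("TAG at bp 115" style);
#' * `protein_features.tsv` — per-protein length, cysteine count, MW (Da),
#'   pI, composition and repeat/poly-Q summaries;
#' * `epitope_counts.tsv` — epitopes x proteins copy-number matrix;
#' * `epitope_map.tsv` — per-protein positional map (1-based inclusive);
#' * `identity_matrix.tsv` — NT above / AA below the diagonal;
#' * `tree.nwk` — NJ tree on `100 - AA identity` (two or more proteins);
#' * `manifest.json` — tool version, settings and seed.
#'
#' Pseudogene products are excluded from the feature and epitope reports
#' unless `readthrough = TRUE`, in which case their readthrough products
#' (internal stops removed) are included and flagged.  Re-running with the
#' same inputs and settings reproduces byte-identical outputs.
#'
#' @param input Path to a genomic nucleotide FASTA, or a named character
#'   vector of sequences.
#' @param output_dir Output directory (created if needed).
#' @param epitope_db Path to an epitope TSV, or `NULL` for the bundled
#'   database.
#' @param min_len,strands Passed to [find_orfs()].
#' @param expected_len_range Passed to [classify_orf()].
#' @param signal_length Passed to [segment_domains()].
#' @param readthrough Include pseudogene readthrough products downstream.
#' @param seed Integer; recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list of class `gliadin_report` with elements
#'   `annotation`, `features`, `epitope_counts`, `epitope_map`, `identity`,
#'   `tree`, `files`.
#' @export
run_pipeline <- function(input, output_dir, epitope_db = NULL,
                         min_len = 450, strands = "both",
                         expected_len_range = c(858, 996),
                         signal_length = 19, readthrough = FALSE, seed = 1) {
  # validate configuration before touching the filesystem
  if (!is.null(epitope_db) && !file.exists(epitope_db)) {
    abort(paste0("epitope database not found: ", epitope_db))
  }
  db <- load_epitope_db(epitope_db)
  seqs <- if (is.character(input) && length(input) == 1L && file.exists(input)) {
    read_fasta(input, type = "nt")
  } else if (is.character(input)) {
    if (!length(input)) abort("empty input FASTA")
    if (is.null(names(input))) names(input) <- paste0("seq_", seq_along(input))
    toupper(input)
  } else {
    abort("input must be a FASTA path or a named character vector")
  }
  if (!length(seqs) || !any(nzchar(seqs))) abort("empty input FASTA")

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  # -- stage 1: annotation ----------------------------------------------------
  ann <- purrr::imap(seqs, function(s, nm) {
    a <- annotate_genes(s, min_len = min_len, strands = strands,
                        expected_len_range = expected_len_range,
                        readthrough = TRUE)
    if (nrow(a)) a$seqid <- nm
    a
  }) |> bind_rows()
  if (!nrow(ann)) abort("pipeline stage 'annotate': no ORFs found in input")
  ann$id <- make.unique(paste0("gene_", seq_len(nrow(ann))), sep = "_")

  include <- ann$status == "full_length" | readthrough
  prods <- setNames(gsub("*", "", ann$protein, fixed = TRUE), ann$id)[include]
  orfs <- setNames(ann$sequence, ann$id)[include]

  # -- stage 2: protein features ---------------------------------------------
  feats <- purrr::map(names(prods), function(id) {
    p <- prods[[id]]
    seg <- segment_domains(p, orf = if (ann$status[ann$id == id] == "full_length")
      orfs[[id]] else NULL, signal_length = signal_length)
    cys <- cysteine_profile(p, seg)
    ph <- physchem(p)
    rep_cnt <- count_repeat_motif(p, mode = "overlapping")$count
    pq <- find_polyq(orfs[[id]])
    tibble(
      id = id,
      length_aa = nchar(p),
      n_cysteines = cys$total,
      canonical_cysteine_skeleton = cys$canonical,
      mw_da = round(ph$mw),
      pi = round(ph$pi, 2),
      glutamine_pct = round(ph$glutamine_pct, 1),
      proline_pct = round(ph$proline_pct, 1),
      essential_aa_pct = round(ph$essential_pct, 1),
      heptapeptide_repeats = rep_cnt,
      polyq_codons = pq$length,
      readthrough_product = ann$status[ann$id == id] != "full_length"
    )
  }) |> bind_rows()

  # -- stage 3: epitopes ------------------------------------------------------
  hits <- scan_epitopes(prods, db)
  counts <- epitope_count_matrix(prods, db)
  maps <- purrr::map(names(prods), function(id) {
    p <- prods[[id]]
    seg <- segment_domains(p, signal_length = signal_length)
    s <- epitope_summary(hits[hits$protein_id == id, ], seg, p)
    mutate(s$map,
           clustering_fraction = round(s$clustering_fraction, 3),
           bcell_7mer_count = s$bcell_7mer_count)
  }) |> bind_rows()

  # -- stage 4: identity + tree ----------------------------------------------
  im <- NULL; tree <- NULL
  if (length(prods) >= 2L) {
    im <- identity_matrix(orfs, prods)
    tree <- nj_tree(identity_to_dist(im))
  } else {
    inform("fewer than two proteins: identity matrix and tree skipped")
  }

  # -- write ------------------------------------------------------------------
  out_file <- function(nm) file.path(output_dir, nm)
  files <- character(0)
  ann_flat <- ann |>
    mutate(note = .data$note) |>
    select("id", "seqid", "start", "end", "strand", "length_bp",
           "family_class", "status", "note")
  write_tsv_report(ann_flat, out_file("annotation.tsv"))
  write_annotation_gff3(ann, out_file("annotation.gff3"))
  write_tsv_report(feats, out_file("protein_features.tsv"))
  write_tsv_report(counts, out_file("epitope_counts.tsv"))
  write_tsv_report(maps, out_file("epitope_map.tsv"))
  files <- c("annotation.tsv", "annotation.gff3", "protein_features.tsv",
             "epitope_counts.tsv", "epitope_map.tsv")
  if (!is.null(im)) {
    write_identity_tsv(im, out_file("identity_matrix.tsv"))
    write_newick(tree, out_file("tree.nwk"))
    files <- c(files, "identity_matrix.tsv", "tree.nwk")
  }
  manifest <- list(
    tool = "gliadinr",
    version = as.character(utils::packageVersion("gliadinr")),
    settings = list(min_len = min_len, strands = strands,
                    expected_len_range = expected_len_range,
                    signal_length = signal_length,
                    readthrough = readthrough,
                    epitope_db = epitope_db %||% "bundled"),
    seed = seed,
    n_sequences = length(seqs),
    n_genes = nrow(ann),
    files = as.list(c(files, "manifest.json"))
  )
  jsonlite::write_json(manifest, out_file("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(
    list(annotation = ann, features = feats, epitope_counts = counts,
         epitope_map = maps, identity = im, tree = tree,
         files = file.path(output_dir, c(files, "manifest.json"))),
    class = "gliadin_report"
  ))
}

#' @export
print.gliadin_report <- function(x, ...) {
  cat("<gliadin_report> ", nrow(x$annotation), " gene(s): ",
      sum(x$annotation$status == "full_length"), " full-length, ",
      sum(x$annotation$status == "pseudogene"), " pseudogene(s)\n", sep = "")
  cat("  reports: ", paste(basename(x$files), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Locate (or try to fetch) the Gli-gamma1a reference ORF
#'
#' The one deposited member of the family (GenBank MZ399711) is not
#' redistributed with the package.  This helper returns the path to a local
#' copy if the user has placed one at
#' `inst/extdata/MZ399711.fasta` (or passes `path`), and otherwise attempts a
#' one-time download from NCBI efetch into `tempdir()`; it errors with
#' instructions when the record is unavailable (e.g. offline).
#'
#' @param path Optional path to an existing FASTA copy of the record.
#' @return Path to a FASTA file containing the ORF.
#' @export
reference_orf_path <- function(path = NULL) {
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("no FASTA at ", path))
    return(path)
  }
  bundled <- system.file("extdata", "MZ399711.fasta", package = "gliadinr")
  if (nzchar(bundled) && file.exists(bundled)) return(bundled)
  dest <- file.path(tempdir(), "MZ399711.fasta")
  if (file.exists(dest)) return(dest)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=MZ399711&rettype=fasta&retmode=text")
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE)
    file.exists(dest) && file.size(dest) > 100
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    if (file.exists(dest)) unlink(dest)
    abort(paste0(
      "GenBank record MZ399711 is not available locally and could not be ",
      "downloaded. Fetch it on a machine with network access and place it ",
      "at inst/extdata/MZ399711.fasta or pass `path`."
    ))
  }
  dest
}
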