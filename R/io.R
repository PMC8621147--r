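# FASTA / GFF3 / TSV input and output.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param type `"nt"` or `"aa"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- if (type == "nt") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  if (!length(set)) abort(paste0("empty FASTA: ", path))
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

# features: tibble with seqid, type, start, end, strand, attributes
# (named-list column or preformatted strings); 1-based inclusive.
write_gff3 <- function(features, path, source = "gliadinr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    attrs <- f$attributes[[1]]
    attr_str <- if (is.character(attrs) && length(attrs) == 1L && is.null(names(attrs))) {
      attrs
    } else {
      paste(paste0(names(attrs), "=", gff3_escape(unlist(attrs))), collapse = ";")
    }
    writeLines(paste(f$seqid, source, f$type, f$start, f$end, ".",
                     f$strand %||% ".", ".", attr_str, sep = "\t"), con)
  }
  invisible(path)
}

#' Write the ground truth of a synthetic gene or locus as GFF3
#'
#' Gene, signal peptide, domain, epitope and premature-stop features with
#' 1-based inclusive coordinates.  For a single gene the coordinate system is
#' the protein (domains, epitopes) alongside gene-level nucleotide features;
#' for a locus, gene intervals are genomic.
#'
#' @param x A `synthetic_gene` or `synthetic_locus`.
#' @param path Output GFF3 file.
#' @param json_path Optional path for a JSON sidecar of the generating spec.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(x, path, json_path = NULL) {
  if (inherits(x, "synthetic_locus")) {
    feats <- x$truth |>
      mutate(seqid = "locus", type = "gene",
             attributes = purrr::map2(.data$id, .data$status,
                                      ~list(ID = .x, status = .y))) |>
      select("seqid", "type", "start", "end", "strand", "attributes")
    write_gff3(feats, path)
    if (!is.null(json_path)) {
      specs <- purrr::map(x$genes, ~unclass(.x$spec))
      names(specs) <- vapply(x$genes, `[[`, character(1), "id")
      jsonlite::write_json(specs, json_path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
    return(invisible(path))
  }
  stopifnot(inherits(x, "synthetic_gene"))
  rows <- list(tibble(seqid = x$id, type = "gene", start = 1L,
                      end = nchar(x$dna), strand = "+",
                      attributes = list(list(ID = x$id, coordinates = "nucleotide"))))
  doms <- x$domains[!is.na(x$domains$start), ]
  for (k in seq_len(nrow(doms))) {
    type <- if (doms$domain[k] == "S") "signal_peptide"
            else paste0("domain_", doms$domain[k])
    rows[[length(rows) + 1L]] <- tibble(
      seqid = x$id, type = type, start = doms$start[k], end = doms$end[k],
      strand = "+", attributes = list(list(coordinates = "protein")))
  }
  for (k in seq_len(nrow(x$epitopes))) {
    rows[[length(rows) + 1L]] <- tibble(
      seqid = x$id, type = "epitope", start = x$epitopes$start[k],
      end = x$epitopes$start[k] + 8L, strand = "+",
      attributes = list(list(Name = x$epitopes$name[k], coordinates = "protein")))
  }
  if (!is.null(x$pseudogene_stop)) {
    ps <- x$pseudogene_stop
    rows[[length(rows) + 1L]] <- tibble(
      seqid = x$id, type = "premature_stop", start = ps$bp, end = ps$bp + 2L,
      strand = "+",
      attributes = list(list(stop_codon = ps$stop_codon,
                             ancestral_codon = ps$ancestral_codon,
                             coordinates = "nucleotide")))
  }
  write_gff3(bind_rows(rows), path)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(x$spec), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Write an annotation table as GFF3
#'
#' One gene feature per annotated ORF with `status` and Table-style `Note`
#' attributes (e.g. "TAG at bp 115").
#'
#' @param annotation An [annotate_genes()] tibble.
#' @param path Output file.
#' @param seqid Sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path, seqid = "genomic") {
  feats <- annotation |>
    mutate(seqid = seqid, type = "gene",
           attributes = purrr::pmap(
             list(.data$id, .data$status, .data$note),
             function(id, status, note) {
               a <- list(ID = id, status = status)
               if (nzchar(note)) a$Note <- note
               a
             })) |>
    select("seqid", "type", "start", "end", "strand", "attributes")
  write_gff3(feats, path)
}

# fixed-precision TSV with a tool-version header comment
write_tsv_report <- function(df, path, comment = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (comment) {
    writeLines(paste0("# gliadinr ",
                      as.character(utils::packageVersion("gliadinr"))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write an identity matrix in the dual-triangle table layout
#'
#' Nucleotide identities above the diagonal, amino-acid identities below,
#' 100 on the diagonal, one decimal place.
#'
#' @param im An [identity_matrix()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(im, path) {
  m <- round(im$combined, 1)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write_tsv_report(df, path)
}
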