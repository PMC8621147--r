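# Pairwise global alignment, percent-identity matrices and neighbor-joining
# phylogeny.

detect_alphabet <- function(x) {
  if (is_nt_string(x)) "nt" else "aa"
}

default_align_params <- function(type) {
  if (type == "nt") {
    list(match = 1, mismatch = -1, gap_open = 5, gap_extend = 1,
         substitution = NULL)
  } else {
    list(match = NA, mismatch = NA, gap_open = 10, gap_extend = 1,
         substitution = "BLOSUM62")
  }
}

#' Optimal global (Needleman-Wunsch) pairwise alignment
#'
#' Affine-gap global alignment via [Biostrings::pairwiseAlignment()].
#' Nucleotide pairs default to match +1 / mismatch -1 with gap open 5 and
#' gap extend 1 (penalties); amino-acid pairs default to BLOSUM62 with gap
#' open 10 / extend 1.  A linear gap cost is obtained with `gap_open = 0`.
#' Mixed alphabets (one nucleotide, one amino-acid sequence) are rejected.
#'
#' @param a,b Sequences (non-empty, same alphabet).
#' @param type `"auto"` (detect), `"nt"` or `"aa"`.
#' @param match,mismatch Nucleotide scores (ignored when a substitution
#'   matrix is used).
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param substitution Name of a Biostrings substitution matrix (e.g.
#'   "BLOSUM62") or a matrix; `NULL` for match/mismatch scoring.
#' @return List of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal length, gap symbol `-`), `score`, `params`.
#' @export
global_align <- function(a, b, type = c("auto", "nt", "aa"),
                         match = NULL, mismatch = NULL,
                         gap_open = NULL, gap_extend = NULL,
                         substitution = NULL) {
  type <- match.arg(type)
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  ta <- detect_alphabet(a); tb <- detect_alphabet(b)
  if (type == "auto") {
    if (ta != tb) {
      abort("mixed alphabets: one sequence looks nucleotide, the other amino acid")
    }
    type <- ta
  }
  par <- default_align_params(type)
  par$match <- match %||% par$match
  par$mismatch <- mismatch %||% par$mismatch
  par$gap_open <- gap_open %||% par$gap_open
  par$gap_extend <- gap_extend %||% par$gap_extend
  if (!is.null(substitution)) par$substitution <- substitution

  if (type == "nt") {
    xs <- Biostrings::DNAString(a); ys <- Biostrings::DNAString(b)
    submat <- if (is.null(par$substitution)) {
      Biostrings::nucleotideSubstitutionMatrix(match = par$match,
                                               mismatch = par$mismatch,
                                               baseOnly = FALSE)
    } else par$substitution
  } else {
    xs <- Biostrings::AAString(a); ys <- Biostrings::AAString(b)
    submat <- par$substitution
    if (is.character(submat)) {
      submat <- get(data(list = submat, package = "Biostrings",
                         envir = environment()))
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    xs, ys, type = "global", substitutionMatrix = submat,
    gapOpening = par$gap_open, gapExtension = par$gap_extend
  )
  out <- list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln),
    params = par[c("match", "mismatch", "gap_open", "gap_extend")],
    type = type
  )
  stopifnot(nchar(out$aligned_a) == nchar(out$aligned_b))
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", x$score, " (", x$type, ", ",
      nchar(x$aligned_a), " columns)\n", sep = "")
  w <- min(60L, nchar(x$aligned_a))
  cat("  ", substr(x$aligned_a, 1, w), if (nchar(x$aligned_a) > w) "...", "\n",
      "  ", substr(x$aligned_b, 1, w), if (nchar(x$aligned_b) > w) "...", "\n",
      sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' `columns` (default): identical columns over all alignment columns,
#' including gapped ones.  `ungapped`: identical columns over columns where
#' neither sequence has a gap.  For any alignment containing gaps the
#' `columns` value is the smaller of the two.
#'
#' @param aln A [global_align()] result.
#' @param convention `"columns"` or `"ungapped"`.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(aln, convention = c("columns", "ungapped")) {
  convention <- match.arg(convention)
  ca <- split_chars(aln$aligned_a)
  cb <- split_chars(aln$aligned_b)
  no_gap <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & no_gap)
  denom <- if (convention == "columns") length(ca) else sum(no_gap)
  if (denom == 0L) return(0)
  100 * ident / denom
}

#' Dual-metric pairwise identity matrix
#'
#' Aligns all sequence pairs with [global_align()] and assembles the layout
#' used for prolamin family comparisons: nucleotide identities above the
#' diagonal, amino-acid identities below, 100 on the diagonal.
#'
#' @param nt_seqs,aa_seqs Named character vectors with identical label sets
#'   (coding sequences and their deduced proteins).
#' @param convention Identity convention, see [percent_identity()].
#' @param ... Passed to [global_align()].
#' @return Object of class `identity_matrix`: `labels`, `nt` and `aa` (full
#'   symmetric matrices) and `combined` (upper triangle NT, lower AA).
#' @export
identity_matrix <- function(nt_seqs, aa_seqs, convention = "columns", ...) {
  if (is.null(names(nt_seqs)) || is.null(names(aa_seqs))) {
    abort("nt_seqs and aa_seqs must be named")
  }
  if (!setequal(names(nt_seqs), names(aa_seqs))) {
    abort("nt_seqs and aa_seqs must share the same label set")
  }
  labels <- names(nt_seqs)
  aa_seqs <- aa_seqs[labels]
  n <- length(labels)
  nt <- aa <- matrix(100, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        # canonical argument order (lexicographic by label) so that the
        # alignment chosen among score ties, and hence the identity, does
        # not depend on input order
        o <- if (labels[i] <= labels[j]) c(i, j) else c(j, i)
        nt_aln <- global_align(nt_seqs[[o[1]]], nt_seqs[[o[2]]],
                               type = "nt", ...)
        aa_aln <- global_align(aa_seqs[[o[1]]], aa_seqs[[o[2]]],
                               type = "aa", ...)
        nt[i, j] <- nt[j, i] <- percent_identity(nt_aln, convention)
        aa[i, j] <- aa[j, i] <- percent_identity(aa_aln, convention)
      }
    }
  }
  combined <- nt
  combined[lower.tri(combined)] <- aa[lower.tri(aa)]
  diag(combined) <- 100
  structure(list(labels = labels, nt = nt, aa = aa, combined = combined,
                 convention = convention),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("<identity_matrix> ", length(x$labels),
      " sequence(s); upper triangle NT %, lower AA % (convention: ",
      x$convention, ")\n", sep = "")
  print(round(x$combined, 1))
  invisible(x)
}

#' Distance matrix from an identity matrix
#'
#' The tree distance used downstream: `d = 100 - amino-acid percent
#' identity` (a p-distance-like measure; no multiple-hit correction).
#'
#' @param im An [identity_matrix()].
#' @param metric `"aa"` (default) or `"nt"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
identity_to_dist <- function(im, metric = c("aa", "nt")) {
  metric <- match.arg(metric)
  d <- 100 - im[[metric]]
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with a warning.  For exactly two taxa the tree is the
#' single edge with the distance split equally between the pendant branches.
#'
#' @param d Symmetric distance matrix (zero diagonal, non-negative, no NaN).
#' @param labels Optional taxon labels (default: dimnames of `d`).
#' @return An [ape] `phylo` object (unrooted).
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) abort("need at least 2 taxa")
  if (any(is.nan(d)) || any(is.na(d))) abort("distance matrix contains NaN/NA")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) abort("distance matrix must have a zero diagonal")
  if (any(d < 0)) abort("distances must be non-negative")
  labels <- labels %||% rownames(d) %||% paste0("t", seq_len(n))
  dimnames(d) <- list(labels, labels)

  if (n == 2L) {
    half <- d[1, 2] / 2
    txt <- sprintf("(%s:%.10g,%s:%.10g);", labels[1], half, labels[2], half)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warn("negative neighbor-joining branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are rounded to 4 decimals.
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 4)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
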