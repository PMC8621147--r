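# Independent oracles and fixture builders used across the suite.

# brute-force sliding-window scanner (the reference the fast scanner must
# agree with)
naive_scan <- function(protein, pattern) {
  n <- nchar(protein); k <- nchar(pattern)
  if (k > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - k + 1)) {
    if (substr(protein, i, i + k - 1) == pattern) starts <- c(starts, i)
  }
  starts
}

# a randomized but always-valid gene spec
random_spec <- function(seed) {
  set.seed(seed)
  n_rep <- sample(3:7, 1)
  epis <- c("QQPQQPFPQ", "PQQSFPQQQ", "IQPQQPAQL", "QQPFPQQPQ")
  k <- sample(0:min(3, n_rep - 1), 1)
  ep <- if (k > 0) {
    picked <- sample(epis, k)
    stats::setNames(rep(1L, k), picked)
  } else integer(0)
  pq <- sample(c(0L, 8L, 15L, 25L), 1)
  ints <- if (pq >= 10 && stats::runif(1) < 0.5) {
    data.frame(offset = sample(3:(pq - 2), 1),
               codon = sample(c("CAG", "GAA", "CTA"), 1))
  } else NULL
  layout <- c(III = sample(4:6, 1), V = sample(1:2, 1))
  if (stats::runif(1) < 0.3) layout <- c(II = 1L, layout)
  gene_spec(
    n_repeats = n_rep, epitopes = ep, polyq_length = pq,
    polyq_interruptions = ints, cysteine_layout = layout,
    domain1_length = sample(15:30, 1), domain3_length = sample(60:110, 1),
    domain5_length = sample(40:70, 1), seed = seed
  )
}

# codon vector of an ORF string
codons_of <- function(dna) {
  substring(dna, seq(1, nchar(dna) - 2, 3), seq(3, nchar(dna), 3))
}

# glutamine codon indices usable by pseudogenize()
q_codons <- function(dna) which(codons_of(dna) %in% c("CAA", "CAG"))

# random unrooted tree with strictly positive branch lengths and its exact
# additive (path-length) distance matrix
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, rooted = TRUE))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 5)
  d <- as.matrix(stats::cophenetic(tr))
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# random peptide over the 20 standard residues
random_peptide <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               len, replace = TRUE), collapse = "")
}

# an ORF of exactly n_bp (including the terminal stop), no internal stops
plain_orf <- function(n_bp, codon = "GCT") {
  stopifnot(n_bp %% 3 == 0, n_bp >= 9)
  paste0("ATG", strrep(codon, n_bp / 3 - 2), "TAA")
}
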