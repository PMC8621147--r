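test_that("generation is deterministic and truth describes the sequence verbatim", {
  spec <- gene_spec(n_repeats = 4, epitopes = c(QQPQQPFPQ = 3),
                    polyq_length = 20, seed = 1)
  g1 <- build_gamma_gene(spec)
  g2 <- build_gamma_gene(spec)
  expect_identical(g1$dna, g2$dna)
  expect_identical(g1$protein, g2$protein)

  for (seed in c(1, 5, 11)) {
    g <- build_gamma_gene(gene_spec(seed = seed))
    # intronless ORF: ATG start, stop end, length divisible by 3
    expect_identical(nchar(g$dna) %% 3L, 0L)
    expect_true(startsWith(g$dna, "ATG"))
    expect_true(substr(g$dna, nchar(g$dna) - 2, nchar(g$dna)) %in%
                  c("TAA", "TAG", "TGA"))
    # translation reproduces the stated protein
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(g$dna),
                                             no.init.codon = TRUE))
    expect_identical(sub("\\*$", "", aa), g$protein)
    # planted epitope copies verified by independent substring search
    for (e in unique(g$epitopes$name)) {
      expect_identical(naive_scan(g$protein, e),
                       sort(g$epitopes$start[g$epitopes$name == e]))
    }
    # cysteines exactly at truth positions
    expect_identical(naive_scan(g$protein, "C"), g$cysteine_positions)
    # domain intervals ordered, non-overlapping, within the protein
    d <- g$domains[!is.na(g$domains$start), ]
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$end >= d$start))
    expect_true(all(utils::head(d$end, -1) < utils::tail(d$start, -1)))
    expect_lte(max(d$end), nchar(g$protein))
  }
})

test_that("default architecture lands in the family's size range", {
  g <- build_gamma_gene(gene_spec(seed = 3))
  expect_gte(nchar(g$protein), 285)
  expect_lte(nchar(g$protein), 328)
  ph <- physchem(g$protein)
  expect_gt(ph$glutamine_pct, 25)
  expect_lt(ph$glutamine_pct, 40)
})

test_that("degenerate specs produce empty repeat domains but a valid ORF", {
  g <- build_gamma_gene(gene_spec(n_repeats = 0, epitopes = integer(0),
                                  polyq_length = 0, seed = 2))
  expect_true(all(is.na(g$domains$start[g$domains$domain %in% c("II", "IV")])))
  expect_true(startsWith(g$dna, "ATG"))
  expect_true(substr(g$dna, nchar(g$dna) - 2, nchar(g$dna)) %in%
                c("TAA", "TAG", "TGA"))
})

test_that("contradictory specs are rejected with an explanation", {
  expect_error(gene_spec(n_repeats = 2, epitopes = c(QQPQQPFPQ = 5)),
               "cannot fit")
  expect_error(gene_spec(polyq_length = 3), "recoverable")
  expect_error(gene_spec(polyq_interruptions = data.frame(offset = 1,
                                                          codon = "CAG")),
               "strictly inside")
  expect_error(gene_spec(polyq_interruptions = data.frame(offset = 10,
                                                          codon = "TTT")),
               "single-base mutants")
})

test_that("pseudogenization mutates exactly one base of a glutamine codon", {
  g <- build_gamma_gene(gene_spec(seed = 4))
  qi <- q_codons(g$dna)
  expect_gt(length(qi), 0)
  i <- qi[7]
  anc <- codons_of(g$dna)[i]
  pg <- pseudogenize(g, i)
  # exactly one differing base: the first base of the codon, C -> T
  diffs <- which(strsplit(g$dna, "")[[1]] != strsplit(pg$dna, "")[[1]])
  expect_identical(diffs, 3L * (i - 1L) + 1L)
  expect_identical(pg$pseudogene_stop$bp, 3L * (i - 1L) + 1L)
  expect_identical(pg$pseudogene_stop$ancestral_codon, anc)
  expect_identical(pg$pseudogene_stop$stop_codon, sub("^C", "T", anc))
  # stop position convention: first base of the stop codon, 1 mod 3
  expect_identical(pg$pseudogene_stop$bp %% 3L, 1L)
  # readthrough protein marks the mutated residue
  expect_identical(substr(pg$protein, i, i), "*")

  # non-glutamine codon refused
  not_q <- setdiff(seq_along(codons_of(g$dna)), qi)[2]
  expect_error(pseudogenize(g, not_q), "CAA/CAG")
})

test_that("truncation drops the tail and the terminal stop", {
  g <- build_gamma_gene(gene_spec(seed = 6))
  tr <- truncate_gene(g, 465)
  expect_identical(nchar(tr$dna), 465L)
  expect_true(tr$truncated)
  expect_identical(tr$dna, substr(g$dna, 1, 465))
})

test_that("locus placement is ordered, non-overlapping and strand-aware", {
  genes <- lapply(1:3, function(i)
    build_gamma_gene(gene_spec(seed = i), id = paste0("g", i)))
  loc <- build_locus(genes, spacer_range = c(200, 400),
                     strands = c("+", "-", "+"), seed = 9)
  tr <- loc$truth
  expect_identical(nrow(tr), 3L)
  expect_true(all(diff(tr$start) > 0))
  expect_true(all(utils::head(tr$end, -1) < utils::tail(tr$start, -1)))
  expect_identical(tr$strand, c("+", "-", "+"))
  # reverse-strand gene is placed reverse-complemented
  placed <- substr(loc$sequence, tr$start[2], tr$end[2])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genes[[2]]$dna)))
  expect_identical(placed, rc)
})

test_that("spacer base composition tracks the requested GC fraction", {
  g <- build_gamma_gene(gene_spec(seed = 1), id = "g1")
  loc <- build_locus(list(g), spacer_range = c(10000, 10000), spacer_gc = 0.5,
                     seed = 3)
  spacer <- paste0(substr(loc$sequence, 1, loc$truth$start - 1),
                   substr(loc$sequence, loc$truth$end + 1,
                          nchar(loc$sequence)))
  gc <- sum(strsplit(spacer, "")[[1]] %in% c("G", "C")) / nchar(spacer)
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("truth export writes parseable GFF3 with the planted features", {
  g <- build_gamma_gene(gene_spec(seed = 8))
  gff <- tempfile(fileext = ".gff3")
  js <- tempfile(fileext = ".json")
  write_truth_gff3(g, gff, json_path = js)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  body <- read.delim(gff, header = FALSE, comment.char = "#")
  expect_true(all(c("gene", "signal_peptide", "domain_II", "epitope") %in%
                    body$V3))
  # epitope features carry 9-residue spans at the truth positions
  ep <- body[body$V3 == "epitope", ]
  expect_setequal(ep$V4, g$epitopes$start)
  expect_true(all(ep$V5 - ep$V4 == 8))
  spec_back <- jsonlite::read_json(js)
  expect_identical(spec_back$n_repeats, g$spec$n_repeats)
})
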