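test_that("a planted ORF is found at its exact interval", {
  filler <- strrep("C", 100)
  orf <- paste0("ATG", strrep("AAA", 40), "TAA")  # 126 bp
  genomic <- paste0(filler, orf, filler)
  found <- find_orfs(genomic, min_len = 120, strands = "forward")
  expect_identical(nrow(found), 1L)
  expect_identical(found$start, 101L)
  expect_identical(found$end, 226L)
  expect_identical(found$length_bp, 126L)
  expect_identical(found$sequence, orf)

  # the same ORF embedded reverse-complemented: strand "-", same sequence
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  genomic2 <- paste0(filler, rc, filler)
  found2 <- find_orfs(genomic2, min_len = 120)
  expect_identical(nrow(found2), 1L)
  expect_identical(found2$strand, "-")
  expect_identical(found2$start, 101L)
  expect_identical(found2$end, 226L)
  expect_identical(found2$sequence, orf)
})

test_that("ORF discovery recovers planted loci exactly", {
  genes <- lapply(c(21, 22, 23), function(i)
    build_gamma_gene(gene_spec(seed = i), id = paste0("g", i)))
  loc <- build_locus(genes, strands = c("+", "-", "+"), seed = 5)
  found <- find_orfs(loc$sequence)
  expect_identical(found$start, loc$truth$start)
  expect_identical(found$end, loc$truth$end)
  expect_identical(found$strand, loc$truth$strand)
  expect_identical(found$sequence,
                   vapply(loc$genes, `[[`, character(1), "dna"))
})

test_that("sequence validation flags bad characters and N-containing ORFs", {
  expect_error(find_orfs("ACGTUACGT"), "non-nucleotide")
  genomic <- paste0(strrep("C", 30), "ATG", strrep("AAA", 20), "AANAAA",
                    strrep("AAA", 20), "TAA", strrep("C", 30))
  expect_warning(found <- find_orfs(genomic, min_len = 120,
                                    strands = "forward"), "N")
  expect_identical(nrow(found), 0L)
})

test_that("classification separates full-length genes from pseudogenes", {
  full <- classify_orf(plain_orf(858), id = "fl")
  expect_identical(full$status, "full_length")
  expect_identical(nrow(full$premature_stops[[1]]), 0L)
  expect_false(full$truncated)
  expect_identical(full$note, "")

  # premature stop from the C->T mechanism at codon 39: bp 115, TAG <- CAG
  ps <- paste0("ATG", strrep("CCT", 37), "TAG", strrep("CCT", 246), "TAA")
  m <- classify_orf(ps, id = "ps")
  expect_identical(m$status, "pseudogene")
  st <- m$premature_stops[[1]]
  expect_identical(st$bp, 115L)
  expect_identical(st$stop_codon, "TAG")
  expect_identical(st$ancestral_codon, "CAG")
  expect_identical(m$note, "TAG at bp 115")

  # TAA maps back to CAA; TGA has no known ancestral glutamine codon
  m2 <- classify_orf(paste0("ATG", strrep("CCT", 53), "TAA",
                            strrep("CCT", 20), "TGA", strrep("CCT", 210),
                            "TAA"))
  st2 <- m2$premature_stops[[1]]
  expect_identical(st2$bp, c(163L, 226L))
  expect_identical(st2$ancestral_codon, c("CAA", "unknown"))

  # pseudogenized generator gene round-trips through classification
  g <- build_gamma_gene(gene_spec(seed = 31))
  i <- q_codons(g$dna)[9]
  pg <- pseudogenize(g, i)
  mg <- classify_orf(pg$dna, id = "g")
  expect_identical(mg$premature_stops[[1]]$bp, pg$pseudogene_stop$bp)
  expect_identical(mg$premature_stops[[1]]$stop_codon,
                   pg$pseudogene_stop$stop_codon)
})

test_that("a truncated ORF with an earlier stop gets both annotations", {
  seq465 <- paste0("ATG", strrep("CCT", 25), "TAG", strrep("CCT", 128))
  seq465 <- substr(seq465, 1, 465)
  m <- classify_orf(seq465, id = "trunc")
  expect_identical(m$status, "pseudogene")
  expect_true(m$truncated)
  expect_identical(m$premature_stops[[1]]$bp, 79L)
  expect_identical(m$note, "TAG at bp 79; Truncated at bp 465")
})

test_that("translation follows the standard code with readthrough control", {
  expect_identical(translate_orf("ATGAAATAA"), "MK")
  # a 966-bp intronless ORF encodes a 321-residue protein
  expect_identical(nchar(translate_orf(plain_orf(966))), 321L)
  expect_identical(nchar(translate_orf(plain_orf(858))), 285L)

  ps <- paste0("ATG", strrep("CCT", 37), "TAG", strrep("CCT", 246), "TAA")
  expect_identical(translate_orf(ps), paste0("M", strrep("P", 37)))
  rt <- translate_orf(ps, readthrough = TRUE)
  expect_identical(substr(rt, 39, 39), "*")
  expect_identical(nchar(rt), 285L)
  expect_warning(aa <- translate_orf("ATGAANTAA"), "X")
  expect_identical(aa, "MX")
})

test_that("every reported premature stop sits on the first base of a codon", {
  for (seed in 41:45) {
    g <- build_gamma_gene(gene_spec(seed = seed))
    qi <- q_codons(g$dna)
    pg <- pseudogenize(g, qi[length(qi) %/% 2])
    m <- classify_orf(pg$dna)
    expect_true(all(m$premature_stops[[1]]$bp %% 3L == 1L))
  }
})

test_that("ORF/protein length bookkeeping is checked, not silently fixed", {
  expect_silent(ok <- validate_length_consistency(c(966, 858, 909, 876),
                                                  c(321, 285, 302, 291)))
  expect_true(all(ok))
  expect_warning(
    bad <- validate_length_consistency(c(894, 996), c(296, 328),
                                       ids = c("a", "b")),
    "mismatch")
  expect_false(any(bad))
})

test_that("annotation rescues pseudogene regions spanning internal stops", {
  genes <- lapply(51:54, function(i)
    build_gamma_gene(gene_spec(seed = i), id = paste0("g", i)))
  # early premature stop: the leading ORF is far below min_len
  genes[[2]] <- pseudogenize(genes[[2]], q_codons(genes[[2]]$dna)[3])
  loc <- build_locus(genes, strands = c("+", "+", "-", "+"), seed = 10)
  ann <- annotate_genes(loc$sequence)
  expect_identical(nrow(ann), 4L)
  expect_identical(ann$start, loc$truth$start)
  expect_identical(ann$end, loc$truth$end)
  expect_identical(ann$status, loc$truth$status)
  expect_match(ann$note[ann$status == "pseudogene"],
               paste0("at bp ", genes[[2]]$pseudogene_stop$bp))
  expect_true(all(ann$family_class == "gamma_gliadin"))
})
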