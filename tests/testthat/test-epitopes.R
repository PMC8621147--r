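test_that("the bundled epitope database has the expected structure", {
  db <- load_epitope_db()
  expect_identical(nrow(db), 10L)
  shared <- db$name[db$sequence == "QQPQQPFPQ"]
  expect_setequal(shared, c("DQ2.5-glia-g4c", "DQ8-glia-g1a"))
  expect_true(all(nchar(db$sequence) == 9L))
  expect_setequal(unique(db$hla), c("DQ2.5", "DQ8", "DQ8.5"))
})

test_that("malformed database rows are rejected with their line number", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\thla\tsequence",
               "ok\tDQ2.5\tQQPQQPFPQ",
               "short\tDQ2.5\tQQPFPQQP"), bad)
  expect_error(load_epitope_db(bad), "line 3")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("name\thla\tsequence",
               "e1\tDQ2.5\tQQPQQPFPQ",
               "e1\tDQ8\tPQQSFPQQQ"), dup)
  expect_error(load_epitope_db(dup), "duplicate")

  expect_error(load_epitope_db("/no/such/file.tsv"), "not found")
})

test_that("a user-supplied database of arbitrary size loads verbatim", {
  set.seed(31)
  seqs <- unique(replicate(50, paste(
    sample(c("Q", "P", "F", "L", "S", "Y", "I", "E"), 9, replace = TRUE),
    collapse = "")))[1:31]
  f <- tempfile(fileext = ".tsv")
  writeLines(c("name\thla\tsequence",
               paste(paste0("epi", 1:31), "DQ2.5", seqs, sep = "\t")), f)
  db <- load_epitope_db(f)
  expect_identical(nrow(db), 31L)
  expect_identical(db$sequence, seqs)
})

test_that("exact-match scanning reports every overlapping start position", {
  db1 <- tibble::tibble(name = "e", hla = "DQ2.5", sequence = "QQPQQPFPQ",
                        deamidation_mask = NA)
  hits <- scan_epitopes(c(p = "QQPQQPFPQQPQQPFPQ"), db1)
  expect_identical(hits$start, c(1L, 9L))

  # epitope equal to the whole protein
  hits2 <- scan_epitopes(c(p = "QQPQQPFPQ"), db1)
  expect_identical(hits2$start, 1L)

  # non-overlapping mode collapses overlapping copies
  hits3 <- scan_epitopes(c(p = "QQPQQPFPQQPQQPFPQ"), db1,
                         mode = "non_overlapping")
  expect_identical(hits3$start, 1L)
})

test_that("the scanner agrees with the naive sliding-window oracle", {
  set.seed(99)
  alpha <- c("Q", "P", "F", "S", "L")
  for (k in 1:150) {
    prot <- paste(sample(alpha, sample(20:60, 1), replace = TRUE),
                  collapse = "")
    epi <- paste(sample(alpha, 9, replace = TRUE), collapse = "")
    db <- tibble::tibble(name = "e", hla = "DQ2.5", sequence = epi,
                         deamidation_mask = NA)
    hits <- scan_epitopes(c(p = prot), db)
    expect_identical(hits$start, naive_scan(prot, epi))
  }
})

test_that("epitopes sharing a sequence report identical hits, independent of row order", {
  g <- build_gamma_gene(gene_spec(seed = 81))
  db <- load_epitope_db()
  hits <- scan_epitopes(c(p = g$protein), db)
  a <- hits[hits$epitope == "DQ2.5-glia-g4c", c("start")]
  b <- hits[hits$epitope == "DQ8-glia-g1a", c("start")]
  expect_identical(a$start, b$start)

  db_rev <- db[rev(seq_len(nrow(db))), ]
  hits_rev <- scan_epitopes(c(p = g$protein), db_rev)
  expect_identical(hits, hits_rev)
})

test_that("planted epitope copies are recovered with exact counts and positions", {
  sp <- gene_spec(n_repeats = 6,
                  epitopes = c(QQPQQPFPQ = 2, IQPQQPAQL = 1, PQQSFPQQQ = 1),
                  seed = 82)
  g <- build_gamma_gene(sp)
  db <- load_epitope_db()
  hits <- scan_epitopes(c(p = g$protein), db)
  for (e in names(sp$epitopes)) {
    got <- hits[hits$sequence == e, ]
    truth <- g$epitopes[g$epitopes$name == e, ]
    # each database entry with this sequence reports the same full hit set
    for (nm in unique(got$epitope)) {
      expect_identical(got$start[got$epitope == nm], sort(truth$start))
    }
  }
})

test_that("summaries compute clustering, the B-cell 7-mer and a positional map", {
  g <- build_gamma_gene(gene_spec(seed = 83))
  seg <- segment_domains(g$protein, orf = g$dna)
  hits <- scan_epitopes(c(p = g$protein))
  hits$protein_id <- "p"
  s <- epitope_summary(hits, seg, g$protein)
  # every planted hit sits in domain II, so clustering is 1
  planted <- hits[hits$sequence %in% g$epitopes$name, ]
  ii <- seg[seg$domain == "II", ]
  expect_true(all(planted$start >= ii$start & planted$start <= ii$end))
  expect_equal(s$clustering_fraction, 1.0)
  expect_false(s$no_hits)
  # tandem canonical units necessarily carry the B-cell 7-mer
  expect_gte(s$bcell_7mer_count, g$spec$n_repeats - 1L)
  expect_identical(nrow(s$map), s$total_hits)
  expect_true(all(s$map$end - s$map$start == 8L))

  # degenerate: no hits at all
  empty_hits <- hits[0, ]
  s0 <- epitope_summary(empty_hits, seg, g$protein)
  expect_identical(s0$total_hits, 0L)
  expect_true(s0$no_hits)
  expect_identical(s0$clustering_fraction, 0)

  # a hit outside the protein is rejected
  bad <- hits[1, ]
  bad$start <- nchar(g$protein)
  expect_error(epitope_summary(bad, seg, g$protein), "outside")
})

test_that("the count matrix is zero-filled and shaped epitopes x proteins", {
  genes <- lapply(84:85, function(i)
    build_gamma_gene(gene_spec(seed = i), id = paste0("g", i)))
  prots <- setNames(vapply(genes, `[[`, character(1), "protein"),
                    c("gA", "gB"))
  m <- epitope_count_matrix(prots)
  expect_identical(nrow(m), 10L)
  expect_true(all(c("gA", "gB") %in% names(m)))
  # duplicated-sequence rows are identical columns
  m4c <- m[m$epitope == "DQ2.5-glia-g4c", c("gA", "gB")]
  m1a <- m[m$epitope == "DQ8-glia-g1a", c("gA", "gB")]
  expect_identical(unlist(m4c), unlist(m1a), ignore_attr = TRUE)
  # planted copies appear with their exact counts
  expect_identical(m$gA[m$epitope == "DQ2.5-glia-g4c"],
                   nrow(genes[[1]]$epitopes))
})
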