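test_that("segmentation recovers generator domain boundaries exactly", {
  for (seed in c(61, 62, 63, 64)) {
    g <- build_gamma_gene(gene_spec(seed = seed))
    seg <- segment_domains(g$protein, orf = g$dna)
    expect_identical(as.data.frame(seg)[, c("domain", "start", "end")],
                     as.data.frame(g$domains)[, c("domain", "start", "end")],
                     info = paste("seed", seed))
  }
})

test_that("missing repeat domains merge the unresolvable boundaries", {
  g <- build_gamma_gene(gene_spec(polyq_length = 0, seed = 65))
  seg <- segment_domains(g$protein, orf = g$dna)
  expect_true(is.na(seg$start[seg$domain == "IV"]))
  expect_true(is.na(seg$start[seg$domain == "V"]))
  expect_identical(seg$end[seg$domain == "III"], nchar(g$protein))
  expect_identical(as.data.frame(seg)[, 1:3], as.data.frame(g$domains)[, 1:3])

  g2 <- build_gamma_gene(gene_spec(n_repeats = 0, epitopes = integer(0),
                                   seed = 66))
  seg2 <- segment_domains(g2$protein, orf = g2$dna)
  expect_true(is.na(seg2$start[seg2$domain == "II"]))
  expect_identical(as.data.frame(seg2)[, 1:3], as.data.frame(g2$domains)[, 1:3])

  expect_warning(seg3 <- segment_domains(strrep("MAVLT", 20)),
                 "non-gliadin-like")
  expect_true(all(is.na(seg3$start[seg3$domain %in% c("II", "III", "IV", "V")])))
})

test_that("repeat motif counting matches a brute-force oracle in both modes", {
  expect_identical(count_repeat_motif(strrep("PQQPFPQ", 3))$count, 3L)
  expect_identical(count_repeat_motif(strrep("PQQPFPQ", 3),
                                      mode = "non_overlapping")$count, 3L)
  ov <- count_repeat_motif("PQQPFPQQPFPQ")
  expect_identical(ov$starts, c(1L, 6L))
  expect_identical(count_repeat_motif("PQQPFPQQPFPQ",
                                      mode = "non_overlapping")$count, 1L)
  expect_identical(count_repeat_motif("AAAA")$count, 0L)

  set.seed(77)
  for (k in 1:40) {
    p <- paste(sample(c("P", "Q", "F"), 60, replace = TRUE), collapse = "")
    motif <- paste(sample(c("P", "Q", "F"), 3, replace = TRUE), collapse = "")
    expect_identical(count_repeat_motif(p, motif)$starts,
                     naive_scan(p, motif))
    # overlapping count always >= non-overlapping
    expect_gte(count_repeat_motif(p, motif)$count,
               count_repeat_motif(p, motif, mode = "non_overlapping")$count)
  }
  # equality when the motif cannot overlap itself
  expect_identical(count_repeat_motif(strrep("QAB", 5), "QAB")$count,
                   count_repeat_motif(strrep("QAB", 5), "QAB",
                                      mode = "non_overlapping")$count)
})

test_that("poly-Q detection applies the CAA-mutant run rules", {
  t1 <- find_polyq(strrep("CAA", 10))
  expect_identical(t1$length, 10L)
  expect_identical(t1$caa_count, 10L)
  expect_identical(nrow(t1$interruptions), 0L)

  t2 <- find_polyq(paste0(strrep("CAA", 4), "CAG", strrep("CAA", 4)))
  expect_identical(t2$length, 9L)
  expect_identical(t2$interruptions$codon, "CAG")
  expect_identical(t2$interruptions$offset, 5L)

  # TTT differs from CAA at all three bases: it splits the run
  t3 <- find_polyq(paste0(strrep("CAA", 3), "TTT", strrep("CAA", 3)))
  expect_identical(t3$length, 0L)

  # two consecutive interruptions break a run
  t4 <- find_polyq(paste0(strrep("CAA", 5), "CAGCAG", strrep("CAA", 5)))
  expect_identical(t4$length, 6L)

  # generator tracts round-trip, including interruption offsets
  sp <- gene_spec(polyq_length = 18,
                  polyq_interruptions = data.frame(offset = c(5, 11),
                                                   codon = c("GAA", "CTA")),
                  seed = 71)
  g <- build_gamma_gene(sp)
  pq <- find_polyq(g$dna)
  expect_identical(pq$length, 18L)
  expect_identical(pq$interruptions$offset, c(5L, 11L))
  expect_identical(pq$interruptions$codon, c("GAA", "CTA"))
  expect_identical(pq$interruptions$residue, c("E", "L"))
  iv <- g$domains[g$domains$domain == "IV", ]
  expect_identical(pq$start_codon, iv$start)
  expect_identical(pq$end_codon, iv$end)
})

test_that("cysteine profiling recognizes the conserved skeleton", {
  g <- build_gamma_gene(gene_spec(seed = 72))
  seg <- segment_domains(g$protein, orf = g$dna)
  cp <- cysteine_profile(g$protein, seg)
  expect_identical(cp$total, 8L)
  expect_true(cp$canonical)
  expect_identical(cp$positions, g$cysteine_positions)
  counts <- setNames(cp$per_domain$n, cp$per_domain$domain)
  expect_identical(counts[["III"]], 6L)
  expect_identical(counts[["V"]], 2L)
  expect_identical(length(cp$extra_positions), 0L)

  # an extra cysteine in domain II breaks the canonical flag
  g9 <- build_gamma_gene(gene_spec(cysteine_layout = c(II = 1, III = 6, V = 2),
                                   seed = 73))
  seg9 <- segment_domains(g9$protein, orf = g9$dna)
  cp9 <- cysteine_profile(g9$protein, seg9)
  expect_identical(cp9$total, 9L)
  expect_false(cp9$canonical)
  ii <- seg9[seg9$domain == "II", ]
  expect_true(all(cp9$extra_positions >= ii$start &
                    cp9$extra_positions <= ii$end))

  # cysteine-free protein
  p0 <- strrep("PQQPFPQ", 5)
  seg0 <- segment_domains(p0, signal_length = 0)
  cp0 <- cysteine_profile(p0, seg0)
  expect_identical(cp0$total, 0L)
  expect_false(cp0$canonical)
})

test_that("molecular weight and composition follow the reference tables", {
  expect_equal(physchem("GG")$mw, 132.12, tolerance = 1e-4)
  ph <- physchem("QQP")
  expect_equal(ph$glutamine_pct, 66.7, tolerance = 0.05)
  expect_equal(ph$proline_pct, 33.3, tolerance = 0.05)
  expect_error(physchem(""), "empty")
  expect_warning(ph2 <- physchem("MK*QL"), "not defined")
  expect_true(is.na(ph2$mw) && is.na(ph2$pi))
  expect_equal(sum(ph2$composition$pct), 100, tolerance = 0.05)
})

test_that("MW is additive and pI responds monotonically to charged residues", {
  set.seed(88)
  w <- physchem("W")$mw
  for (k in 1:50) {
    a <- random_peptide(sample(3:30, 1))
    b <- random_peptide(sample(3:30, 1))
    joint <- physchem(paste0(a, b))$mw
    expect_equal(joint, physchem(a)$mw + physchem(b)$mw - 18.01524,
                 tolerance = 1e-6)
    # composition sums to 100
    expect_equal(sum(physchem(a)$composition$pct), 100, tolerance = 0.05)
    # lysine never lowers pI; aspartate never raises it
    base_pi <- physchem(a)$pi
    expect_gte(physchem(paste0(a, "K"))$pi, base_pi - 0.002)
    expect_lte(physchem(paste0(a, "D"))$pi, base_pi + 0.002)
  }
})
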