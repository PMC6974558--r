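test_that("IUPAC consensus encoding and expansion are mutual inverses", {
  expect_identical(encode_heterozygous_consensus("AAT", "AAT"), "AAT")
  expect_identical(encode_heterozygous_consensus("AAT", "ATT"), "AWT")
  ## per-position two-fold code lookup
  expect_identical(encode_heterozygous_consensus("ACGT", "TGCA"), "WSSW")
  expect_identical(encode_heterozygous_consensus("ANT", "AAT"), "ANT")
  expect_error(encode_heterozygous_consensus("AA", "AAT"), "length")

  aln <- marker_alignment(c("x", "y"), c("AWA", "CCC"), locus = "demo")
  ex <- expand_biallelic(aln)
  expect_identical(ex$seq[1:2], c("AAA", "ATA"))
  expect_identical(ex$seq[3:4], c("CCC", "CCC"))

  ## round trip on random simulated consensus panels
  rnd <- random_iupac_alignment(6, 80, het_prob = 0.2, seed = 3)
  ex2 <- expand_biallelic(rnd)
  back <- encode_heterozygous_consensus(ex2$seq[c(TRUE, FALSE)],
                                        ex2$seq[c(FALSE, TRUE)])
  expect_identical(back, rnd$seq)

  expect_error(
    expand_biallelic(marker_alignment("x", "ABT")),
    "unsupported"
  )
})

test_that("site counts follow the heterozygous/polymorphic definitions", {
  a <- marker_alignment(c("s1", "s2", "s3"), c("AAAA", "AAAT", "AATA"))
  sc <- site_counts(a)
  expect_identical(sc$n_total_sites, 4L)
  expect_identical(sc$n_heterozygous_sites, 0L)
  expect_identical(sc$n_polymorphic_sites, 2L)
  expect_identical(sc$pct_polymorphic, 50)

  ## an ambiguity contributes both constituent alleles
  b <- site_counts(marker_alignment(c("s1", "s2"), c("AAWA", "AAAA")))
  expect_identical(b$n_heterozygous_sites, 1L)
  expect_identical(b$n_polymorphic_sites, 1L)

  ## gap/N columns are excluded from every count
  g <- site_counts(marker_alignment(c("s1", "s2"), c("A-TA", "ATTN")))
  expect_identical(g$n_total_sites, 2L)

  ## het <= poly <= total on random alignments
  for (seed in 1:5) {
    sc <- site_counts(random_iupac_alignment(5, 60, 0.15, seed = seed))
    expect_lte(sc$n_heterozygous_sites, sc$n_polymorphic_sites)
    expect_lte(sc$n_polymorphic_sites, sc$n_total_sites)
  }

  expect_error(site_counts(marker_alignment("s1", "AAAA")), "2 sequences")
})

test_that("nucleotide diversity equals the brute-force all-pairs oracle", {
  ident <- marker_alignment(c("a", "b", "c"), c("ACGT", "ACGT", "ACGT"))
  expect_identical(nucleotide_diversity(ident)$Pi, 0)

  ## three homozygous strains: enumerate the 15 pairs of 6 haplotypes
  tri <- marker_alignment(c("a", "b", "c"), c("AAAA", "AAAT", "AATT"))
  haps <- expand_biallelic(tri)$seq
  expect_identical(nucleotide_diversity(tri)$Pi, brute_force_pi(haps))

  ## oracle equivalence on random heterozygous alignments
  for (seed in 1:4) {
    aln <- random_iupac_alignment(sample(3:8, 1), 50, 0.2, seed = seed)
    nd <- nucleotide_diversity(aln)
    expect_equal(nd$Pi, brute_force_pi(expand_biallelic(aln)$seq))
    ## per-kb rescaling consistency
    expect_equal(nd$pi_per_kb, 1000 * nd$Pi / nd$n_total_sites)
  }

  expect_error(nucleotide_diversity(marker_alignment("a", "ACGT")), "one strain")
})

test_that("marker concatenation keeps shared strains and adds counts", {
  a1 <- marker_alignment(c("x", "y", "z"), c("AAAA", "AATA", "AAAA"),
                         locus = "l1")
  a2 <- marker_alignment(c("x", "y"), c("CCCC", "CCCG"), locus = "l2")
  expect_warning(cc <- concatenate_markers(list(a1, a2)), "z")
  expect_identical(nchar(cc$seq[1]), 8L)
  expect_identical(cc$strain, c("x", "y"))

  ## additivity of site counts when nothing is filtered
  sub1 <- marker_alignment(c("x", "y"), c("AAAA", "AATA"), locus = "l1")
  cc_counts <- site_counts(cc)
  expect_identical(cc_counts$n_polymorphic_sites,
                   site_counts(sub1)$n_polymorphic_sites +
                     site_counts(a2)$n_polymorphic_sites)

  expect_error(concatenate_markers(list(
    marker_alignment("x", "AAAA"), marker_alignment("q", "AAAA")
  )), "shared")
})

test_that("alignments survive a FASTA round trip", {
  aln <- random_iupac_alignment(4, 30, 0.2, seed = 9)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_marker_alignment(aln, path)
  back <- read_marker_alignment(path, locus = "rand")
  expect_identical(back$seq, aln$seq)
  expect_identical(back$strain, aln$strain)
})
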