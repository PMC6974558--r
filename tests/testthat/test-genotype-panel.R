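make_panel <- function(a1, a2, locus = "L1") {
  genotype_panel(tibble::tibble(
    individual = sprintf("i%02d", seq_along(a1)),
    locus = locus, allele_1 = a1, allele_2 = a2
  ))
}

test_that("Weir-Cockerham Fis matches the closed-form boundary cases", {
  ## all homozygous, two allele classes at 50/50: Ho = 0 so f = 1
  hom <- make_panel(rep(c("A", "T"), 5), rep(c("A", "T"), 5))
  expect_equal(fis_estimate(hom), 1)

  ## every individual heterozygous A/T: the component algebra gives -1
  het <- make_panel(rep("A", 10), rep("T", 10))
  expect_equal(fis_estimate(het), -1)

  expect_error(fis_estimate(make_panel(rep("A", 6), rep("A", 6))),
               "monomorphic")

  ## equilibrium recovery: E[Fis] = s/(2-s) under partial selfing
  panel <- simulate_mlst_population(500, 5, h0 = 0.5, s = 0.8, seed = 11)
  expect_lt(abs(fis_estimate(panel) - 0.8 / 1.2), 0.05)

  ## the naive estimator agrees with W&C to first order on large panels
  expect_lt(abs(fis_estimate(panel) - fis_estimate(panel, "ho_he")), 0.02)
})

test_that("Fis transforms to selfing with clamping and table rounding", {
  expect_identical(selfing_from_fis(0.4372), 0.61)
  expect_identical(selfing_from_fis(0.974), 0.99)
  expect_identical(selfing_from_fis(0.116), 0.21)
  expect_identical(selfing_from_fis(0.5825), 0.74)
  expect_identical(selfing_from_fis(0), 0)
  expect_identical(selfing_from_fis(1), 1)
  expect_warning(s <- selfing_from_fis(-0.2), "negative")
  expect_identical(s, 0)
  expect_error(selfing_from_fis(-1), "undefined")
})

test_that("STRUCTURE export encodes digits 0-3 and round-trips", {
  panel <- genotype_panel(tibble::tibble(
    individual = c("i1", "i1", "i2", "i2"),
    locus = rep(c("L1", "L2"), 2),
    allele_1 = c("A", "A", "A", NA),
    allele_2 = c("A", "T", "C", NA)
  ))
  path <- withr::local_tempfile(fileext = ".str")
  export_structure(panel, path)
  lines <- readLines(path)
  expect_identical(lines[1], "L1\tL2")
  expect_identical(lines[2], "i1\t0\t0")   # homozygote A/A
  expect_identical(lines[3], "i1\t0\t3")   # heterozygote A/T
  expect_identical(lines[5], "i2\t1\t-9")  # missing genotype

  back <- read_structure(path)
  expect_identical(
    dplyr::arrange(tibble::as_tibble(back), individual, locus),
    dplyr::arrange(tibble::as_tibble(panel), individual, locus)
  )

  bad <- make_panel(c("A", "X"), c("A", "X"))
  expect_error(export_structure(bad, tempfile()), "non-nucleotide")
})

test_that("alignment-derived panels feed the inbreeding statistics", {
  aln <- random_iupac_alignment(8, 100, 0.15, seed = 13)
  panel <- panel_from_alignment(aln)
  expect_true(all(c("individual", "locus", "allele_1") %in% names(panel)))
  expect_true(is.finite(fis_estimate(panel)))
})
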