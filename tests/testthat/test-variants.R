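test_that("the pileup caller recovers planted heterozygous sites", {
  pair <- simulate_parental_pair(3e4, 0.02, seed = 51)
  plan <- hybrid_plan(data.frame(start = 0, end = 3e4,
                                 copies_a = 2, copies_b = 1),
                      het_rate_a = 3)
  truth <- simulate_hybrid_genome(pair, plan, seed = 52)
  reads <- simulate_reads(truth, coverage = 15, error_rate = 0, seed = 53)
  asn <- assign_reads(reads, pair)
  sites <- pileup_genotype(asn, "A")

  planted <- truth$planted_het$pos[truth$planted_het$subgenome == "A"]
  inner <- planted[planted > 500 & planted < 3e4 - 500]
  expect_gt(mean(inner %in% sites$pos), 0.9)
  expect_true(all(sites$gt == "0/1"))
  ## allele balance near 1/2 on the two-copy subgenome
  fr <- vapply(sites$ad, function(x) x[2] / sum(x), numeric(1))
  expect_lt(abs(median(fr) - 0.5), 0.05)
  ## no sites away from planted positions (error-free reads)
  expect_true(all(sites$pos %in% planted))

  ## homozygous-reference region emits nothing
  sites_b <- pileup_genotype(asn, "B")
  expect_identical(nrow(sites_b), 0L)
})

test_that("hard filtering applies each annotation criterion when present", {
  sites <- fake_sites(
    gt = rep("0/1", 5),
    ad = rep(list(c(10L, 10L)), 5),
    qd = c(4.9, 5.1, NA, 10, 10),
    fs = c(10, 10, NA, 56, 10),
    sor = c(1, 1, NA, 1, 2.5)
  )
  kept <- hard_filter(sites)
  ## QD=4.9 removed; FS=56 removed; SOR=2.5 removed; NA annotations retained
  expect_identical(kept$pos, sites$pos[c(2, 3)])

  rank <- fake_sites(gt = "0/1", ad = list(c(8L, 9L)), mqrs = -5.5)
  expect_identical(nrow(hard_filter(rank)), 0L)
})

test_that("allelic-state classes follow the GT/AD rule with the 5% cut", {
  sites <- fake_sites(
    gt = c("0/1", "1/2", "1/2", "1/1"),
    ad = list(c(12L, 11L), c(1L, 20L, 19L), c(6L, 20L, 18L), c(0L, 30L))
  )
  cl <- classify_allelic_state(sites)
  expect_identical(cl$allelic_state,
                   c("biallelic", "biallelic", "triallelic", "other"))

  ## scaling every AD by a constant changes nothing
  scaled <- sites
  scaled$ad <- lapply(sites$ad, function(x) x * 7L)
  expect_identical(classify_allelic_state(scaled)$allelic_state,
                   cl$allelic_state)

  ## the alternative strict reading also gates 0/1 genotypes
  strict <- classify_allelic_state(sites, strict_01 = TRUE)
  expect_identical(strict$allelic_state[1], "other")

  missing_ad <- fake_sites(gt = "0/1", ad = list(integer()))
  expect_error(classify_allelic_state(missing_ad), "AD")
})

test_that("heterozygosity windows count sites and report the genome rate", {
  sites <- fake_sites(gt = rep("0/1", 3), ad = rep(list(c(10L, 10L)), 3),
                      pos = c(1000L, 5000L, 15000L))
  hw <- het_density_windows(sites, window = 10000, ref_length = 30000)
  expect_identical(hw$n_het, c(2L, 1L, 0L))
  expect_equal(attr(hw, "pct_heterozygosity"), 100 * 3 / 30000)

  none <- het_density_windows(fake_sites(character(), list()),
                              ref_length = 30000)
  expect_identical(none$n_het, c(0L, 0L, 0L))
})

test_that("LOH segments are maximal low-heterozygosity runs", {
  hw <- structure(
    tibble::tibble(start = seq(0, 9e4, 1e4), end = seq(1e4, 1e5, 1e4),
                   n_het = c(9, 0, 1, 0, 0, 1, 8, 9, 9, 9)),
    class = c("het_windows", "tbl_df", "tbl", "data.frame")
  )
  seg <- detect_loh(hw, max_het_per_window = 1, min_windows = 5)
  expect_identical(nrow(seg), 1L)
  expect_identical(c(seg$start, seg$end), c(1e4, 6e4))

  ## uniformly heterozygous track: nothing called
  hw$n_het <- rep(10L, 10)
  expect_identical(nrow(detect_loh(hw)), 0L)

  ## fully homozygous subgenome: one segment spanning the scaffold
  hw$n_het <- rep(0L, 10)
  all_loh <- detect_loh(hw)
  expect_identical(c(all_loh$start, all_loh$end), c(0, 1e5))
})

test_that("minor-allele windows report balanced fractions and the mode", {
  single <- fake_sites(gt = "0/1", ad = list(c(10L, 20L)), pos = 500L)
  maw <- minor_allele_windows(single, window = 2000, ref_length = 2000)
  expect_equal(maw$mean_minor_fraction[1], 1 / 3)

  ## binomial depths around 1/2: mode lands near 0.5 despite the fold
  set.seed(54)
  n <- 400
  alt <- rbinom(n, 40, 0.5)
  sites <- fake_sites(gt = rep("0/1", n),
                      ad = lapply(alt, function(a) c(40L - a, a)),
                      pos = sort(sample.int(5e4, n)))
  maw2 <- minor_allele_windows(sites, ref_length = 5e4)
  expect_lt(abs(attr(maw2, "mode") - 0.5), 0.03)
  expect_identical(attr(maw2, "interpretation"), "diploid-like")

  empty <- minor_allele_windows(fake_sites(character(), list()),
                                ref_length = 1000)
  expect_identical(nrow(empty), 0L)
})

test_that("VCF import carries GT, AD and the filter annotations", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##contig=<ID=chr1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tT\t50\t.\tQD=4.2;FS=3.0\tGT:AD\t0/1:12,11",
    "chr1\t200\t.\tG\tC,T\t60\t.\tQD=20;FS=1.0\tGT:AD\t1/2:1,20,19"
  ), vcf)
  sites <- read_vcf_sites(vcf)
  expect_identical(sites$gt, c("0/1", "1/2"))
  expect_identical(sites$ad[[2]], c(1L, 20L, 19L))
  expect_equal(sites$qd, c(4.2, 20))
  ## the QD < 5 site is removed by the hard filter
  expect_identical(hard_filter(sites)$pos, 200L)
  expect_identical(
    classify_allelic_state(hard_filter(sites))$allelic_state, "biallelic"
  )
})
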