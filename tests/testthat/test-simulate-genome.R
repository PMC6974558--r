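test_that("parental pair divergence matches the requested rate", {
  p0 <- simulate_parental_pair(10000, 0, seed = 1)
  expect_identical(p0$seq_a, p0$seq_b)
  expect_length(p0$divergence_map, 0)

  p <- simulate_parental_pair(1e5, 0.02, seed = 7)
  rate <- length(p$divergence_map) / p$length
  tol <- 3 * sqrt(0.02 * 0.98 / 1e5)
  expect_lt(abs(rate - 0.02), tol)
  ## the map is exactly the positions where the sequences differ
  ca <- strsplit(p$seq_a, "")[[1]]
  cb <- strsplit(p$seq_b, "")[[1]]
  expect_identical(which(ca != cb), p$divergence_map)
  expect_false(grepl("[^ACGT]", p$seq_a))

  expect_identical(simulate_parental_pair(1e4, 0.02, seed = 7),
                   simulate_parental_pair(1e4, 0.02, seed = 7))
  expect_error(simulate_parental_pair(100, 0.02, seed = 1), "length")
})

test_that("hybrid plans validate tiling and report exact weighted ploidy", {
  plan <- hybrid_plan(data.frame(start = c(0, 5e4), end = c(5e4, 2e5),
                                 copies_a = c(2, 1), copies_b = c(1, 1)))
  ## length-weighted mean copies: (5e4*3 + 1.5e5*2) / 2e5
  expect_identical(attr(plan, "total_ploidy"),
                   (5e4 * 3 + 1.5e5 * 2) / 2e5)
  expect_error(
    hybrid_plan(data.frame(start = c(0, 4e4), end = c(5e4, 2e5),
                           copies_a = 1, copies_b = 1)),
    "tile"
  )
  expect_error(
    hybrid_plan(data.frame(start = 0, end = 1e4, copies_a = 0, copies_b = 0)),
    "copies"
  )
})

test_that("hybrid genomes carry planted heterozygosity outside LOH only", {
  pair <- simulate_parental_pair(5e4, 0.02, seed = 2)

  ## 1:1 with no heterozygosity: copies reproduce the parents exactly
  plain <- simulate_hybrid_genome(
    pair, hybrid_plan(data.frame(start = 0, end = 5e4,
                                 copies_a = 1, copies_b = 1)), seed = 3)
  expect_identical(sort(plain$copies$seq), sort(c(pair$seq_a, pair$seq_b)))
  expect_identical(nrow(plain$planted_het), 0L)

  ## Poisson oracle for the planted-site count on a 2:1 plan
  pair2 <- simulate_parental_pair(1e5, 0.02, seed = 5)
  plan2 <- hybrid_plan(data.frame(start = 0, end = 1e5,
                                  copies_a = 2, copies_b = 1),
                       het_rate_a = 2)
  truth2 <- simulate_hybrid_genome(pair2, plan2, seed = 6)
  n_a <- sum(truth2$planted_het$subgenome == "A")
  expect_lt(abs(n_a - 200), 3 * sqrt(200))

  ## LOH tract receives no planted sites
  plan3 <- hybrid_plan(
    data.frame(start = c(0, 4e4, 6e4), end = c(4e4, 6e4, 1e5),
               copies_a = 2, copies_b = 1,
               loh = c(FALSE, TRUE, FALSE)),
    het_rate_a = 5
  )
  truth3 <- simulate_hybrid_genome(pair2, plan3, seed = 7)
  in_loh <- truth3$planted_het$pos > 4e4 & truth3$planted_het$pos <= 6e4
  expect_identical(sum(in_loh), 0L)

  ## copies overlapping any position match the segment copy numbers
  at <- function(truth, pos) {
    sum(truth$copies$start < pos & truth$copies$end >= pos)
  }
  expect_identical(at(truth3, 1e4), 3L)
  expect_identical(at(truth3, 9e4), 3L)
})

test_that("simulated reads hit target depth, match their source, rerun identically", {
  pair <- simulate_parental_pair(5e4, 0, seed = 8)
  plan <- hybrid_plan(data.frame(start = 0, end = 5e4,
                                 copies_a = 1, copies_b = 0))
  truth <- simulate_hybrid_genome(pair, plan, seed = 9)
  reads <- simulate_reads(truth, coverage = 10, error_rate = 0, seed = 10)

  ## Poisson depth oracle: mean depth of the single copy near 10x
  total_bases <- sum(nchar(reads$seq))
  expect_gt(total_bases / 5e4, 8.8)
  expect_lt(total_bases / 5e4, 11.2)

  ## error-free reads substring-match their source copy
  src <- truth$copies$seq[1]
  m1 <- reads[reads$mate == 1, ]
  hits <- substring(src, m1$frag_start, m1$frag_start + nchar(m1$seq) - 1L)
  expect_identical(hits, m1$seq)

  ## origin labels partition the read set
  expect_identical(sum(table(reads$copy_id)), nrow(reads))

  rerun <- simulate_reads(truth, coverage = 10, error_rate = 0, seed = 10)
  expect_identical(reads, rerun)
})

test_that("read length controls how often reads span a diagnostic site", {
  ## binomial overlap property: a read misses all diagnostic sites with
  ## probability (1 - d)^read_len; at d = 0.04 over 99% of reads hit one
  pair <- simulate_parental_pair(1e5, 0.04, seed = 20)
  plan <- hybrid_plan(data.frame(start = 0, end = 1e5,
                                 copies_a = 1, copies_b = 1))
  truth <- simulate_hybrid_genome(pair, plan, seed = 21)
  reads <- simulate_reads(truth, coverage = 4, error_rate = 0, seed = 22)
  div <- pair$divergence_map
  m1 <- reads[reads$mate == 1, ]
  starts <- m1$frag_start
  hit <- vapply(seq_len(nrow(m1)), function(i) {
    any(div >= starts[i] & div <= starts[i] + 149)
  }, logical(1))
  expect_gt(mean(hit), 0.99)
  expect_lt(abs(mean(hit) - (1 - (1 - 0.04)^150)), 0.01)
})
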