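## small shared simulation for assignment tests
asn_fixture <- function(divergence = 0.02, L = 3e4, coverage = 8,
                        error_rate = 0.001, seed = 31) {
  pair <- simulate_parental_pair(L, divergence, seed = seed)
  plan <- hybrid_plan(data.frame(start = 0, end = L,
                                 copies_a = 1, copies_b = 1))
  truth <- simulate_hybrid_genome(pair, plan, seed = seed + 1)
  reads <- simulate_reads(truth, coverage = coverage,
                          error_rate = error_rate, seed = seed + 2)
  list(pair = pair, truth = truth, reads = reads,
       assignment = assign_reads(reads, pair))
}

test_that("assignment labels partition reads and respect the truth", {
  fx <- asn_fixture()
  asn <- fx$assignment
  summ <- assignment_summary(asn)
  expect_identical(sum(summ$n_reads), nrow(asn))

  ## error-free-enough reads overlapping a diagnostic site go to their
  ## true subgenome: no cross-assignments at 2% divergence
  uniq <- asn[asn$label %in% c("A_unique", "B_unique"), ]
  expect_identical(unique(uniq$subgenome[uniq$label == "A_unique"]), "A")
  expect_identical(unique(uniq$subgenome[uniq$label == "B_unique"]), "B")
  expect_gt(nrow(uniq) / nrow(asn), 0.8)

  ## identical references: every mapped read is ambiguous
  fx0 <- asn_fixture(divergence = 0, L = 2e4, coverage = 4, error_rate = 0)
  s0 <- assignment_summary(fx0$assignment)
  expect_identical(s0$n_reads[s0$label %in% c("A_unique", "B_unique")],
                   c(0L, 0L))
  expect_identical(s0$n_reads[s0$label == "unmapped"], 0L)
})

test_that("SAM import applies the same uniqueness rule", {
  ## two tiny hand-built SAM files for the same three reads
  sam_line <- function(id, flag, pos, seq, as) {
    paste(id, flag, "ref", pos, 60, paste0(nchar(seq), "M"), "*", 0, 0,
          seq, strrep("I", nchar(seq)), paste0("AS:i:", as), sep = "\t")
  }
  sam_a <- withr::local_tempfile(fileext = ".sam")
  sam_b <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sam_line("r1", 0, 10, "ACGTACGT", 0),     # better in A
               sam_line("r2", 4, 0, "ACGTACGT", -99),    # unmapped in A
               sam_line("r3", 0, 40, "ACGTACGT", -2)),   # tie
             sam_a)
  writeLines(c("@HD\tVN:1.6",
               sam_line("r1", 0, 12, "ACGTACGT", -4),
               sam_line("r2", 0, 30, "ACGTACGT", 0),     # only in B
               sam_line("r3", 0, 44, "ACGTACGT", -2)),
             sam_b)
  asn <- read_sam_assignment(sam_a, sam_b)
  expect_identical(asn$label[match(c("r1", "r2", "r3"), asn$read_id)],
                   c("A_unique", "B_unique", "ambiguous"))
  empty <- withr::local_tempfile(fileext = ".sam")
  writeLines("@HD\tVN:1.6", empty)
  expect_error(read_sam_assignment(sam_a, empty), "no alignment")
})
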