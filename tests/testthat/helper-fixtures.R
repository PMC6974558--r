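## Shared fixture builders and independent oracles, all generated in code.

## independent brute-force nucleotide diversity: mean pairwise Hamming
## distance over all haplotype pairs, columns with gap/N removed first
brute_force_pi <- function(hap_seqs) {
  m <- do.call(rbind, strsplit(hap_seqs, "", fixed = TRUE))
  m <- m[, colSums(m == "-" | m == "N") == 0, drop = FALSE]
  pairs <- utils::combn(nrow(m), 2)
  d <- apply(pairs, 2, function(p) sum(m[p[1], ] != m[p[2], ]))
  mean(d)
}

## alignment with an exact number of polymorphic columns among `total`
## usable sites (homozygous variation only)
alignment_with_polymorphism <- function(total, n_poly, n_strains = 4,
                                        locus = "locus", seed = 1) {
  set.seed(seed)
  m <- matrix("A", nrow = n_strains, ncol = total)
  poly_cols <- sample.int(total, n_poly)
  for (j in poly_cols) {
    carrier <- sample.int(n_strains, 1)
    m[carrier, j] <- "T"
  }
  marker_alignment(
    strain = sprintf("strain%02d", seq_len(n_strains)),
    seq = apply(m, 1, paste, collapse = ""),
    locus = locus
  )
}

## random IUPAC-coded alignment (diploid consensus of random haplotypes)
random_iupac_alignment <- function(n_strains, n_sites, het_prob = 0.1,
                                   seed = 1) {
  set.seed(seed)
  hap <- function() paste(sample(c("A", "C", "G", "T"), n_sites,
                                 replace = TRUE), collapse = "")
  base <- hap()
  seqs <- vapply(seq_len(n_strains), function(i) {
    h1 <- base
    h2 <- base
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      k <- which(runif(n_sites) < het_prob)
      ch[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
      paste(ch, collapse = "")
    }
    encode_heterozygous_consensus(mut(h1), mut(h2))
  }, character(1))
  marker_alignment(sprintf("s%02d", seq_len(n_strains)), seqs, locus = "rand")
}

## minimal variant_sites tibble for filter/classification tests
fake_sites <- function(gt, ad, qd = NA_real_, fs = NA_real_, sor = NA_real_,
                       mq = NA_real_, mqrs = NA_real_, rprs = NA_real_,
                       pos = NULL) {
  n <- length(gt)
  out <- tibble::tibble(
    scaffold = "A", pos = if (is.null(pos)) seq_len(n) * 100L else as.integer(pos),
    ref = "A", alt = "T", gt = gt, ad = ad,
    depth = vapply(ad, sum, numeric(1)),
    qd = rep_len(qd, n), fs = rep_len(fs, n), sor = rep_len(sor, n),
    mq = rep_len(mq, n), mq_rank_sum = rep_len(mqrs, n),
    read_pos_rank_sum = rep_len(rprs, n)
  )
  structure(out, class = c("variant_sites", class(out)))
}
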