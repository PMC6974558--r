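## Synthetic MLST genotype panels under partial selfing, and synthetic
## flow-cytometry DNA-content event mixtures.

#' Simulate an MLST genotype panel under partial selfing
#'
#' Each individual draws a number of consecutive selfing generations `t`
#' from the geometric distribution `P(t) = (1 - s) s^t` truncated at
#' `t_max`, with the tail mass lumped into `t_max` (so full selfing
#' `s = 1` degenerates to `t = t_max`). Conditional on `t`, locus `k` is
#' heterozygous with
#' probability `h0_k * 2^(-t)`, independently across loci: heterozygosity
#' halves with every selfing generation. Because all loci share the same
#' `t`, heterozygosity is positively correlated across loci (identity
#' disequilibrium), which is the signal the profile-likelihood selfing
#' estimator exploits.
#'
#' Loci are bi-allelic with nucleotide alleles. The outcrossed allele
#' frequency `p` solves `2 p (1 - p) = h0`, and homozygote alleles are
#' drawn so that the marginal allele frequency stays `p` at every `t`;
#' this keeps the panel at the classical inbreeding equilibrium where
#' `E[Fis] = s / (2 - s)`.
#'
#' @param n_individuals,n_loci Panel dimensions.
#' @param h0 Per-locus outcrossed heterozygosity probability, scalar or
#'   vector of length `n_loci`, in `(0, 0.5]` (a bi-allelic locus cannot
#'   exceed 0.5 under Hardy-Weinberg).
#' @param s Selfing rate in `[0, 1]`.
#' @param t_max Truncation of the selfing-generation count (default 20).
#' @param seed Integer seed.
#' @return A `genotype_panel` tibble: `individual`, `locus`, `allele_1`,
#'   `allele_2` (nucleotide characters). The per-individual selfing
#'   generation counts are kept in the `truth_t` attribute.
#' @export
#' @examples
#' panel <- simulate_mlst_population(50, 5, h0 = 0.5, s = 0.8, seed = 1)
#' dplyr::count(panel, heterozygous = allele_1 != allele_2)
simulate_mlst_population <- function(n_individuals, n_loci, h0, s,
                                     t_max = 20, seed = 1) {
  check_scalar_number(s, "s", 0, 1)
  check_scalar_number(t_max, "t_max", lower = 0)
  if (s == 1 && t_max == 0) {
    abort("s = 1 with t_max = 0 is contradictory: full selfing needs t > 0.")
  }
  if (length(h0) == 1) h0 <- rep(h0, n_loci)
  if (length(h0) != n_loci) abort("`h0` must have length 1 or n_loci.")
  if (any(h0 <= 0 | h0 > 0.5)) {
    abort("`h0` must lie in (0, 0.5] for a bi-allelic locus under HWE.")
  }
  set.seed(seed)

  w <- selfing_t_weights(s, t_max)
  t_i <- sample(0:t_max, n_individuals, replace = TRUE, prob = w)

  p <- (1 - sqrt(1 - 2 * h0)) / 2          # minor allele frequency per locus
  alleles <- purrr::map(seq_len(n_loci), function(k) sample(DNA_BASES, 2))

  out <- purrr::map_dfr(seq_len(n_loci), function(k) {
    h <- h0[k] * 2^(-t_i)
    het <- runif(n_individuals) < h
    ## homozygote minor-allele prob keeping marginal frequency at p
    p_hom <- (p[k] - h / 2) / (1 - h)
    minor <- runif(n_individuals) < p_hom
    a1 <- ifelse(het, alleles[[k]][1], ifelse(minor, alleles[[k]][1], alleles[[k]][2]))
    a2 <- ifelse(het, alleles[[k]][2], a1)
    tibble(
      individual = sprintf("ind%03d", seq_len(n_individuals)),
      locus = sprintf("L%02d", k),
      allele_1 = a1, allele_2 = a2
    )
  })
  out <- dplyr::arrange(out, .data$individual, .data$locus)
  structure(out,
            class = c("genotype_panel", class(out)),
            truth_t = t_i, h0 = h0, s = s)
}

#' Simulate flow-cytometry DNA-content events
#'
#' Draws fluorescence intensities from a two-component normal mixture with
#' the G2 component mean fixed at twice the G1 mean (cells after genome
#' replication carry twice the DNA), component standard deviations
#' `cv * mean`, and weights `(1 - g2_fraction, g2_fraction)`. Negative
#' draws are resampled so all intensities are positive.
#'
#' @param g1_mean Mean G1 fluorescence (arbitrary units).
#' @param cv Coefficient of variation of each component (> 0).
#' @param g2_fraction Fraction of events in G2, in `[0, 1]`.
#' @param n_events Number of events (a typical acquisition is 30,000).
#' @param seed Integer seed.
#' @return Tibble with columns `event` and `intensity`, plus a `truth`
#'   attribute recording the generating parameters.
#' @export
simulate_flow_events <- function(g1_mean, cv, g2_fraction, n_events = 30000,
                                 seed = 1) {
  check_scalar_number(g1_mean, "g1_mean", lower = 1e-9)
  check_scalar_number(cv, "cv", lower = 1e-9)
  check_scalar_number(g2_fraction, "g2_fraction", 0, 1)
  set.seed(seed)
  phase <- runif(n_events) < g2_fraction
  mu <- ifelse(phase, 2 * g1_mean, g1_mean)
  x <- rnorm(n_events, mu, cv * mu)
  while (any(bad <- x <= 0)) {
    x[bad] <- rnorm(sum(bad), mu[bad], cv * mu[bad])
  }
  structure(
    tibble(event = seq_len(n_events), intensity = x),
    truth = list(g1_mean = g1_mean, cv = cv, g2_fraction = g2_fraction)
  )
}
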