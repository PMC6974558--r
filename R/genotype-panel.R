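## Co-dominant genotype panels (individuals x loci, two alleles per cell),
## the Weir-Cockerham inbreeding coefficient, the Fis -> selfing transform
## and STRUCTURE-format export/import.

#' Construct a genotype panel
#'
#' @param x Data frame with columns `individual`, `locus`, `allele_1`,
#'   `allele_2`. Missing genotypes are `NA` in both allele columns.
#' @return A `genotype_panel` tibble.
#' @export
genotype_panel <- function(x) {
  x <- as_tibble(x)
  need <- c("individual", "locus", "allele_1", "allele_2")
  if (!all(need %in% names(x))) {
    abort("a genotype panel needs columns individual, locus, allele_1, allele_2.")
  }
  if (any(is.na(x$allele_1) != is.na(x$allele_2))) {
    abort("half-missing genotypes are not allowed: both alleles or neither.")
  }
  structure(x, class = unique(c("genotype_panel", class(x))))
}

#' Derive a genotype panel from an IUPAC-coded alignment
#'
#' Every usable polymorphic column of the alignment becomes a locus; the
#' two alleles of each strain come from splitting its IUPAC code (both
#' equal for unambiguous bases). This mirrors treating each bi-allelic MLST
#' position as a co-dominant marker for inbreeding statistics.
#'
#' @param aln A `marker_alignment`.
#' @return A `genotype_panel` with loci named `<locus>_p<position>`.
#' @export
panel_from_alignment <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  m <- aln_matrix(aln)
  keep <- which(usable_columns(m))
  split_allele <- function(ch, side) {
    amb <- ch %in% names(IUPAC2_SPLIT)
    out <- ch
    if (any(amb)) {
      out[amb] <- vapply(IUPAC2_SPLIT[ch[amb]], `[`, character(1), side)
    }
    out
  }
  cols <- purrr::map_dfr(keep, function(j) {
    a1 <- split_allele(m[, j], 1L)
    a2 <- split_allele(m[, j], 2L)
    if (length(unique(c(a1, a2))) < 2) return(NULL)
    tibble(individual = aln$strain,
           locus = sprintf("%s_p%04d", attr(aln, "locus"), j),
           allele_1 = a1, allele_2 = a2)
  })
  if (!nrow(cols)) abort("alignment has no polymorphic usable columns.")
  genotype_panel(cols)
}

#' Multilocus inbreeding coefficient (Fis)
#'
#' The default estimator is the Weir & Cockerham (1984) within-individual
#' correlation f for a single population: per locus and allele, the
#' between-individual and within-individual variance components are
#'
#' \deqn{b_u = n/(n-1) (\bar p_u (1-\bar p_u) - (2n-1)/(4n) \bar h_u),
#'       \quad c_u = \bar h_u / 2}
#'
#' with `n` the number of genotyped individuals, `p_u` the allele frequency
#' and `h_u` the frequency of heterozygotes carrying allele `u`; components
#' are summed over alleles and loci before forming
#' `f = 1 - sum(c) / sum(b + c)`. Individuals missing a locus are excluded
#' locus-wise. The naive `1 - Ho/He` estimator is available for
#' sensitivity checks.
#'
#' @param panel A `genotype_panel`.
#' @param method `"wc"` (Weir-Cockerham, default) or `"ho_he"`.
#' @return The multilocus Fis (scalar).
#' @export
#' @examples
#' panel <- simulate_mlst_population(200, 5, h0 = 0.5, s = 0.8, seed = 1)
#' fis_estimate(panel)
fis_estimate <- function(panel, method = c("wc", "ho_he")) {
  method <- match.arg(method)
  panel <- genotype_panel(panel)
  panel <- panel[!is.na(panel$allele_1), ]
  by_locus <- split(panel, panel$locus)
  comp <- purrr::map_dfr(by_locus, function(g) {
    n <- nrow(g)
    if (n < 2) return(NULL)
    alleles <- unique(c(g$allele_1, g$allele_2))
    if (length(alleles) < 2) return(NULL)
    het <- g$allele_1 != g$allele_2
    purrr::map_dfr(alleles, function(u) {
      p <- (sum(g$allele_1 == u) + sum(g$allele_2 == u)) / (2 * n)
      hbar <- mean(het & (g$allele_1 == u | g$allele_2 == u))
      tibble(
        b = n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar),
        c = hbar / 2,
        ho = hbar / 2,                       # per-allele share of Ho
        he = p * (1 - p)                     # per-allele share of He
      )
    })
  })
  if (!nrow(comp)) abort("Fis is undefined: all loci monomorphic or too few data.")
  if (method == "wc") {
    denom <- sum(comp$b + comp$c)
    if (denom == 0) abort("Fis is undefined: zero variance components.")
    1 - sum(comp$c) / denom
  } else {
    1 - sum(comp$ho) / sum(comp$he)
  }
}

#' Selfing rate implied by an inbreeding coefficient
#'
#' At inbreeding equilibrium a selfing rate `s` produces
#' `Fis = s / (2 - s)`; inverting gives `s = 2 Fis / (1 + Fis)`. Negative
#' Fis (heterozygote excess) is clamped to a selfing rate of 0 with a
#' warning rather than reported as a negative rate.
#'
#' @param fis Inbreeding coefficient in `(-1, 1]`.
#' @param digits Decimal places for the reported rate (half-up rounding,
#'   default 2, matching conventional table precision). Use `NULL` for the
#'   unrounded value.
#' @return The selfing rate in `[0, 1]`.
#' @export
#' @examples
#' selfing_from_fis(0.4372)
selfing_from_fis <- function(fis, digits = 2) {
  check_scalar_number(fis, "fis", -1, 1)
  if (fis == -1) abort("s is undefined at fis = -1.")
  if (fis < 0) {
    warn("negative Fis: reporting selfing rate 0.")
    s <- 0
  } else {
    s <- min(1, 2 * fis / (1 + fis))
  }
  if (is.null(digits)) s else round_half_up(s, digits)
}

STRUCTURE_DIGITS <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Export a genotype panel in STRUCTURE format
#'
#' Two rows per individual (one per allele), bases encoded by digits
#' A=0, C=1, G=2, T=3 and missing as -9, with a header line of locus
#' names. The digit range matches the conventional 0-3 nucleotide coding
#' for bi-allelic positions; the alphabetical base order and -9 missing
#' code are this package's documented (and configurable) choice.
#'
#' @param panel A `genotype_panel` with nucleotide alleles.
#' @param path Output file.
#' @param mapping Named integer vector base -> digit.
#' @param missing Missing-data code (default -9).
#' @return The path, invisibly.
#' @export
export_structure <- function(panel, path, mapping = STRUCTURE_DIGITS,
                             missing = -9L) {
  panel <- genotype_panel(panel)
  ok <- is.na(panel$allele_1) |
    (panel$allele_1 %in% names(mapping) & panel$allele_2 %in% names(mapping))
  if (!all(ok)) abort("non-nucleotide allele found; cannot encode.")
  loci <- sort(unique(panel$locus))
  wide <- function(col) {
    w <- tidyr::pivot_wider(panel, id_cols = "individual",
                            names_from = "locus",
                            values_from = dplyr::all_of(col))
    w[, c("individual", loci)]
  }
  w1 <- wide("allele_1")
  w2 <- wide("allele_2")
  enc <- function(w) {
    digits <- apply(as.matrix(w[, -1]), c(1, 2), function(a) {
      if (is.na(a)) missing else mapping[[a]]
    })
    cbind(w$individual, digits)
  }
  m1 <- enc(w1)
  m2 <- enc(w2)
  ## interleave the two allele rows of each individual
  rows <- rbind(m1, m2)[order(rep(seq_len(nrow(m1)), 2)), , drop = FALSE]
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(loci, collapse = "\t"), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a STRUCTURE file written by [export_structure()]
#'
#' @param path STRUCTURE-format file (two rows per individual).
#' @param mapping,missing Same coding as used on export.
#' @return A `genotype_panel`.
#' @export
read_structure <- function(path, mapping = STRUCTURE_DIGITS, missing = -9L) {
  lines <- readLines(path)
  loci <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- do.call(rbind, strsplit(lines[-1], "\t", fixed = TRUE))
  if (nrow(body) %% 2 != 0) abort("expected two rows per individual.")
  inv <- setNames(names(mapping), mapping)
  decode <- function(d) {
    d <- as.integer(d)
    out <- unname(inv[as.character(d)])
    out[d == missing] <- NA_character_
    out
  }
  odd <- seq(1, nrow(body), by = 2)
  purrr::map_dfr(odd, function(i) {
    tibble(individual = body[i, 1], locus = loci,
           allele_1 = decode(body[i, -1]),
           allele_2 = decode(body[i + 1, -1]))
  }) |>
    genotype_panel()
}
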