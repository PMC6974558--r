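## Between-strain genetic distance from joint genotypes: identity-by-state
## site classes (IBS0/IBS1) and principal component analysis of SNP
## dosages.

## multiset shared-allele count between two diploid genotypes (0, 1 or 2)
shared_alleles <- function(a1, a2, b1, b2) {
  pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
}

#' Pairwise IBS0/IBS1 counts between strains
#'
#' From a joint genotype table (one row per strain and site), counts for
#' every strain pair the sites sharing zero alleles identical by state
#' (IBS0) and exactly one (IBS1). Sites with missing data in any strain
#' are removed first — the extra filtering step used before cohort
#' distance analysis. For haploid subgenomes only IBS0 is meaningful (one
#' allele per strain), so `haploid = TRUE` compares `allele_1` only and
#' reports `ibs1` as `NA`.
#'
#' @param genotypes Tibble with columns `strain`, `pos` (site key),
#'   `allele_1`, `allele_2`.
#' @param haploid Compare single alleles only (default `FALSE`).
#' @return Symmetric tibble of pairs: `strain_1`, `strain_2`, `ibs0`,
#'   `ibs1`, `n_sites`. `ibs0 + ibs1 <= n_sites` always holds.
#' @export
ibs_matrix <- function(genotypes, haploid = FALSE) {
  g <- as_tibble(genotypes)
  strains <- unique(g$strain)
  if (length(strains) < 2) abort("IBS needs at least 2 strains.")
  ## keep only sites fully observed in all strains
  complete <- g |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::count(.data$pos) |>
    dplyr::filter(.data$n == length(strains))
  g <- g[g$pos %in% complete$pos & !is.na(g$allele_1), ]
  wide1 <- tidyr::pivot_wider(g, id_cols = "pos", names_from = "strain",
                              values_from = "allele_1")
  wide2 <- tidyr::pivot_wider(g, id_cols = "pos", names_from = "strain",
                              values_from = "allele_2")
  pairs <- combn(strains, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    x <- pairs[1, j]
    y <- pairs[2, j]
    if (haploid) {
      ibs0 <- sum(wide1[[x]] != wide1[[y]])
      ibs1 <- NA_integer_
    } else {
      sh <- shared_alleles(wide1[[x]], wide2[[x]], wide1[[y]], wide2[[y]])
      ibs0 <- sum(sh == 0)
      ibs1 <- sum(sh == 1)
    }
    tibble(strain_1 = x, strain_2 = y, ibs0 = as.integer(ibs0),
           ibs1 = as.integer(ibs1), n_sites = nrow(wide1))
  })
  ## emit both orientations so the matrix form is symmetric
  dplyr::bind_rows(out, dplyr::rename(out, strain_1 = "strain_2",
                                      strain_2 = "strain_1"))
}

#' Principal component analysis of joint SNP genotypes
#'
#' Codes each site as the per-strain dosage of non-major alleles
#' (0/1/2 for diploid genotypes), drops constant sites, column-centers
#' and eigendecomposes the covariance via [stats::prcomp()].
#'
#' @param genotypes Tibble with `strain`, `pos`, `allele_1`, `allele_2`
#'   (sites with missing data are removed).
#' @param n_components Number of axes to return (default all).
#' @return A `snp_pca` object: list with `scores` (tibble, one row per
#'   strain) and `var_explained` (fractions summing to 1 over all
#'   components). `tidy()` returns the scores, `glance()` the variance
#'   fractions.
#' @export
snp_pca <- function(genotypes, n_components = NULL) {
  g <- as_tibble(genotypes)
  strains <- unique(g$strain)
  if (length(strains) < 3) abort("PCA needs at least 3 strains.")
  complete <- g |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::count(.data$pos) |>
    dplyr::filter(.data$n == length(strains))
  g <- g[g$pos %in% complete$pos & !is.na(g$allele_1), ]
  ## dosage of non-major alleles per site
  dose <- g |>
    dplyr::group_by(.data$pos) |>
    dplyr::mutate(major = names(which.max(table(c(.data$allele_1, .data$allele_2))))) |>
    dplyr::ungroup() |>
    dplyr::mutate(dosage = (.data$allele_1 != .data$major) +
                    (.data$allele_2 != .data$major))
  m <- tidyr::pivot_wider(dose, id_cols = "strain", names_from = "pos",
                          values_from = "dosage")
  mat <- as.matrix(m[, -1])
  rownames(mat) <- m$strain
  mat <- mat[, apply(mat, 2, function(x) length(unique(x)) > 1), drop = FALSE]
  if (!ncol(mat)) abort("genotype matrix is constant; PCA undefined.")
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  var_exp <- pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components %||% ncol(pc$x)
  k <- min(k, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(strain = rownames(mat)), scores)
  structure(list(scores = scores, var_explained = var_exp[seq_len(k)],
                 n_sites = ncol(mat)),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat(sprintf("<snp_pca> %d strains, %d variable sites; PC1 %.1f%%\n",
              nrow(x$scores), x$n_sites, 100 * x$var_explained[1]))
  invisible(x)
}

#' @method tidy snp_pca
#' @export
tidy.snp_pca <- function(x, ...) x$scores

#' @method glance snp_pca
#' @export
glance.snp_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained)
}
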