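geno_tbl <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(strain = r[[1]], pos = seq_along(r[[2]]),
                   allele_1 = r[[2]], allele_2 = r[[3]])
  })
}

test_that("IBS counts follow the shared-allele definitions", {
  g <- geno_tbl(
    list("x", c("A", "A", "A", "C"), c("A", "T", "A", "C")),
    list("y", c("T", "A", "A", "C"), c("T", "A", "A", "C"))
  )
  ibs <- ibs_matrix(g)
  row <- ibs[ibs$strain_1 == "x" & ibs$strain_2 == "y", ]
  expect_identical(row$ibs0, 1L)  # A/A vs T/T
  expect_identical(row$ibs1, 1L)  # A/T vs A/A
  expect_identical(row$n_sites, 4L)

  ## identical strains share everything
  same <- ibs_matrix(geno_tbl(
    list("x", c("A", "C"), c("T", "C")),
    list("x2", c("A", "C"), c("T", "C"))
  ))
  expect_identical(same$ibs0[1], 0L)
  expect_identical(same$ibs1[1], 0L)

  ## haploid mode compares single alleles, IBS1 undefined
  hap <- ibs_matrix(g, haploid = TRUE)
  expect_identical(hap$ibs0[1], 1L)
  expect_true(is.na(hap$ibs1[1]))
})

test_that("IBS output is symmetric and conserves site counts", {
  set.seed(61)
  strains <- c("s1", "s2", "s3")
  g <- purrr::map_dfr(strains, function(s) {
    tibble::tibble(strain = s, pos = 1:60,
                   allele_1 = sample(c("A", "T"), 60, TRUE),
                   allele_2 = sample(c("A", "T"), 60, TRUE))
  })
  ibs <- ibs_matrix(g)
  for (i in seq_len(nrow(ibs))) {
    mirror <- ibs[ibs$strain_1 == ibs$strain_2[i] &
                    ibs$strain_2 == ibs$strain_1[i], ]
    expect_identical(mirror$ibs0, ibs$ibs0[i])
    expect_identical(mirror$ibs1, ibs$ibs1[i])
  }
  expect_true(all(ibs$ibs0 + ibs$ibs1 <= ibs$n_sites))

  ## missing data excluded site-wise before counting
  g$allele_1[g$strain == "s1" & g$pos <= 10] <- NA
  g$allele_2[g$strain == "s1" & g$pos <= 10] <- NA
  expect_identical(unique(ibs_matrix(g)$n_sites), 50L)
})

test_that("PCA separates planted clusters and partitions variance", {
  set.seed(62)
  ## two clusters of strains differing at 100 fixed sites plus noise
  make_strain <- function(id, grp) {
    fixed <- if (grp == 1) "A" else "T"
    tibble::tibble(
      strain = id, pos = 1:120,
      allele_1 = c(rep(fixed, 100), sample(c("A", "T"), 20, TRUE)),
      allele_2 = c(rep(fixed, 100), sample(c("A", "T"), 20, TRUE))
    )
  }
  g <- dplyr::bind_rows(
    purrr::map_dfr(1:4, function(i) make_strain(paste0("g1_", i), 1)),
    purrr::map_dfr(1:4, function(i) make_strain(paste0("g2_", i), 2))
  )
  pc <- snp_pca(g)
  expect_gt(pc$var_explained[1], 0.9)
  pc1 <- pc$scores$PC1
  grp <- startsWith(pc$scores$strain, "g1")
  expect_true(max(pc1[grp]) < min(pc1[!grp]) ||
                min(pc1[grp]) > max(pc1[!grp]))
  expect_equal(sum(glance(snp_pca(g))$var_explained), 1)

  ## duplicated strain lands on identical coordinates
  dup <- dplyr::bind_rows(
    g, dplyr::mutate(dplyr::filter(g, strain == "g1_1"), strain = "g1_copy")
  )
  pcd <- snp_pca(dup)
  sc <- pcd$scores
  expect_equal(unlist(sc[sc$strain == "g1_1", -1]),
               unlist(sc[sc$strain == "g1_copy", -1]),
               tolerance = 1e-8)

  flat <- geno_tbl(
    list("a", c("A", "A"), c("A", "A")),
    list("b", c("A", "A"), c("A", "A")),
    list("c", c("A", "A"), c("A", "A"))
  )
  expect_error(snp_pca(flat), "constant")
})
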