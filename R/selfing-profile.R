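## Maximum-likelihood selfing-rate estimation from the multilocus
## heterozygosity profile, exploiting identity disequilibrium: under
## partial selfing all loci of an individual share its (latent) number of
## consecutive selfing generations t, so heterozygosity is correlated
## across loci, which separates selfing from simply low diversity.

## binary heterozygosity matrix (individuals x loci) from a panel; NA kept
het_matrix <- function(panel) {
  panel <- genotype_panel(panel)
  w <- tidyr::pivot_wider(
    dplyr::mutate(panel, het = as.integer(.data$allele_1 != .data$allele_2)),
    id_cols = "individual", names_from = "locus", values_from = "het"
  )
  m <- as.matrix(w[, -1])
  rownames(m) <- w$individual
  storage.mode(m) <- "integer"
  m
}

## log-likelihood of (s, h0) for the truncated-geometric selfing model:
## P(t) = (1-s) s^t with the tail lumped at t_max;
## P(het at locus k | t) = h0_k 2^-t
profile_loglik <- function(s, h0, H, t_max) {
  t_seq <- 0:t_max
  log_w <- log(selfing_t_weights(s, t_max))
  per_t <- vapply(t_seq, function(t) {
    hk <- pmin(pmax(h0 * 2^(-t), 1e-12), 1 - 1e-12)
    lp <- sweep(H, 2, log(hk), `*`) + sweep(1 - H, 2, log(1 - hk), `*`)
    rowSums(lp, na.rm = TRUE)
  }, numeric(nrow(H)))
  if (is.null(dim(per_t))) per_t <- matrix(per_t, nrow = nrow(H))
  lw <- sweep(per_t, 2, log_w, `+`)
  mx <- apply(lw, 1, max)
  sum(mx + log(rowSums(exp(lw - mx))))
}

## maximize over h0 for fixed s (used for the profile likelihood / SE)
opt_h0_given_s <- function(s, H, t_max, h0_init) {
  obj <- function(q) -profile_loglik(s, stats::plogis(q), H, t_max)
  fit <- optim(stats::qlogis(pmin(pmax(h0_init, 1e-3), 0.999)), obj,
               method = "BFGS", control = list(maxit = 200))
  -fit$value
}

#' Estimate the selfing rate from a multilocus heterozygosity profile
#'
#' Fits, by maximum likelihood, the model in which each individual has
#' undergone `t` consecutive selfing generations with truncated-geometric
#' probability proportional to `s^t` (`t = 0..t_max`) and is heterozygous
#' at locus `k` with probability `h0_k * 2^(-t)` independently across loci
#' given `t`. Optimization is multi-start over `s` in `{0.1, ..., 0.9}` on
#' logit scale to avoid boundary traps; the standard error comes from the
#' numerical curvature of the profile log-likelihood in `s`. The moment
#' diagnostic `g2_hat` (mean over locus pairs of
#' `E[Hk Hl] / (E[Hk] E[Hl]) - 1`) is reported as an identity-
#' disequilibrium check, not used in the fit.
#'
#' @param panel A `genotype_panel` with >= 2 loci.
#' @param t_max Truncation of the selfing-generation count (default 20).
#' @return A `selfing_fit` object; see [tidy.selfing_fit()] and
#'   [glance.selfing_fit()].
#' @export
#' @examples
#' panel <- simulate_mlst_population(200, 5, h0 = 0.5, s = 0.8, seed = 1)
#' glance(selfing_from_profile(panel))
selfing_from_profile <- function(panel, t_max = 20) {
  H <- het_matrix(panel)
  if (ncol(H) < 2) abort("profile-likelihood selfing needs >= 2 loci.")
  n_het <- sum(H, na.rm = TRUE)
  het_bar <- colMeans(H, na.rm = TRUE)

  ## identity-disequilibrium diagnostic
  pairs <- combn(ncol(H), 2)
  g2_terms <- apply(pairs, 2, function(p) {
    ok <- stats::complete.cases(H[, p])
    hk <- H[ok, p[1]]
    hl <- H[ok, p[2]]
    if (!sum(ok) || mean(hk) == 0 || mean(hl) == 0) return(NA_real_)
    mean(hk * hl) / (mean(hk) * mean(hl)) - 1
  })
  g2_hat <- mean(g2_terms, na.rm = TRUE)

  if (n_het == 0) {
    fit <- structure(
      list(s_hat = 1, se = NA_real_, h0_hat = setNames(het_bar, colnames(H)),
           g2_hat = g2_hat, logLik = NA_real_, t_max = t_max,
           boundary = TRUE, n_individuals = nrow(H), n_loci = ncol(H)),
      class = "selfing_fit"
    )
    return(fit)
  }

  h0_init <- pmin(pmax(het_bar * 1.5, 1e-3), 0.99)
  obj <- function(par) {
    -profile_loglik(stats::plogis(par[1]), stats::plogis(par[-1]), H, t_max)
  }
  starts <- seq(0.1, 0.9, by = 0.2)
  fits <- purrr::map(starts, function(s0) {
    optim(c(stats::qlogis(s0), stats::qlogis(h0_init)), obj,
          method = "BFGS", control = list(maxit = 300))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  s_hat <- stats::plogis(best$par[1])
  h0_hat <- setNames(stats::plogis(best$par[-1]), colnames(H))

  ## SE from profile-likelihood curvature in s (central second difference)
  delta <- 0.01
  s_lo <- max(s_hat - delta, 1e-4)
  s_hi <- min(s_hat + delta, 1 - 1e-4)
  se <- tryCatch({
    l0 <- -best$value
    l_lo <- opt_h0_given_s(s_lo, H, t_max, h0_hat)
    l_hi <- opt_h0_given_s(s_hi, H, t_max, h0_hat)
    d2 <- (l_hi - 2 * l0 + l_lo) / ((s_hi - s_hat) * (s_hat - s_lo))
    if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  }, error = function(e) NA_real_)

  structure(
    list(s_hat = s_hat, se = se, h0_hat = h0_hat, g2_hat = g2_hat,
         logLik = -best$value, t_max = t_max, boundary = FALSE,
         n_individuals = nrow(H), n_loci = ncol(H)),
    class = "selfing_fit"
  )
}

#' @export
print.selfing_fit <- function(x, ...) {
  cat(sprintf(
    "<selfing_fit> s = %.3f (se %.3f), g2 = %.3f, %d individuals x %d loci%s\n",
    x$s_hat, x$se, x$g2_hat, x$n_individuals, x$n_loci,
    if (x$boundary) " [boundary: no heterozygote observed]" else ""
  ))
  invisible(x)
}

#' Tidy a selfing-profile fit
#'
#' @param x A `selfing_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`s`, then per-locus `h0`).
#' @method tidy selfing_fit
#' @export
tidy.selfing_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "s", estimate = x$s_hat, std_error = x$se),
    tibble(term = paste0("h0_", names(x$h0_hat)), estimate = unname(x$h0_hat),
           std_error = NA_real_)
  )
}

#' One-row summary of a selfing-profile fit
#'
#' @param x A `selfing_fit`.
#' @param ... Unused.
#' @return One-row tibble with `s_hat`, `se`, `g2_hat`, `log_lik`,
#'   `boundary`, `n_individuals`, `n_loci`.
#' @method glance selfing_fit
#' @export
glance.selfing_fit <- function(x, ...) {
  tibble(s_hat = x$s_hat, se = x$se, g2_hat = x$g2_hat, log_lik = x$logLik,
         boundary = x$boundary, n_individuals = x$n_individuals,
         n_loci = x$n_loci)
}

#' Combined mating-system summary of a genotype panel
#'
#' Convenience wrapper reporting the Weir-Cockerham Fis, the
#' equilibrium-transformed selfing rate, and the profile-likelihood
#' selfing estimate with its identity-disequilibrium diagnostic, i.e. the
#' standard mating-system row block of an MLST diversity table.
#'
#' @param panel A `genotype_panel`.
#' @param t_max Truncation for the profile-likelihood model.
#' @return One-row tibble: `fis`, `s_from_fis`, `s_from_profile`,
#'   `s_profile_se`, `g2_hat`.
#' @export
selfing_estimate <- function(panel, t_max = 20) {
  fis <- fis_estimate(panel)
  fit <- selfing_from_profile(panel, t_max = t_max)
  tibble(
    fis = fis,
    s_from_fis = selfing_from_fis(fis),
    s_from_profile = fit$s_hat,
    s_profile_se = fit$se,
    g2_hat = fit$g2_hat
  )
}
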