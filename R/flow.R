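## Flow-cytometry DNA-content analysis: fit G1/G2 fluorescence peaks with
## a constrained two-component mixture and call relative ploidy against a
## reference strain. Input is a plain one-column event table (gated
## events); binary FCS parsing is left to an upstream converter.

kde_modes <- function(x) {
  d <- density(x, n = 512)
  i <- which(diff(sign(diff(d$y))) == -2) + 1L
  tibble(mode = d$x[i], height = d$y[i]) |>
    dplyr::arrange(dplyr::desc(.data$height))
}

## EM for a two-component normal mixture with the mean ratio mu2/mu1
## projected into `band` after each M-step
em_two_normal <- function(x, mu1, mu2, band, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  s1 <- s2 <- stats::sd(x) / 4
  w <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w * dnorm(x, mu1, s1)
    d2 <- (1 - w) * dnorm(x, mu2, s2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    w <- mean(r1)
    if (w < 1e-6 || w > 1 - 1e-6) break
    mu1 <- sum(r1 * x) / sum(r1)
    mu2 <- sum((1 - r1) * x) / sum(1 - r1)
    ## relaxed doubling constraint on the G2 mean
    ratio <- mu2 / mu1
    if (ratio < band[1]) mu2 <- band[1] * mu1
    if (ratio > band[2]) mu2 <- band[2] * mu1
    s1 <- sqrt(sum(r1 * (x - mu1)^2) / sum(r1))
    s2 <- sqrt(sum((1 - r1) * (x - mu2)^2) / sum(1 - r1))
    s1 <- max(s1, 1e-6 * mu1)
    s2 <- max(s2, 1e-6 * mu1)
    ll <- sum(log(w * dnorm(x, mu1, s1) + (1 - w) * dnorm(x, mu2, s2)))
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2, w1 = w,
       loglik = sum(log(w * dnorm(x, mu1, s1) +
                          (1 - w) * dnorm(x, mu2, s2))))
}

#' Fit G1 and G2 fluorescence peaks
#'
#' Fits a two-component normal mixture to DNA-content event intensities
#' with the G2 mean constrained to twice the G1 mean relaxed to the
#' `ratio_band` (default 1.7-2.3x). Initialization uses the two highest
#' kernel-density modes whose ratio falls in the band, followed by EM with
#' seeded random restarts. Populations with no acceptable second mode are
#' reported with the G2 component absent; more than two substantial
#' density modes raise a `multimodal` flag (a mixed population of cells
#' with different genome contents).
#'
#' @param events Data frame with an `intensity` column (e.g. from
#'   [simulate_flow_events()]) or a numeric vector; >= 1000 events.
#' @param ratio_band Accepted G2/G1 mean ratio interval.
#' @param restarts Number of jittered EM restarts (default 5).
#' @param seed Seed for the restarts.
#' @return A `flow_fit` object: `g1_mean`, `g2_mean`, `g1_sd`, `g2_sd`,
#'   `g1_fraction`, `fit_quality` (mean per-event log-likelihood),
#'   `flags` (character: any of `g2_absent`, `multimodal`), `n_events`.
#' @export
detect_g1_g2 <- function(events, ratio_band = c(1.7, 2.3), restarts = 5,
                         seed = 1) {
  x <- if (is.data.frame(events)) events$intensity else as.numeric(events)
  if (length(x) < 1000) abort("need >= 1000 events for a stable fit.")
  if (any(x <= 0)) abort("intensities must be positive.")
  set.seed(seed)
  flags <- character()

  modes <- kde_modes(x)
  ## substantial, well-separated modes; three or more means the events mix
  ## cell populations with different genome contents
  main <- modes[modes$height >= 0.05 * max(modes$height), ]
  main <- main[order(main$mode), ]
  if (nrow(main) > 1) {
    sep <- c(TRUE, diff(main$mode) / main$mode[-nrow(main)] > 0.15)
    main <- main[sep, ]
  }
  if (nrow(main) > 2) flags <- c(flags, "multimodal")

  ## candidate (G1, G2) mode pair: ratio within band, maximal joint height
  cand <- NULL
  if (nrow(modes) >= 2) {
    pairs <- expand.grid(i = seq_len(nrow(modes)), j = seq_len(nrow(modes)))
    pairs <- pairs[pairs$i != pairs$j, ]
    lo <- pmin(modes$mode[pairs$i], modes$mode[pairs$j])
    hi <- pmax(modes$mode[pairs$i], modes$mode[pairs$j])
    ok <- hi / lo >= ratio_band[1] & hi / lo <= ratio_band[2]
    if (any(ok)) {
      h <- modes$height[pairs$i] + modes$height[pairs$j]
      best <- which(ok)[which.max(h[ok])]
      cand <- c(lo[best], hi[best])
    }
  }
  if (is.null(cand)) {
    ## no acceptable G2 mode: single-peak population
    flags <- c(flags, "g2_absent")
    fit <- list(mu1 = modes$mode[1], s1 = stats::sd(x), w1 = 1)
    ## refine G1 with a trimmed mean around the main mode
    near <- abs(x - fit$mu1) < 2 * stats::mad(x)
    g1 <- mean(x[near])
    out <- structure(
      list(g1_mean = g1, g2_mean = NA_real_, g1_sd = stats::sd(x[near]),
           g2_sd = NA_real_, g1_fraction = 1,
           fit_quality = mean(dnorm(x, g1, stats::sd(x[near]), log = TRUE)),
           flags = unique(flags), n_events = length(x),
           ratio_band = ratio_band),
      class = "flow_fit"
    )
    return(out)
  }

  fits <- purrr::map(seq_len(restarts), function(r) {
    jit <- if (r == 1) c(1, 1) else runif(2, 0.95, 1.05)
    em_two_normal(x, cand[1] * jit[1], cand[2] * jit[2], ratio_band)
  })
  best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]
  if (best$w1 < 0.02) flags <- c(flags, "g2_absent")

  structure(
    list(g1_mean = best$mu1, g2_mean = best$mu2, g1_sd = best$s1,
         g2_sd = best$s2, g1_fraction = best$w1,
         fit_quality = best$loglik / length(x), flags = unique(flags),
         n_events = length(x), ratio_band = ratio_band),
    class = "flow_fit"
  )
}

#' @export
print.flow_fit <- function(x, ...) {
  cat(sprintf(
    "<flow_fit> G1 %.1f, G2 %s (ratio %s), G1 fraction %.2f%s\n",
    x$g1_mean,
    if (is.na(x$g2_mean)) "absent" else sprintf("%.1f", x$g2_mean),
    if (is.na(x$g2_mean)) "-" else sprintf("%.2f", x$g2_mean / x$g1_mean),
    x$g1_fraction,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' @method tidy flow_fit
#' @export
tidy.flow_fit <- function(x, ...) {
  tibble(
    component = c("G1", "G2"),
    mean = c(x$g1_mean, x$g2_mean),
    sd = c(x$g1_sd, x$g2_sd),
    weight = c(x$g1_fraction, 1 - x$g1_fraction)
  )
}

#' @method glance flow_fit
#' @export
glance.flow_fit <- function(x, ...) {
  tibble(
    g1_mean = x$g1_mean, g2_mean = x$g2_mean,
    g2_g1_ratio = x$g2_mean / x$g1_mean,
    g1_fraction = x$g1_fraction, fit_quality = x$fit_quality,
    flags = paste(x$flags, collapse = ","), n_events = x$n_events
  )
}

#' Call relative ploidy against a reference strain
#'
#' DNA content scales with ploidy, so the ploidy estimate is
#' `reference_ploidy * G1(sample) / G1(reference)`. The distance of the
#' real-valued estimate to the nearest integer is reported as a
#' confidence proxy; multiplying every intensity of both samples by a
#' constant leaves the call unchanged.
#'
#' @param sample,reference `flow_fit` objects for the query and the
#'   reference strain.
#' @param reference_ploidy Known ploidy of the reference (default 2).
#' @return One-row tibble: `ploidy`, `ploidy_integer`,
#'   `distance_to_integer`, `normalized_g1`, `flags`.
#' @export
call_ploidy <- function(sample, reference, reference_ploidy = 2) {
  stopifnot(inherits(sample, "flow_fit"), inherits(reference, "flow_fit"))
  if (!is.finite(reference$g1_mean)) abort("reference G1 peak absent.")
  rel <- sample$g1_mean / reference$g1_mean
  est <- reference_ploidy * rel
  tibble(
    ploidy = est,
    ploidy_integer = as.integer(round(est)),
    distance_to_integer = abs(est - round(est)),
    normalized_g1 = rel,
    flags = paste(unique(c(sample$flags, reference$flags)), collapse = ",")
  )
}
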