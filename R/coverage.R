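## Windowed read-depth profiles of the two subgenomes and integer
## copy-number inference, the coverage-track stage of hybrid genome
## characterization (non-overlapping windows, depth normalized to the
## depth of a single chromosome copy, log2 scale).

## per-base depth vector from read starts (constant read length, no indels)
depth_vector <- function(starts, read_len, L) {
  d <- numeric(L + 1L)
  tab_s <- tabulate(starts, nbins = L)
  ends <- pmin(starts + read_len, L + 1L)
  tab_e <- tabulate(ends, nbins = L + 1L)
  d[seq_len(L)] <- tab_s
  d <- d - tab_e
  cumsum(d)[seq_len(L)]
}

window_means <- function(depth, window) {
  L <- length(depth)
  starts <- seq(0L, L - 1L, by = window)
  ends <- pmin(starts + window, L)
  cs <- c(0, cumsum(depth))
  tibble(
    start = starts, end = ends,
    mean_depth = (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts),
    short = (ends - starts) < window
  )
}

#' Windowed, 1n-normalized coverage profile of both subgenomes
#'
#' Computes mean unique-read depth in consecutive non-overlapping windows
#' along each parental reference and normalizes by the depth of a single
#' chromosome copy: the total unique-read depth pooled over both
#' subgenomes divided by the total ploidy. Values are also reported on a
#' log2 scale, with a pseudo-depth for empty windows so the logarithm is
#' defined. A trailing partial window is flagged `short` and excluded from
#' profile summaries.
#'
#' @param assignment A `read_assignment` with at least one unique read.
#' @param window Window size in nucleotides (default 1700).
#' @param total_ploidy Total chromosome copies genome-wide. If `NULL`, the
#'   integer in 2..4 minimizing the mean squared rounding residual of the
#'   normalized window depths is used and flagged in the output attributes.
#' @param epsilon Pseudo-depth in reads for empty windows (default 0.25,
#'   half the smallest countable depth).
#' @return A `coverage_windows` tibble: `subgenome`, `start`, `end`
#'   (0-based half-open), `mean_depth`, `norm_depth` (multiples of the 1n
#'   depth), `log2_norm`, `short`. Attributes: `one_n_depth`,
#'   `total_ploidy`, `ploidy_estimated`, `window`.
#' @export
coverage_profile <- function(assignment, window = 1700, total_ploidy = NULL,
                             epsilon = 0.25) {
  stopifnot(inherits(assignment, "read_assignment"))
  read_len <- attr(assignment, "read_len")
  refs <- list(A = attr(assignment, "ref_a"), B = attr(assignment, "ref_b"))
  if (is.null(refs$A) || is.null(refs$B)) {
    abort("assignment lacks reference sequences; pass ref_a/ref_b on import.")
  }
  uniq <- assignment[assignment$label %in% c("A_unique", "B_unique"), ]
  if (!nrow(uniq)) abort("no unique reads; cannot profile coverage.")

  win <- purrr::map_dfr(c("A", "B"), function(sub) {
    L <- nchar(refs[[sub]])
    starts <- uniq$ref_start[uniq$label == paste0(sub, "_unique")]
    depth <- depth_vector(starts, read_len, L)
    w <- window_means(depth, window)
    w$subgenome <- sub
    w
  })

  ## 1n depth: pooled unique-read depth over both subgenomes / total ploidy
  mean_len <- mean(c(nchar(refs$A), nchar(refs$B)))
  total_depth <- nrow(uniq) * read_len / mean_len
  if (is.null(total_ploidy)) {
    cand <- 2:4
    resid <- vapply(cand, function(p) {
      nd <- win$mean_depth[!win$short] / (total_depth / p)
      mean((nd - round(nd))^2)
    }, numeric(1))
    total_ploidy <- cand[which.min(resid)]
    estimated <- TRUE
  } else {
    estimated <- FALSE
  }
  one_n <- total_depth / total_ploidy

  win$norm_depth <- win$mean_depth / one_n
  win$log2_norm <- log2(pmax(win$mean_depth, epsilon) / one_n)
  out <- win[, c("subgenome", "start", "end", "mean_depth", "norm_depth",
                 "log2_norm", "short")]
  structure(as_tibble(out),
            class = unique(c("coverage_windows", class(as_tibble(out)))),
            one_n_depth = one_n, total_ploidy = total_ploidy,
            ploidy_estimated = estimated, window = window)
}

#' Integer copy-number calls and parental genome proportion
#'
#' Median-filters the normalized window depths per subgenome (robust to
#' single-window noise), rounds to integer copy number capped at the total
#' ploidy, and summarizes the genome-length-weighted mean copy number of
#' each subgenome as a reduced ratio (e.g. `2:1` for an allotriploid).
#' Windows whose smoothed depth sits persistently away from an integer
#' (residual > 0.2) are flagged `mixed_flag`, the signature of a
#' heterogeneous cell population rather than a clean integer plateau.
#'
#' @param windows A `coverage_windows` tibble.
#' @param total_ploidy Defaults to the attribute carried by `windows`.
#' @param smooth_k Median filter width in windows (odd, default 5).
#' @return A `cn_profile` tibble: the windows plus `cn` (integer copies)
#'   and `mixed_flag`. Attributes: `proportion` (reduced ratio string),
#'   `mean_cn` (named per subgenome).
#' @export
infer_copy_number <- function(windows, total_ploidy = NULL, smooth_k = 5) {
  stopifnot(inherits(windows, "coverage_windows"))
  total_ploidy <- total_ploidy %||% attr(windows, "total_ploidy")
  if (is.null(total_ploidy) || total_ploidy <= 0) {
    abort("total_ploidy must be positive.")
  }
  cap <- max(1L, round(total_ploidy) + 1L)

  out <- windows |>
    dplyr::group_by(.data$subgenome) |>
    dplyr::mutate(
      smooth = if (dplyr::n() >= smooth_k) {
        as.numeric(runmed(.data$norm_depth, smooth_k, endrule = "median"))
      } else .data$norm_depth,
      cn = pmin(pmax(as.integer(round(.data$smooth)), 0L), cap),
      mixed_flag = abs(.data$smooth - round(.data$smooth)) > 0.2
    ) |>
    dplyr::ungroup()

  full <- out[!out$short, ]
  mean_cn <- tapply((full$end - full$start) * full$cn, full$subgenome, sum) /
    tapply(full$end - full$start, full$subgenome, sum)
  prop <- reduce_ratio(round(mean_cn[["A"]]), round(mean_cn[["B"]]))

  structure(out,
            class = unique(c("cn_profile", class(out))),
            proportion = prop, mean_cn = mean_cn,
            total_ploidy = total_ploidy)
}
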