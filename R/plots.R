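## ggplot2 views of the result tracks.

#' @method autoplot coverage_windows
#' @export
autoplot.coverage_windows <- function(object, ...) {
  ggplot2::ggplot(object[!object$short, ],
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$log2_norm,
                               colour = .data$subgenome)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "genome position (bp)",
                  y = "log2(depth / 1n depth)",
                  colour = "subgenome") +
    ggplot2::theme_minimal()
}

#' @method autoplot cn_profile
#' @export
autoplot.cn_profile <- function(object, ...) {
  autoplot.coverage_windows(object) +
    ggplot2::geom_step(ggplot2::aes(y = log2(pmax(.data$cn, 0.25))),
                       linewidth = 0.3)
}

#' @method autoplot het_windows
#' @export
autoplot.het_windows <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$n_het)) +
    ggplot2::geom_point(size = 0.7, colour = "steelblue") +
    ggplot2::labs(x = "genome position (bp)",
                  y = sprintf("heterozygous SNPs / %d bp window",
                              attr(object, "window") %||% NA_integer_)) +
    ggplot2::theme_minimal()
}

#' @method autoplot flow_fit
#' @export
autoplot.flow_fit <- function(object, events = NULL, ...) {
  comp <- tidy(object)
  comp <- comp[!is.na(comp$mean), ]
  grid <- tibble(
    intensity = seq(0.5 * object$g1_mean,
                    2.8 * max(comp$mean), length.out = 400)
  )
  dens <- purrr::pmap_dfr(comp, function(component, mean, sd, weight) {
    tibble(component = component, intensity = grid$intensity,
           density = weight * dnorm(grid$intensity, mean, sd))
  })
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$intensity,
                                          y = .data$density,
                                          colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fluorescence intensity (a.u.)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    x <- if (is.data.frame(events)) events$intensity else events
    p <- p + ggplot2::geom_histogram(
      data = tibble(intensity = x),
      ggplot2::aes(x = .data$intensity, y = ggplot2::after_stat(density)),
      bins = 100, inherit.aes = FALSE, alpha = 0.3
    )
  }
  p
}

#' @method autoplot snp_pca
#' @export
autoplot.snp_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$strain)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
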