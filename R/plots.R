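## Static cluster plots: 1-D VAF histogram with posterior predictive
## curves, 2-D scatter colored by cluster, pairwise panels for D >= 3.

#' One-dimensional VAF density plot
#'
#' Histogram of the clustered VAFs overlaid with each cluster's posterior
#' predictive density (scaled by its mixing expectation) and their sum.
#'
#' @param fit A `vaf_fit` with D = 1.
#' @param grid_n Number of grid points for the predictive curves.
#' @param seed Seed for the Monte-Carlo predictive (beta model).
#' @return A ggplot object.
#' @export
plot_vaf_density <- function(fit, grid_n = 256, seed = 1) {
  stopifnot(ncol(fit$means) == 1)
  grid <- seq(0.002, 0.998, length.out = grid_n)
  pp <- posterior_predictive(fit, grid, seed = seed)
  curves <- data.frame(
    vaf = rep(grid, fit$K + 1),
    density = c(as.vector(pp$per_cluster %*% diag(fit$pi, fit$K)), pp$total),
    cluster = factor(rep(c(seq_len(fit$K), "all"), each = grid_n),
                     levels = c(seq_len(fit$K), "all")))
  pts <- data.frame(vaf = fit$data$x[, 1])
  ggplot2::ggplot() +
    ggplot2::geom_histogram(data = pts,
                            ggplot2::aes(x = .data$vaf,
                                         y = ggplot2::after_stat(density)),
                            bins = 100, fill = "grey85", color = "grey70") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$vaf, y = .data$density,
                                    color = .data$cluster)) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "variant allele frequency", y = "density",
                  color = "cluster") +
    ggplot2::theme_minimal()
}

#' Scatter plot of VAFs colored by cluster
#'
#' One panel per unordered pair of samples (a single panel when D = 2).
#' Outliers, if flagged, are drawn as open triangles.
#'
#' @param fit A `vaf_fit` with D >= 2.
#' @param sample_names Optional axis labels (length D).
#' @return A ggplot object.
#' @export
plot_vaf_scatter <- function(fit, sample_names = NULL) {
  d <- ncol(fit$means)
  stopifnot(d >= 2)
  if (is.null(sample_names)) sample_names <- paste0("sample ", seq_len(d))
  pairs <- utils::combn(d, 2)
  out <- is_outlier(fit)
  dfs <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    data.frame(x = fit$data$x[, a], y = fit$data$x[, b],
               cluster = factor(ifelse(out, NA, fit$assignments)),
               outlier = out,
               panel = paste(sample_names[a], "vs", sample_names[b]))
  })
  df <- do.call(rbind, dfs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$cluster,
                                        shape = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2),
                                guide = "none") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "VAF", y = "VAF", color = "cluster") +
    ggplot2::theme_minimal()
  if (ncol(pairs) > 1) p <- p + ggplot2::facet_wrap(~panel)
  p
}

#' Write the standard plot set for a fit
#'
#' Density plot for single-sample fits, scatter panels for multi-sample
#' fits; PDF output.
#'
#' @param fit A `vaf_fit`.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_fit_plots <- function(fit, prefix) {
  files <- character(0)
  d <- ncol(fit$means)
  if (d == 1) {
    f <- paste0(prefix, ".density.pdf")
    grDevices::pdf(f, width = 7, height = 4.5)
    print(plot_vaf_density(fit))
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    f <- paste0(prefix, ".scatter.pdf")
    grDevices::pdf(f, width = if (d == 2) 6 else 9, height = 5)
    print(plot_vaf_scatter(fit))
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
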