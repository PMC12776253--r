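#' Volcano plot of a differential result
#'
#' @param object A `kme_diff` tibble.
#' @param contrast Which pairwise contrast to show (default `"6v0"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kme_diff <- function(object, contrast = "6v0", ...) {
  df <- tidy(object)
  want <- paste0("day", sub("v", "_vs_day", contrast))
  df <- df[df$contrast == want, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_padj,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = bquote(log[2] ~ "fold change (" * .(want) * ")"),
                  y = bquote(-log[10] ~ "adjusted p (ANOVA)"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Sample PCA plot
#'
#' @param object A `kme_pca` object.
#' @param design Optional [study_design()] to colour samples by day.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kme_pca <- function(object, design = NULL, ...) {
  df <- object$scores
  if (!is.null(design)) {
    df$day <- factor(design$day[match(df$sample, design$sample)])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(design)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$day), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Module eigengene profiles
#'
#' Eigengene value per sample, one panel per module, coloured by the
#' module's color label.
#'
#' @param object A `kme_modules` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kme_modules <- function(object, ...) {
  eg <- object$eigengenes
  if (nrow(eg) == 0) abort("No modules to plot.")
  samples <- object$design$sample
  long <- tidyr::pivot_longer(eg, dplyr::all_of(samples),
                              names_to = "sample", values_to = "eigengene")
  long$day <- object$design$day[match(long$sample, object$design$sample)]
  cols <- unique(eg$module)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$eigengene)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$module), alpha = 0.8) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$module,
                                       colour = .data$module),
                          fun = mean, geom = "line") +
    ggplot2::scale_colour_manual(values = stats::setNames(cols, cols)) +
    ggplot2::facet_wrap(~ module) +
    ggplot2::labs(x = "differentiation day", y = "module eigengene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' K/R-density histogram plot
#'
#' @param density Tibble from [kr_density()].
#' @return A ggplot object.
#' @export
plot_kr_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = factor(.data$n_kr),
                                        y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "additional K/R residues", y = "fraction of sites") +
    ggplot2::theme_minimal()
}
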