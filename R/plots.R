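#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot genotype PCA coordinates
#'
#' Scatter of the first two principal components, optionally colored by a
#' sample annotation (e.g. breed).
#'
#' @param object A `geno_pca` result.
#' @param annotation Optional tibble with `sample` plus one label column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, annotation = NULL, ...) {
  d <- object$scores
  if (!is.null(annotation)) {
    d <- dplyr::left_join(d, annotation, by = "sample")
    lab <- setdiff(names(annotation), "sample")[1]
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[lab]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot male/female ratio distribution
#'
#' Histogram of per-gene log2 male/female ratios with the median marked;
#' incomplete Z dosage compensation shows as a mode between 0 and 1.
#'
#' @param object A `sex_ratio` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sex_ratio
#' @export
autoplot.sex_ratio <- function(object, ...) {
  d <- object$per_gene
  ggplot2::ggplot(d, ggplot2::aes(log2(.data$mf_ratio))) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = log2(object$median_ratio),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "log2 male/female ratio", y = "genes",
                  title = sprintf("%s genes: median M/F = %.2f",
                                  object$chromosome,
                                  object$median_ratio)) +
    ggplot2::theme_minimal()
}

#' Plot LPS response as an MA-style scatter
#'
#' @param object An `lps_response` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lps_response
#' @export
autoplot.lps_response <- function(object, ...) {
  d <- object$per_gene
  ggplot2::ggplot(d, ggplot2::aes(
    x = log2((.data$mean_control + .data$mean_lps) / 2 + 0.5),
    y = .data$log2fc, colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(induced = "firebrick",
                                            repressed = "steelblue",
                                            unchanged = "grey70")) +
    ggplot2::labs(x = "log2 mean TPM", y = "log2 LPS fold change") +
    ggplot2::theme_minimal()
}

#' Plot a family contrast
#'
#' @param object A `family_contrast` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot family_contrast
#' @export
autoplot.family_contrast <- function(object, ...) {
  d <- object$table[object$table$eligible, ]
  ggplot2::ggplot(d, ggplot2::aes(log2(.data$mean_other + 0.5),
                                  log2(.data$mean_target + 0.5),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            unchanged = "grey70")) +
    ggplot2::labs(x = sprintf("log2 mean TPM, other families (n=%d)",
                              object$n_other),
                  y = sprintf("log2 mean TPM, family %s (n=%d)",
                              object$target_family, object$n_target)) +
    ggplot2::theme_minimal()
}

#' Plot cluster mean expression profiles
#'
#' Line profiles of per-cluster mean TPM across samples, faceted by
#' cluster, samples ordered by treatment when a sample sheet is given.
#'
#' @param profiles Output of [cluster_profiles()].
#' @param samples Optional sample sheet for treatment ordering/coloring.
#' @param clusters Optional subset of cluster numbers.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(profiles, samples = NULL,
                                  clusters = NULL) {
  if (!is.null(clusters)) {
    profiles <- profiles[profiles$cluster %in% clusters, ]
  }
  idc <- intersect(c("cluster", "size", "trend"), names(profiles))
  long <- tidyr::pivot_longer(profiles, -dplyr::all_of(idc),
                              names_to = "sample", values_to = "tpm")
  if (!is.null(samples)) {
    long <- dplyr::left_join(long,
                             samples[, c("sample", "treatment")],
                             by = "sample")
    long$sample <- stats::reorder(long$sample,
                                  as.integer(factor(long$treatment)))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$tpm,
                                            fill = .data$treatment))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$tpm))
  }
  p + ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample", y = "mean TPM")
}
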