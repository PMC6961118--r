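#' Phenotype-space scatter plot
#'
#' PC1 vs PC2 of the centered phenotype space with wells coloured by role,
#' the standard control-separation picture for a normalized multi-line
#' screen (negative controls concentrate at the origin, positive controls
#' displace together).
#'
#' @param centered Centered PC table from [project_and_center()] (or a
#'   `theta_run`).
#' @param colour_by Column mapped to colour, default `"role"`.
#' @return A ggplot object.
#' @export
plot_phenospace <- function(centered, colour_by = "role") {
  if (inherits(centered, "theta_run")) centered <- centered$centered
  assert_cols(centered, c("PC1", "PC2", colour_by), "centered table")
  ggplot2::ggplot(centered,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey50") +
    ggplot2::labs(x = "PC1", y = "PC2", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Divergence profile of the ranked hit list
#'
#' Mean delta-theta against final rank, a quick look at how sharply the
#' divergent pairs separate from the bulk.
#'
#' @param ranked [rank_product()] or [build_hit_list()] output (or a
#'   `theta_run`).
#' @return A ggplot object.
#' @export
plot_rank_profile <- function(ranked) {
  if (inherits(ranked, "theta_run")) ranked <- ranked$ranked
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$final_rank,
                                       y = .data$mean_delta_theta)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "final rank (increasing rank product)",
                  y = "mean Δθ (degrees)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pheno_pca <- function(object, n = 20, ...) {
  df <- head(tidy(object), n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$var_frac,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance fraction") +
    ggplot2::theme_minimal()
}
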