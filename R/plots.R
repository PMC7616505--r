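#' Forest-style plot of balance-feature associations
#'
#' Pearson r with its Fisher-z confidence interval per feature, the
#' tabular counterpart of the per-feature scatter panels.
#'
#' @param object A `homeolog_assoc` tibble
#'   (e.g. [feature_association_table()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.homeolog_assoc <- function(object, ...) {
  df <- object[object$computable %||% TRUE, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r,
                                   y = stats::reorder(.data$feature, .data$r))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$transform), size = 2) +
    ggplot2::labs(x = "Pearson r (vs average R_FPKM)", y = NULL,
                  colour = "transform") +
    ggplot2::theme_minimal()
}

#' Distribution of average R_FPKM across homeolog pairs
#'
#' The right-skewed histogram of expression divergence: most pairs show
#' biased expression while a subset stays balanced.
#'
#' @param profiles [pair_balance()] output.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_balance_distribution <- function(profiles, bins = 40) {
  ggplot2::ggplot(profiles[profiles$informative, ],
                  ggplot2::aes(x = .data$avg_rfpkm)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white",
                            boundary = 0) +
    ggplot2::labs(x = "average R_FPKM", y = "homeolog pairs") +
    ggplot2::theme_minimal()
}

#' Expression balance by GO-slim category
#'
#' Violin plot of average R_FPKM per category, ordered by median.
#'
#' @param profiles [pair_balance()] output.
#' @param pairs Pair table.
#' @param go GO-slim map (`gene`, `go_slim`).
#' @return A ggplot.
#' @export
plot_go_slim <- function(profiles, pairs, go) {
  pairs <- ensure_pair_id(pairs)
  long <- dplyr::bind_rows(
    dplyr::inner_join(pairs[c("pair_id", "copy1")], go, by = c(copy1 = "gene")),
    dplyr::inner_join(pairs[c("pair_id", "copy2")], go, by = c(copy2 = "gene"))
  ) |> dplyr::distinct(.data$pair_id, .data$go_slim)
  long$avg_rfpkm <- profiles$avg_rfpkm[match(long$pair_id, profiles$pair_id)]
  long <- long[!is.na(long$avg_rfpkm), ]
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$go_slim, .data$avg_rfpkm, FUN = median),
    y = .data$avg_rfpkm)) +
    ggplot2::geom_violin(fill = "thistle") +
    ggplot2::stat_summary(fun = median, geom = "point", colour = "red") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "average R_FPKM") +
    ggplot2::theme_minimal()
}

#' Stability of correlations under random pair deletion
#'
#' Mean correlation (+/- 1 sd) per deletion fraction and feature.
#'
#' @param robustness [robustness_by_deletion()] output.
#' @return A ggplot.
#' @export
plot_robustness <- function(robustness) {
  ggplot2::ggplot(robustness,
                  ggplot2::aes(x = .data$deletion_fraction, y = .data$r_mean,
                               colour = .data$feature)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r_mean - .data$r_sd,
                                      ymax = .data$r_mean + .data$r_sd,
                                      fill = .data$feature),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "deletion fraction", y = "mean Pearson r") +
    ggplot2::theme_minimal()
}
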