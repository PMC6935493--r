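# ggplot2 views of the benchmark tables.

#' Plot true-positive rate against mapping percentage
#'
#' One point per evaluated configuration, the standard benchmarking view:
#' top-right is best; random/multi reporting pushes mapping up while
#' hit-weighting pulls the TP rate down for over-reporters.
#'
#' @param metrics A tibble with `mapping_pct`, `tp_rate` and optionally
#'   `mode` (colour) and `library` (shape), e.g. `run_demo()$metrics`.
#' @return A ggplot object.
#' @export
plot_tp_vs_mapping <- function(metrics) {
  aes_args <- list(x = rlang::sym("mapping_pct"), y = rlang::sym("tp_rate"))
  if ("mode" %in% names(metrics)) aes_args$colour <- rlang::sym("mode")
  if ("library" %in% names(metrics)) aes_args$shape <- rlang::sym("library")
  ggplot2::ggplot(metrics, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Mapping percentage", y = "True-positive rate (%)") +
    ggplot2::theme_minimal()
}

#' Plot per-family mapping percentage
#'
#' @param family_tbl Output of [family_metrics()].
#' @return A ggplot object (bars ordered by mapping percentage).
#' @export
plot_family_mappability <- function(family_tbl) {
  ggplot2::ggplot(family_tbl,
                  ggplot2::aes(x = stats::reorder(.data$scope,
                                                  .data$mapping_pct),
                               y = .data$mapping_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mapping percentage (unique mode)") +
    ggplot2::theme_minimal()
}

#' Estimated versus true abundance scatter
#'
#' @param object A `te_abundance_comparison` from [compare_abundance()].
#' @param ... Unused.
#' @return A ggplot object with the identity line and the R^2 in the title.
#' @export
autoplot.te_abundance_comparison <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("%s counting: R² = %.4f", object$mode,
                      object$r_squared),
      x = "True abundance (fragments)", y = "Estimated abundance"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
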