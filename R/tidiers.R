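#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GA/KNN evaluation
#'
#' One row per sample with its class, averaged training and testing
#' accuracies and appearance counts.
#'
#' @param x A `gaknn_eval` from [run_gaknn_evaluation()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gaknn_eval <- function(x, ...) {
  dplyr::mutate(x$sample_accuracy,
                class = unname(x$labels[.data$sample_id]),
                .after = "sample_id")
}

#' One-row summary of a GA/KNN evaluation
#'
#' @param x A `gaknn_eval`.
#' @param ... Unused.
#' @return Tibble with overall mean/median train and test accuracy, the
#'   number of partitions and feature sets, and the fraction of GA runs
#'   that reached the fitness threshold.
#' @export
glance.gaknn_eval <- function(x, ...) {
  ov <- dplyr::filter(x$summary, .data$group == "Overall")
  tibble::tibble(
    mean_train_accuracy = ov$mean[ov$role == "train"],
    median_train_accuracy = ov$median[ov$role == "train"],
    mean_test_accuracy = ov$mean[ov$role == "test"],
    median_test_accuracy = ov$median[ov$role == "test"],
    n_partitions = nrow(x$partitions),
    n_sets = nrow(x$sets),
    frac_threshold_runs = mean(x$sets$stop_reason == "threshold")
  )
}

#' Plot per-sample accuracy distributions
#'
#' Boxplots of per-sample training and testing accuracy by class,
#' visualising the training-bias gap between roles.
#'
#' @param object A `gaknn_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaknn_eval <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("train_accuracy", "test_accuracy"),
                        names_to = "role", values_to = "accuracy") |>
    dplyr::mutate(role = factor(sub("_accuracy$", "", .data$role),
                                levels = c("train", "test"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$class, y = .data$accuracy,
                                 fill = .data$role)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "sample class", y = "per-sample accuracy",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot gene selection frequencies
#'
#' Bar chart of how often the top-ranked genes were selected across all
#' collected feature sets.
#'
#' @param x A `gaknn_eval` or a gene-frequency tibble from
#'   [rank_genes_by_frequency()].
#' @param top_n Number of genes to show.
#' @return A ggplot.
#' @export
plot_gene_frequency <- function(x, top_n = 20) {
  tbl <- if (inherits(x, "gaknn_eval")) x$gene_frequency else x
  tbl |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(gene_id = stats::reorder(.data$gene_id, .data$count)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$count, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "selection count across feature sets", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an anchor co-expression table
#'
#' Pooled Spearman correlation of the strongest positively and negatively
#' correlated genes with the anchor.
#'
#' @param object An `anchor_cor` table from [correlate_anchor()].
#' @param top_n Genes to show from each tail.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.anchor_cor <- function(object, top_n = 10, ...) {
  anchor <- attr(object, "anchor")
  tbl <- object |>
    dplyr::filter(.data$gene_id != anchor, !is.na(.data$r_pooled)) |>
    dplyr::arrange(dplyr::desc(.data$r_pooled))
  shown <- dplyr::bind_rows(utils::head(tbl, top_n), utils::tail(tbl, top_n)) |>
    dplyr::distinct() |>
    dplyr::mutate(gene_id = stats::reorder(.data$gene_id, .data$r_pooled))
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$r_pooled, y = .data$gene_id,
                                      fill = .data$r_pooled > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = paste("Spearman r with", anchor), y = NULL) +
    ggplot2::theme_minimal()
}
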