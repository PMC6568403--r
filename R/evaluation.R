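#' Random stratified train/test partitions
#'
#' Draws `n_partitions` independent splits of the samples into a training
#' fraction (default 75%) and a held-out test fraction. Splits are
#' stratified by class, each class rounded half-up, so the class balance
#' of the cohort is preserved in every fold; `stratify = FALSE` gives the
#' unstratified split of the whole cohort instead.
#'
#' @param labels Named character vector, sample id -> class.
#' @param n_partitions Number of independent partitions (e.g. 100).
#' @param train_fraction Fraction of samples assigned to training.
#' @param seed RNG seed.
#' @param stratify Stratify by class (default `TRUE`).
#' @return Tibble with one row per partition: `partition_id`, list-columns
#'   `train_ids` and `test_ids`, and `seed`.
#' @export
make_partitions <- function(labels, n_partitions, train_fraction = 0.75,
                            seed = 1L, stratify = TRUE) {
  stopifnot(!is.null(names(labels)), length(labels) >= 8,
            train_fraction > 0, train_fraction < 1, n_partitions >= 1)
  classes <- split(names(labels), labels)
  if (any(lengths(classes) < 2)) {
    stop("every class needs >= 2 samples to partition")
  }
  round_half_up <- function(x) floor(x + 0.5)
  withr_seed(seed, {
    purrr::map_dfr(seq_len(n_partitions), function(p) {
      train <- if (stratify) {
        unlist(lapply(classes, function(ids) {
          sample(ids, round_half_up(train_fraction * length(ids)))
        }), use.names = FALSE)
      } else {
        sample(names(labels), round_half_up(train_fraction * length(labels)))
      }
      tibble::tibble(partition_id = p,
                     train_ids = list(sort(train)),
                     test_ids = list(sort(setdiff(names(labels), train))),
                     seed = as.integer(seed))
    })
  })
}

#' Per-sample correctness fractions for one partition
#'
#' Scores every sample of the cohort against a collection of feature sets:
#' training samples by leave-one-out cross-validation within the training
#' fold, test samples by KNN against the full training fold. Returns, for
#' each sample, the fraction of feature sets that classified it correctly
#' — the quantity averaged over partitions by [aggregate_accuracy()].
#'
#' @param sets Feature-set tibble from [collect_feature_sets()] (needs the
#'   `genes` list-column).
#' @param matrix An [expr_matrix] with two-class labels covering all
#'   partition samples.
#' @param partition One row of [make_partitions()] output (or a list with
#'   `train_ids`/`test_ids`).
#' @param k KNN neighbours.
#' @param standardize Standardise genes by training-fold statistics.
#' @return Tibble: `sample_id`, `role` ("train"/"test"), `fraction_correct`.
#' @export
classify_with_sets <- function(sets, matrix, partition, k = 5L,
                               standardize = TRUE) {
  train_ids <- unlist(partition$train_ids)
  test_ids <- unlist(partition$test_ids)
  stopifnot(length(train_ids) > 0, length(test_ids) > 0)
  all_genes <- unique(unlist(sets$genes))
  missing <- setdiff(all_genes, gene_ids(matrix))
  if (length(missing) > 0) {
    stop("feature-set gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  lv <- classification_labels(matrix)
  y_train <- as.integer(match(matrix$labels[train_ids], lv) - 1L)
  y_test <- as.integer(match(matrix$labels[test_ids], lv) - 1L)
  Vtr <- matrix$values[, train_ids, drop = FALSE]
  Vte <- matrix$values[, test_ids, drop = FALSE]

  n_sets <- nrow(sets)
  correct_train <- numeric(length(train_ids))
  correct_test <- numeric(length(test_ids))
  for (s in seq_len(n_sets)) {
    g <- sets$genes[[s]]
    Xtr <- Vtr[g, , drop = FALSE]
    pred_tr <- loocv_predict_cpp(Xtr, y_train, as.integer(k), standardize)
    correct_train <- correct_train + (pred_tr == y_train)
    pred_te <- knn_predict_cpp(Xtr, y_train, Vte[g, , drop = FALSE],
                               as.integer(k), standardize)
    correct_test <- correct_test + (pred_te == y_test)
  }
  dplyr::bind_rows(
    tibble::tibble(sample_id = train_ids, role = "train",
                   fraction_correct = correct_train / n_sets),
    tibble::tibble(sample_id = test_ids, role = "test",
                   fraction_correct = correct_test / n_sets)
  )
}

#' Average per-sample accuracy over partitions
#'
#' With 100 partitions at a 75% training fraction, each sample lands in
#' training ~75 times and in testing ~25 times; its overall training and
#' testing accuracies are the arithmetic means of its per-partition
#' correctness fractions in each role.
#'
#' @param fractions Row-bound output of [classify_with_sets()] over all
#'   partitions.
#' @return Tibble: `sample_id`, `train_accuracy`, `test_accuracy`,
#'   `n_train_appearances`, `n_test_appearances`. A role never observed for
#'   a sample yields `NA` with a zero count.
#' @export
aggregate_accuracy <- function(fractions) {
  wide <- fractions |>
    dplyr::group_by(.data$sample_id, .data$role) |>
    dplyr::summarise(accuracy = mean(.data$fraction_correct),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("accuracy", "n"),
                       values_fill = list(n = 0L))
  for (col in c("accuracy_train", "accuracy_test", "n_train", "n_test")) {
    if (!col %in% names(wide)) {
      wide[[col]] <- if (startsWith(col, "n_")) 0L else NA_real_
    }
  }
  tibble::tibble(sample_id = wide$sample_id,
                 train_accuracy = wide$accuracy_train,
                 test_accuracy = wide$accuracy_test,
                 n_train_appearances = wide$n_train,
                 n_test_appearances = wide$n_test)
}

#' Six-number summary of per-sample accuracies
#'
#' Min, first quartile, median, mean, third quartile and max of the
#' per-sample accuracies, per class and overall, for the training and
#' testing roles — the layout of a classification-performance summary
#' table. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param accuracies Output of [aggregate_accuracy()].
#' @param labels Named character vector, sample id -> class.
#' @return Tibble: `role`, `group` (class name or "Overall"), `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`.
#' @export
summarize_accuracy <- function(accuracies, labels) {
  stopifnot(nrow(accuracies) > 0)
  six <- function(v) {
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(min = min(v), q1 = q[1], median = q[2], mean = mean(v),
                   q3 = q[3], max = max(v))
  }
  long <- accuracies |>
    dplyr::mutate(group = unname(labels[.data$sample_id])) |>
    tidyr::pivot_longer(c("train_accuracy", "test_accuracy"),
                        names_to = "role", values_to = "accuracy") |>
    dplyr::mutate(role = sub("_accuracy$", "", .data$role))
  per_group <- long |>
    dplyr::group_by(.data$role, .data$group) |>
    dplyr::reframe(six(.data$accuracy))
  overall <- long |>
    dplyr::group_by(.data$role) |>
    dplyr::reframe(six(.data$accuracy)) |>
    dplyr::mutate(group = "Overall", .after = "role")
  dplyr::bind_rows(per_group, overall) |>
    dplyr::arrange(dplyr::desc(.data$role == "train"))
}

#' Gene selection-frequency ranking
#'
#' Counts how often each gene appears across all collected feature sets
#' (over all partitions) and ranks genes by descending count; the most
#' frequently selected genes are the signature candidates. Count ties
#' break lexicographically by gene id.
#'
#' @param sets Feature-set tibble (rows from one or many
#'   [collect_feature_sets()] calls, row-bound).
#' @return Tibble: `gene_id`, `count`, `rank`.
#' @export
rank_genes_by_frequency <- function(sets) {
  stopifnot(nrow(sets) > 0)
  tibble::tibble(gene_id = unlist(sets$genes)) |>
    dplyr::count(.data$gene_id, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Run the full GA/KNN resampled evaluation
#'
#' The end-to-end pipeline: draw random stratified 75/25 partitions, run
#' the GA on each training fold to collect near-optimal feature sets,
#' score every sample with every set (training by LOOCV, testing held
#' out), aggregate per-sample accuracies across partitions, and rank genes
#' by selection frequency.
#'
#' @param matrix An [expr_matrix] (log2 scale) with two-class labels.
#' @param config A [ga_config()]; `config$n_sets` feature sets are
#'   collected in total, split evenly across partitions.
#' @param n_partitions Number of random partitions.
#' @param train_fraction Training fraction per partition.
#' @param seed Master seed for partitions and GA substreams.
#' @return A `gaknn_eval` object: list with `sample_accuracy`, `summary`,
#'   `gene_frequency`, `sets`, `partitions`, `config`, `labels`. Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_gaknn_evaluation <- function(matrix, config = desk_config(),
                                 n_partitions = 4L, train_fraction = 0.75,
                                 seed = config$seed) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(config, "ga_config"))
  sets_per_partition <- max(1L, config$n_sets %/% n_partitions)
  partitions <- make_partitions(matrix$labels, n_partitions,
                                train_fraction = train_fraction, seed = seed)
  part_seeds <- withr_seed(seed + 1L,
                           sample.int(.Machine$integer.max, n_partitions))
  all_sets <- list()
  all_fracs <- list()
  for (p in seq_len(n_partitions)) {
    part <- partitions[p, ]
    train_ids <- part$train_ids[[1]]
    train <- expr_matrix(matrix$values[, train_ids, drop = FALSE],
                         labels = matrix$labels[train_ids],
                         transformed = matrix$transformed)
    cfg_p <- config
    cfg_p$seed <- part_seeds[p]
    sets <- collect_feature_sets(train, cfg_p, n_sets = sets_per_partition)
    sets$partition_id <- p
    all_sets[[p]] <- sets
    fr <- classify_with_sets(sets, matrix, part, k = config$k,
                             standardize = config$standardize)
    fr$partition_id <- p
    all_fracs[[p]] <- fr
  }
  sets <- dplyr::bind_rows(all_sets)
  fractions <- dplyr::bind_rows(all_fracs)
  accuracy <- aggregate_accuracy(fractions)
  structure(
    list(sample_accuracy = accuracy,
         summary = summarize_accuracy(accuracy, matrix$labels),
         gene_frequency = rank_genes_by_frequency(sets),
         sets = sets, partitions = partitions, fractions = fractions,
         config = config, labels = matrix$labels),
    class = "gaknn_eval"
  )
}

#' @export
print.gaknn_eval <- function(x, ...) {
  ov <- dplyr::filter(x$summary, .data$group == "Overall")
  cat("<gaknn_eval> ", nrow(x$partitions), " partitions, ", nrow(x$sets),
      " feature sets (L=", x$config$chromosome_length, ")\n", sep = "")
  cat(sprintf("  mean accuracy: train %.3f, test %.3f\n",
              ov$mean[ov$role == "train"], ov$mean[ov$role == "test"]))
  cat("  top genes: ",
      paste(utils::head(x$gene_frequency$gene_id, 5), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
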