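#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (midranks for ties).
#' Returns `NA` with a warning if either vector is constant, where the
#' coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` for a constant input.
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Anchor-gene co-expression table
#'
#' Spearman correlation between a designated anchor gene and every other
#' gene, pooled over all samples and (optionally) within sample groups
#' such as tumour tissue sites. The `average_r` column is the unweighted
#' mean of the per-group coefficients.
#'
#' @param matrix An [expr_matrix] (log2 scale).
#' @param anchor Anchor gene id (must be present).
#' @param groups Optional named character vector, sample id -> group; each
#'   group needs >= 3 samples.
#' @return An `anchor_cor` tibble: `gene_id`, one `r_<group>` column per
#'   group, `r_pooled`, and `average_r` when groups are given. The anchor
#'   row is included (pooled r = 1) so the table is complete; selection
#'   helpers exclude it.
#' @export
correlate_anchor <- function(matrix, anchor, groups = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!anchor %in% gene_ids(matrix)) {
    stop("anchor gene '", anchor, "' not found in the matrix")
  }
  V <- matrix$values
  anchor_v <- V[anchor, ]
  r_against_anchor <- function(cols) {
    a_rank <- rank(anchor_v[cols])
    if (stats::sd(a_rank) == 0) return(rep(NA_real_, nrow(V)))
    gene_ranks <- apply(V[, cols, drop = FALSE], 1, rank)  # samples x genes
    as.vector(suppressWarnings(
      stats::cor(gene_ranks, a_rank, method = "pearson")
    ))
  }
  out <- tibble::tibble(gene_id = gene_ids(matrix))
  if (!is.null(groups)) {
    stopifnot(!is.null(names(groups)))
    groups <- groups[sample_ids(matrix)]
    gl <- split(sample_ids(matrix), groups)
    if (any(lengths(gl) < 3)) stop("every group needs >= 3 samples")
    for (g in names(gl)) out[[paste0("r_", g)]] <- r_against_anchor(gl[[g]])
    out$average_r <- rowMeans(out[, paste0("r_", names(gl)), drop = FALSE])
  }
  out$r_pooled <- r_against_anchor(sample_ids(matrix))
  structure(dplyr::relocate(out, "r_pooled", .after = "gene_id"),
            class = c("anchor_cor", class(out)),
            anchor = anchor)
}

#' Select strongly correlated genes by threshold
#'
#' Positive list: pooled Spearman r at or above `r_min`; negative list: at
#' or below `r_max`. The anchor gene itself is always excluded.
#'
#' @param table An `anchor_cor` table from [correlate_anchor()].
#' @param r_min Positive threshold (default 0.5).
#' @param r_max Negative threshold (default -0.5).
#' @return List with character vectors `positive` and `negative`, each
#'   ordered by decreasing |r|.
#' @export
select_by_threshold <- function(table, r_min = 0.5, r_max = -0.5) {
  stopifnot(r_max <= 0, r_min >= 0)
  anchor <- attr(table, "anchor")
  tbl <- dplyr::filter(table, .data$gene_id != anchor,
                       !is.na(.data$r_pooled))
  pos <- dplyr::arrange(dplyr::filter(tbl, .data$r_pooled >= r_min),
                        dplyr::desc(.data$r_pooled))
  neg <- dplyr::arrange(dplyr::filter(tbl, .data$r_pooled <= r_max),
                        .data$r_pooled)
  list(positive = pos$gene_id, negative = neg$gene_id)
}

#' Welch two-sample t test
#'
#' Two-sided t test with unequal variances (Welch-Satterthwaite degrees of
#' freedom), e.g. for comparing a gene's expression between tissue-site
#' groups. A pooled-variance test is available via `var_equal = TRUE`.
#'
#' @param x,y Numeric vectors, each length >= 2.
#' @param var_equal Assume equal variances (default `FALSE`, Welch).
#' @return One-row tibble: `statistic` (t), `df`, `p_value`,
#'   `mean_x`, `mean_y`.
#' @export
two_sample_ttest <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 observations")
  }
  ht <- stats::t.test(x, y, alternative = "two.sided",
                      var.equal = var_equal)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}

#' Aggregate anchor-correlation ranks across datasets
#'
#' Within each dataset, genes are ranked by descending pooled correlation
#' with the anchor; the aggregate score is the geometric mean of a gene's
#' per-dataset ranks (the rank product, normalised by the D-th root), a
#' robust parameter-free way to combine discordant lists. Only genes
#' present in every dataset are aggregated; the number dropped is
#' reported via a message. `method = "median"` uses the median rank
#' instead.
#'
#' @param tables List of `anchor_cor` tables (one per dataset, e.g. per
#'   tumour type); length >= 2.
#' @param method "geometric" (rank product, default) or "median".
#' @return Tibble: `gene_id`, `rank_1` ... `rank_D`, `score`,
#'   `overall_rank` (ascending score, ties broken lexicographically).
#' @export
aggregate_ranks <- function(tables, method = c("geometric", "median")) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 2)
  common <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  if (length(common) == 0) stop("no gene is present in every dataset")
  n_dropped <- length(unique(unlist(lapply(tables, `[[`, "gene_id")))) -
    length(common)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) absent from >=1 dataset were dropped")
  }
  ranks <- matrix(vapply(tables, function(t) {
    r <- t$r_pooled[match(common, t$gene_id)]
    rank(-r, ties.method = "average")
  }, numeric(length(common))), nrow = length(common))
  score <- if (method == "geometric") {
    exp(rowMeans(log(ranks)))
  } else {
    apply(ranks, 1, stats::median)
  }
  out <- tibble::as_tibble(ranks, .name_repair = ~ paste0("rank_",
                                                          seq_along(.x)))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = common), out)
  out$score <- score
  out |>
    dplyr::arrange(.data$score, .data$gene_id) |>
    dplyr::mutate(overall_rank = dplyr::row_number())
}
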