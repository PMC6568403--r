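#' Construct an expression matrix container
#'
#' Bundles a genes-by-samples numeric matrix with a per-sample class label
#' and a flag recording whether the log2 floor transform has been applied.
#' Downstream classification (GA/KNN, evaluation) requires exactly two
#' distinct labels; correlation analyses accept any number of groups.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param labels Named character vector mapping sample id to class label.
#'   Samples without a label are dropped with a warning.
#' @param transformed Logical; `TRUE` if `values` are already on the log2
#'   floor-transformed scale.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, labels = NULL, transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (!is.null(labels)) {
    if (is.null(names(labels))) stop("`labels` must be named by sample id")
    missing_lab <- setdiff(sample_ids, names(labels))
    if (length(missing_lab) > 0) {
      warning(length(missing_lab), " sample(s) absent from the label map ",
              "were dropped: ", paste(missing_lab, collapse = ", "))
      values <- values[, setdiff(sample_ids, missing_lab), drop = FALSE]
      sample_ids <- colnames(values)
    }
    labels <- as.character(labels[sample_ids])
    names(labels) <- sample_ids
  }
  structure(
    list(values = values, labels = labels, transformed = isTRUE(transformed)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples; log2-transformed: ", x$transformed, "\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Log2 transform with a floor at 1
#'
#' Normalised read counts below 1 are raised to 1 before taking log2, so
#' the transformed scale is non-negative and zero counts map to 0. No
#' further normalisation is applied. An `expr_matrix` records its
#' transformed state and refuses a second application.
#'
#' @param x Numeric matrix/vector of non-negative values, or an
#'   `expr_matrix` holding raw counts.
#' @return Same shape as the input, on the log2 scale.
#' @examples
#' log2_floor_transform(c(0.5, 1, 1024))  # 0, 0, 10
#' @export
log2_floor_transform <- function(x) {
  if (inherits(x, "expr_matrix")) {
    if (x$transformed) stop("expression matrix is already log2-transformed")
    x$values <- log2_floor_transform(x$values)
    x$transformed <- TRUE
    return(x)
  }
  if (any(x < 0)) stop("negative expression values are not allowed")
  log2(pmax(x, 1))
}

#' Read an expression matrix and its sample labels from TSV files
#'
#' The expression file is tab-separated with a header row of sample ids and
#' gene ids in the first column (TCGA level-3 style). The label file has
#' two columns, sample id and class, without a header. Samples missing from
#' the label file are dropped with a warning; duplicate ids and non-numeric
#' cells are hard errors.
#'
#' @param path Expression TSV path.
#' @param label_path Optional labels TSV path.
#' @param transformed Whether the stored values are already log2
#'   floor-transformed (default `FALSE`, i.e. raw normalised counts).
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, label_path = NULL, transformed = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(tab) < 2) stop("expression TSV needs a gene id column and >=1 sample")
  genes <- tab[[1]]
  samples <- colnames(tab)[-1]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-numeric value at gene '", genes[bad[1]], "', sample '",
         samples[bad[2]], "'")
  }
  rownames(num) <- genes
  colnames(num) <- samples
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- readr::read_tsv(label_path, col_names = c("sample_id", "class"),
                           col_types = "cc", progress = FALSE)
    labels <- stats::setNames(lab$class, lab$sample_id)
  }
  expr_matrix(num, labels = labels, transformed = transformed)
}

#' Write an expression matrix (and labels) to TSV
#'
#' Inverse of [read_expression_tsv()]: values are written at full precision
#' so a write/read round trip reproduces the matrix exactly.
#'
#' @param x An `expr_matrix`.
#' @param path Output expression TSV path.
#' @param label_path Optional output path for the two-column label TSV.
#' @return `x`, invisibly.
#' @export
write_expression_tsv <- function(x, path, label_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- tibble::as_tibble(x$values, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids(x)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(label_path)) {
    if (is.null(x$labels)) stop("no labels to write")
    readr::write_tsv(
      tibble::tibble(sample_id = names(x$labels), class = unname(x$labels)),
      label_path, col_names = FALSE, progress = FALSE
    )
  }
  invisible(x)
}

# two-class label bookkeeping used by gaknn/evaluation
classification_labels <- function(x) {
  if (is.null(x$labels)) stop("expression matrix has no sample labels")
  lv <- sort(unique(x$labels))
  if (length(lv) != 2) {
    stop("classification requires exactly two classes, found ",
         length(lv), ": ", paste(lv, collapse = ", "))
  }
  lv
}
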