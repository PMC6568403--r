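# Independent brute-force oracles: plain-R implementations that share no
# code with the package's Rcpp/vectorised paths.

# expression container from a plain matrix of values
toy_expr <- function(values, labels) {
  expr_matrix(values, labels = labels, transformed = TRUE)
}

# one-gene-per-row matrix builder with automatic ids
toy_matrix <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive KNN: full distance vector, explicit order(), majority count
oracle_knn_predict <- function(X, y, query, k, standardize = TRUE,
                               exclude = NULL) {
  cols <- setdiff(seq_len(ncol(X)), exclude)
  Xs <- X[, cols, drop = FALSE]
  ys <- y[cols]
  sds <- apply(Xs, 1, stats::sd)
  if (!standardize) sds[] <- 1
  sds[sds == 0] <- Inf  # zero-variance gene carries no distance
  d <- vapply(seq_len(ncol(Xs)), function(j) {
    sum(((query - Xs[, j]) / sds)^2)
  }, numeric(1))
  ord <- order(d, cols)  # ties by ascending original sample index
  votes <- ys[ord[seq_len(k)]]
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1) return(ys[ord[1]])
  winners
}

oracle_loocv_fitness <- function(X, y, k, standardize = TRUE) {
  preds <- vapply(seq_len(ncol(X)), function(i) {
    oracle_knn_predict(X, y, X[, i], k, standardize = standardize,
                       exclude = i)
  }, character(1))
  mean(preds == y)
}

# brute-force seed-site enumerator: builds every window explicitly and
# classifies all pairs with pair_class()
oracle_scan <- function(target, spec) {
  target <- chartr("Tt", "UU", toupper(target))
  sl <- spec$seed_length
  seed_nt <- strsplit(substr(spec$mirna_sequence, spec$seed_offset,
                             spec$seed_offset + sl - 1), "")[[1]]
  n <- nchar(target)
  hits <- list()
  for (s in seq_len(n - sl + 1)) {
    win <- strsplit(substr(target, s, s + sl - 1), "")[[1]]
    # window position sl-j+1 pairs seed position j, so the reversed
    # window aligns with the seed elementwise
    cls <- pair_class(rev(win), seed_nt)
    n_wc <- sum(cls == "WC")
    n_gu <- sum(cls == "GU")
    if (n_wc + min(n_gu, spec$max_gu) >= spec$min_complementary) {
      hits[[length(hits) + 1]] <- data.frame(
        start = s - 1L, end = s - 1L + sl,
        n_wc = n_wc, n_gu = n_gu, n_mismatch = sl - n_wc - n_gu
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(), n_wc = integer(),
                      n_gu = integer(), n_mismatch = integer()))
  }
  do.call(rbind, hits)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
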