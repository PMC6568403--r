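#' GA/KNN configuration
#'
#' Parameters for the genetic-algorithm feature-set search scored by
#' leave-one-out cross-validated KNN accuracy. The defaults are the
#' full-scale settings (20-gene chromosomes, population 300, up to 1000
#' generations, k = 5, 5000 collected sets); [desk_config()] gives a small
#' configuration suitable for simulation studies on a laptop.
#'
#' @param chromosome_length Genes per feature set (L).
#' @param population_size GA population size (P).
#' @param max_generations Generation cap per run.
#' @param k KNN neighbours; must be odd.
#' @param n_sets Near-optimal feature sets to collect.
#' @param fitness_threshold LOOCV accuracy at which a run stops and its
#'   best chromosome is declared near-optimal; runs hitting the generation
#'   cap return their best-so-far and record that the cap fired.
#' @param mutation_rate Per-slot probability of mutating to a random
#'   unused gene.
#' @param crossover_rate Probability that a child is produced by uniform
#'   crossover rather than cloning.
#' @param elitism_count Top chromosomes copied unchanged each generation.
#' @param standardize Standardise each gene by training-fold mean/SD
#'   before computing Euclidean distances.
#' @param seed Master RNG seed; each GA run uses an independent substream.
#' @return A `ga_config` object (validated list).
#' @export
ga_config <- function(chromosome_length = 20L, population_size = 300L,
                      max_generations = 1000L, k = 5L, n_sets = 5000L,
                      fitness_threshold = 0.95, mutation_rate = 0.05,
                      crossover_rate = 0.9, elitism_count = 2L,
                      standardize = TRUE, seed = 1L) {
  cfg <- list(chromosome_length = as.integer(chromosome_length),
              population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              k = as.integer(k), n_sets = as.integer(n_sets),
              fitness_threshold = fitness_threshold,
              mutation_rate = mutation_rate,
              crossover_rate = crossover_rate,
              elitism_count = as.integer(elitism_count),
              standardize = isTRUE(standardize), seed = as.integer(seed))
  stopifnot(cfg$chromosome_length >= 1, cfg$population_size >= 2,
            cfg$max_generations >= 0, cfg$k >= 1, cfg$k %% 2 == 1,
            cfg$n_sets >= 0,
            cfg$fitness_threshold >= 0, cfg$fitness_threshold <= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
            cfg$elitism_count >= 0)
  structure(cfg, class = "ga_config")
}

#' @rdname ga_config
#' @param ... Overrides passed to [ga_config()].
#' @export
desk_config <- function(...) {
  defaults <- list(chromosome_length = 5L, population_size = 50L,
                   max_generations = 20L, k = 5L, n_sets = 200L,
                   fitness_threshold = 0.9)
  do.call(ga_config, utils::modifyList(defaults, list(...)))
}

#' Read a GA/KNN configuration from YAML
#'
#' Shipped configurations: `system.file("config", "paper.yaml", package =
#' "metasig")` (full scale) and `"desk.yaml"` (simulation scale).
#'
#' @param path YAML file whose keys mirror [ga_config()] arguments.
#' @return A `ga_config`.
#' @export
read_ga_config <- function(path) {
  do.call(ga_config, yaml::read_yaml(path))
}

#' @export
print.ga_config <- function(x, ...) {
  cat("<ga_config> L=", x$chromosome_length, " P=", x$population_size,
      " gens<=", x$max_generations, " k=", x$k, " n_sets=", x$n_sets,
      " threshold=", x$fitness_threshold, "\n", sep = "")
  invisible(x)
}

# internal: labels as 0/1 integers in sorted-level order
label_codes <- function(x) {
  lv <- classification_labels(x)
  list(codes = as.integer(match(x$labels, lv) - 1L), levels = lv)
}

#' KNN class prediction for query profiles
#'
#' Euclidean distance over the selected genes, each gene standardised by
#' its training mean/SD (zero-variance genes are ignored); the k nearest
#' training samples vote and the majority label wins. Distance ties break
#' by ascending training-sample index; vote ties (impossible for two
#' classes with odd k) fall back to the nearest neighbour's label.
#'
#' @param train An [expr_matrix] with two-class labels, restricted (or
#'   restrictable via `genes`) to the feature set.
#' @param query Numeric vector (one profile) or matrix (genes x queries)
#'   on the same gene order as `genes`.
#' @param k Number of neighbours.
#' @param genes Gene ids to use (default: all genes of `train`).
#' @param standardize Standardise per gene before computing distances.
#' @return Character vector of predicted class labels.
#' @export
knn_predict <- function(train, query, k = 5L, genes = gene_ids(train),
                        standardize = TRUE) {
  X <- train_submatrix(train, genes)
  lab <- label_codes(train)
  if (k > ncol(X)) stop("k (", k, ") exceeds the number of training samples")
  Q <- if (is.matrix(query)) query else matrix(query, ncol = 1)
  if (nrow(Q) != nrow(X)) stop("query length must equal the number of genes")
  pred <- knn_predict_cpp(X, lab$codes, Q, as.integer(k), standardize)
  lab$levels[pred + 1L]
}

#' Leave-one-out cross-validated KNN accuracy of a gene set
#'
#' Each training sample is predicted from all others; standardisation
#' statistics are recomputed excluding the held-out sample. This is the GA
#' fitness function.
#'
#' @inheritParams knn_predict
#' @param genes Gene ids forming the feature set.
#' @return Fraction of samples classified correctly, in \[0, 1\].
#' @export
loocv_fitness <- function(train, genes, k = 5L, standardize = TRUE) {
  X <- train_submatrix(train, genes)
  lab <- label_codes(train)
  if (k > ncol(X) - 1) {
    stop("k (", k, ") exceeds the number of leave-one-out neighbours")
  }
  loocv_accuracy_cpp(X, lab$codes, as.integer(k), standardize)
}

train_submatrix <- function(train, genes) {
  stopifnot(inherits(train, "expr_matrix"))
  missing <- setdiff(genes, gene_ids(train))
  if (length(missing) > 0) {
    stop("gene(s) not in the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  train$values[genes, , drop = FALSE]
}

#' Evolve one near-optimal feature set
#'
#' One GA run: the population starts as random L-subsets of the gene
#' universe; each generation keeps the elites, selects parents with
#' rank-proportional probability, recombines by uniform gene exchange with
#' duplicate repair, and mutates slots to random unused genes. The run
#' stops at the first chromosome whose LOOCV fitness reaches the
#' threshold, or at the generation cap with the best chromosome found.
#'
#' @param train An [expr_matrix] with two-class labels.
#' @param config A [ga_config()].
#' @param run_seed RNG seed for this run (derive substreams via
#'   [collect_feature_sets()] for multi-run reproducibility).
#' @param run_index Recorded in the result.
#' @return One-row tibble: `genes` (list-column, sorted gene ids),
#'   `fitness`, `generation_found`, `run_index`, `stop_reason`
#'   ("threshold" or "generation_cap").
#' @export
evolve_one <- function(train, config, run_seed = config$seed,
                       run_index = 1L) {
  stopifnot(inherits(config, "ga_config"))
  universe <- gene_ids(train)
  G <- length(universe)
  L <- config$chromosome_length
  if (G < L) stop("gene universe (", G, ") smaller than chromosome length")
  lab <- label_codes(train)
  V <- train$values
  k <- as.integer(config$k)
  std <- config$standardize

  withr_seed(run_seed, {
    if (G == L) {
      idx <- matrix(seq_len(G), nrow = 1)
      f <- loocv_accuracy_batch_cpp(V, idx, lab$codes, k, std)
      return(feature_set_row(universe[idx[1, ]], f, 0L, run_index,
                             "threshold"))
    }
    P <- config$population_size
    pop <- t(vapply(seq_len(P), function(i) sample.int(G, L), integer(L)))
    for (gen in 0:config$max_generations) {
      fit <- loocv_accuracy_batch_cpp(V, pop, lab$codes, k, std)
      best <- which.max(fit)
      if (fit[best] >= config$fitness_threshold) {
        return(feature_set_row(universe[pop[best, ]], fit[best], gen,
                               run_index, "threshold"))
      }
      if (gen == config$max_generations) {
        return(feature_set_row(universe[pop[best, ]], fit[best], gen,
                               run_index, "generation_cap"))
      }
      ord <- order(fit, decreasing = TRUE)
      elites <- pop[ord[seq_len(min(config$elitism_count, P))], ,
                    drop = FALSE]
      # rank-proportional selection: best rank P, worst rank 1
      rank_w <- numeric(P)
      rank_w[ord] <- P:1
      n_children <- P - nrow(elites)
      pa <- sample.int(P, n_children, replace = TRUE, prob = rank_w)
      pb <- sample.int(P, n_children, replace = TRUE, prob = rank_w)
      children <- matrix(0L, nrow = n_children, ncol = L)
      do_cross <- stats::runif(n_children) < config$crossover_rate
      for (c_i in seq_len(n_children)) {
        child <- if (do_cross[c_i]) {
          take_a <- stats::runif(L) < 0.5
          ifelse(take_a, pop[pa[c_i], ], pop[pb[c_i], ])
        } else pop[pa[c_i], ]
        mut <- stats::runif(L) < config$mutation_rate
        if (any(mut)) child[mut] <- sample.int(G, sum(mut))
        dup <- duplicated(child)
        if (any(dup)) {
          unused <- setdiff(seq_len(G), child)
          child[dup] <- sample(unused, sum(dup))
        }
        children[c_i, ] <- child
      }
      pop <- rbind(elites, children)
    }
  })
}

feature_set_row <- function(genes, fitness, generation, run_index,
                            stop_reason) {
  tibble::tibble(genes = list(sort(genes)), fitness = fitness,
                 generation_found = as.integer(generation),
                 run_index = as.integer(run_index),
                 stop_reason = stop_reason)
}

#' Collect many near-optimal feature sets
#'
#' Runs [evolve_one()] `n_sets` times with independent, reproducible RNG
#' substreams derived from the master seed. Duplicate sets across runs are
#' legal: downstream gene-frequency ranking counts every occurrence.
#'
#' @inheritParams evolve_one
#' @param n_sets Number of runs (default `config$n_sets`).
#' @return Tibble of feature sets, one row per run, as in [evolve_one()].
#' @export
collect_feature_sets <- function(train, config, n_sets = config$n_sets) {
  stopifnot(inherits(config, "ga_config"))
  if (n_sets == 0) {
    return(tibble::tibble(genes = list(), fitness = numeric(0),
                          generation_found = integer(0),
                          run_index = integer(0),
                          stop_reason = character(0)))
  }
  run_seeds <- withr_seed(config$seed,
                          sample.int(.Machine$integer.max, n_sets))
  purrr::map_dfr(seq_len(n_sets), function(i) {
    evolve_one(train, config, run_seed = run_seeds[i], run_index = i)
  })
}
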