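#' Simulate a two-class expression matrix with planted structure
#'
#' Generates log2-scale expression for `n_genes` genes across two sample
#' classes. Background genes are Normal(mu_g, sigma^2) with per-gene
#' baselines mu_g drawn uniformly in \[2, 10\]. A chosen set of informative
#' genes gains a mean shift of `delta` in the second class; a block of
#' genes is generated with target correlation `rho` to a designated anchor
#' gene via `rho * z_anchor + sqrt(1 - rho^2) * noise`. The result mimics
#' the statistical structure of a log2-transformed tumour RNA-seq matrix
#' (not its count noise, batch effects, or purity gradients).
#'
#' @param n_per_class Integer pair: samples in class "A" and class "B".
#' @param n_genes Total number of genes.
#' @param n_informative Number of genes carrying the class effect.
#' @param delta Class mean shift on the log2 scale (>= 0).
#' @param sigma Within-class standard deviation (> 0).
#' @param n_correlated Number of genes correlated with the anchor.
#' @param rho Target Spearman/Pearson correlation to the anchor, |rho| <= 1.
#' @param seed Integer RNG seed; the output is fully reproducible from it.
#' @return A list with `matrix` (an [expr_matrix], already on the log2
#'   scale) and `truth`, a list recording `informative_genes`, `delta`,
#'   `sigma`, `anchor_gene`, `correlated_genes`, `rho` and `seed`.
#' @examples
#' sim <- simulate_expression(c(30, 30), n_genes = 100, n_informative = 5,
#'                            delta = 2, sigma = 1, seed = 1)
#' sim$truth$informative_genes
#' @export
simulate_expression <- function(n_per_class, n_genes, n_informative,
                                delta, sigma = 1, n_correlated = 0,
                                rho = 0.8, seed = 1) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 4),
            delta >= 0, sigma > 0, abs(rho) <= 1)
  if (n_informative + n_correlated + 1 > n_genes) {
    stop("gene budget infeasible: n_informative + n_correlated + 1 > n_genes")
  }
  n <- sum(n_per_class)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n))
  labels <- stats::setNames(rep(c("A", "B"), times = n_per_class), samples)

  withr_seed(seed, {
    mu <- stats::runif(n_genes, 2, 10)
    vals <- matrix(stats::rnorm(n_genes * n, mean = mu, sd = sigma),
                   nrow = n_genes, ncol = n,
                   dimnames = list(genes, samples))
    informative <- sample(genes, n_informative)
    vals[informative, labels == "B"] <- vals[informative, labels == "B"] + delta

    remaining <- setdiff(genes, informative)
    anchor <- sample(remaining, 1)
    correlated <- character(0)
    if (n_correlated > 0) {
      correlated <- sample(setdiff(remaining, anchor), n_correlated)
      z_anchor <- (vals[anchor, ] - mu[match(anchor, genes)]) / sigma
      for (g in correlated) {
        noise <- stats::rnorm(n)
        z <- rho * z_anchor + sqrt(1 - rho^2) * noise
        vals[g, ] <- mu[match(g, genes)] + sigma * z
      }
    }
    list(
      matrix = expr_matrix(vals, labels = labels, transformed = TRUE),
      truth = list(informative_genes = sort(informative), delta = delta,
                   sigma = sigma, anchor_gene = anchor,
                   correlated_genes = sort(correlated), rho = rho,
                   seed = seed)
    )
  })
}

# run code under a fixed seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate 3'UTR-like sequences with planted miRNA seed sites
#'
#' Generates uniform-random RNA sequences and plants non-overlapping
#' windows that pair antiparallel with the seed region of `spec`: either a
#' perfect Watson-Crick reverse complement ("perfect") or a complement
#' carrying exactly one G:U wobble ("one_GU"). Sites are assigned to
#' random sequences; placement retries up to 1000 times before failing.
#'
#' @param n_sequences Number of sequences.
#' @param length Length of each sequence in nucleotides (>= seed length).
#' @param spec A [seed_spec()] defining the miRNA seed.
#' @param n_perfect,n_one_gu Numbers of planted sites of each kind.
#' @param seed Integer RNG seed.
#' @return A list with `sequences` (named character vector, RNA alphabet)
#'   and `truth`, a tibble of planted sites with columns `sequence_id`,
#'   `start`, `end` (0-based half-open) and `site_kind`.
#' @export
simulate_utr <- function(n_sequences, length, spec, n_perfect = 0,
                         n_one_gu = 0, seed = 1) {
  stopifnot(inherits(spec, "seed_spec"), length >= spec$seed_length,
            n_sequences >= 1)
  sl <- spec$seed_length
  seed_nt <- seed_region(spec)

  perfect_window <- antiparallel_complement(seed_nt)
  gu_positions <- which(strsplit(seed_nt, "")[[1]] %in% c("G", "U"))
  if (n_one_gu > 0 && length(gu_positions) == 0) {
    stop("seed contains no G or U: cannot plant a one-G:U site")
  }

  withr_seed(seed, {
    ids <- sprintf("utr%03d", seq_len(n_sequences))
    seqs <- vapply(ids, function(i) {
      paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
            collapse = "")
    }, character(1))

    kinds <- c(rep("perfect", n_perfect), rep("one_GU", n_one_gu))
    placed <- vector("list", length(kinds))
    occupied <- stats::setNames(vector("list", n_sequences), ids)
    for (s in seq_along(kinds)) {
      window <- if (kinds[s] == "perfect") {
        perfect_window
      } else {
        # swap one Watson-Crick pair for a G:U wobble: seed U pairs target
        # G (instead of A); seed G pairs target U (instead of C)
        j <- if (length(gu_positions) == 1) gu_positions else
          sample(gu_positions, 1)
        w <- strsplit(perfect_window, "")[[1]]
        sj <- substr(seed_nt, j, j)
        w[sl - j + 1] <- if (sj == "U") "G" else "U"
        paste(w, collapse = "")
      }
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        id <- if (n_sequences == 1) ids else sample(ids, 1)
        start <- sample.int(length - sl + 1, 1) - 1L  # 0-based
        iv <- c(start, start + sl)
        clash <- any(vapply(occupied[[id]], function(o) {
          iv[1] < o[2] && o[1] < iv[2]
        }, logical(1)))
        if (!clash) {
          occupied[[id]] <- c(occupied[[id]], list(iv))
          substr(seqs[id], start + 1, start + sl) <- window
          placed[[s]] <- tibble::tibble(sequence_id = id, start = start,
                                        end = start + sl,
                                        site_kind = kinds[s])
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place site ", s, " without overlap after ",
                    "1000 attempts")
    }
    truth <- if (length(placed) > 0) {
      dplyr::arrange(dplyr::bind_rows(placed), .data$sequence_id, .data$start)
    } else {
      tibble::tibble(sequence_id = character(), start = integer(),
                     end = integer(), site_kind = character())
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Write a simulation's ground truth as a JSON sidecar
#'
#' Records the planted structure (informative/correlated genes and the
#' anchor for expression simulations; planted site intervals for UTR
#' simulations) next to the simulated data files, so downstream recovery
#' can be audited without rerunning the generator.
#'
#' @param truth The `truth` element of [simulate_expression()] or
#'   [simulate_utr()] output.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write simulated UTR sequences as FASTA
#'
#' @param sequences Named character vector from [simulate_utr()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(sequences, path) {
  set <- Biostrings::RNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
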