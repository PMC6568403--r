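cohort_labels <- function(n_a = 74, n_b = 66) {
  stats::setNames(rep(c("primary", "cutaneous"), c(n_a, n_b)),
                  sprintf("s%03d", seq_len(n_a + n_b)))
}

test_that("stratified 75/25 partitions follow the per-class round-half-up rule", {
  labels <- cohort_labels()
  parts <- make_partitions(labels, 10, seed = 5)
  for (i in 1:10) {
    tr <- parts$train_ids[[i]]
    te <- parts$test_ids[[i]]
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), names(labels))
    # round(0.75*74)=56 primary, round(0.75*66)=50 cutaneous
    expect_identical(sum(labels[tr] == "primary"), 56L)
    expect_identical(sum(labels[tr] == "cutaneous"), 50L)
    expect_length(tr, 106)
    expect_length(te, 34)
  }
  expect_error(make_partitions(c(a = "A", b = "B", c = "A", d = "A",
                                 e = "A", f = "A", g = "A", h = "A"),
                               5),
               ">= 2")
})

test_that("role counts over 100 partitions sum to 100 with ~75 training appearances", {
  labels <- cohort_labels()
  parts <- make_partitions(labels, 100, seed = 17)
  train_counts <- table(unlist(parts$train_ids))
  test_counts <- table(unlist(parts$test_ids))
  all_counts <- train_counts[names(labels)]
  all_counts[is.na(all_counts)] <- 0
  tc <- test_counts[names(labels)]
  tc[is.na(tc)] <- 0
  expect_true(all(all_counts + tc == 100))
  expect_equal(mean(all_counts), 100 * 106 / 140)
  expect_gt(mean(all_counts), 74)
  expect_lt(mean(all_counts), 77)
})

test_that("classify_with_sets honours the averaging contract", {
  sim <- simulate_expression(c(10, 10), 30, 2, delta = 6, sigma = 0.5,
                             seed = 71)
  m <- sim$matrix
  part <- make_partitions(m$labels, 1, seed = 2)[1, ]
  good <- sim$truth$informative_genes
  one_set <- tibble::tibble(genes = list(good), fitness = 1,
                            generation_found = 0L, run_index = 1L,
                            stop_reason = "threshold")
  fr <- classify_with_sets(one_set, m, part, k = 3)
  expect_true(all(fr$fraction_correct == 1))

  # averaging contract: the fraction under two sets is the mean of the
  # per-set fractions
  noise <- setdiff(gene_ids(m), good)[1:2]
  noise_set <- tibble::tibble(genes = list(noise))
  fr_noise <- classify_with_sets(noise_set, m, part, k = 3)
  both <- dplyr::bind_rows(one_set["genes"], noise_set)
  fr_both <- classify_with_sets(both, m, part, k = 3)
  expect_equal(fr_both$fraction_correct,
               (fr$fraction_correct + fr_noise$fraction_correct) / 2)

  bad_set <- tibble::tibble(genes = list(c("nope1", good[1])))
  expect_error(classify_with_sets(bad_set, m, part), "nope1")
})

test_that("aggregate_accuracy averages fractions per role with counts", {
  fr <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s1", "s2"),
    role = c("test", "test", "test", "test", "train"),
    fraction_correct = c(1, 1, 1, 0, 0.8)
  )
  acc <- aggregate_accuracy(fr)
  s1 <- acc[acc$sample_id == "s1", ]
  expect_equal(s1$test_accuracy, 0.75)
  expect_identical(s1$n_test_appearances, 4L)
  expect_identical(s1$n_train_appearances, 0L)
  expect_true(is.na(s1$train_accuracy))
  s2 <- acc[acc$sample_id == "s2", ]
  expect_equal(s2$train_accuracy, 0.8)
})

test_that("summary statistics use type-7 quartiles per group and overall", {
  acc <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                        train_accuracy = c(1, 2, 3, 4),
                        test_accuracy = c(0, 0.5, 1, 0.5),
                        n_train_appearances = 1L, n_test_appearances = 1L)
  labels <- stats::setNames(rep("A", 4), acc$sample_id)
  s <- summarize_accuracy(acc, labels)
  tr <- s[s$role == "train" & s$group == "Overall", ]
  expect_equal(tr$q1, 1.75)
  expect_equal(tr$q3, 3.25)
  expect_equal(tr$mean, 2.5)
  te <- s[s$role == "test" & s$group == "A", ]
  expect_equal(te$min, 0)
  expect_equal(te$median, 0.5)
  expect_equal(te$max, 1)
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median & s$median <= s$q3 &
                    s$q3 <= s$max))

  one <- summarize_accuracy(acc[1, ], labels)
  expect_true(all(one[one$role == "train", c("min", "q1", "median", "mean",
                                             "q3", "max")] == 1))
})

test_that("gene frequency ranking counts occurrences with lexicographic ties", {
  sets <- tibble::tibble(genes = list(c("a", "b"), c("a", "c"), c("a", "b")))
  tab <- rank_genes_by_frequency(sets)
  expect_identical(tab$gene_id, c("a", "b", "c"))
  expect_identical(tab$count, c(3L, 2L, 1L))
  expect_identical(tab$rank, 1:3)

  tied <- tibble::tibble(genes = list(c("z", "m"), c("m", "z")))
  tab2 <- rank_genes_by_frequency(tied)
  expect_identical(tab2$gene_id, c("m", "z"))
})

test_that("the evaluation pipeline is deterministic end to end", {
  sim <- simulate_expression(c(12, 12), 40, 2, delta = 3, sigma = 1,
                             seed = 81)
  cfg <- desk_config(chromosome_length = 3, population_size = 20,
                     n_sets = 8, max_generations = 5, k = 3, seed = 4)
  a <- run_gaknn_evaluation(sim$matrix, cfg, n_partitions = 2, seed = 6)
  b <- run_gaknn_evaluation(sim$matrix, cfg, n_partitions = 2, seed = 6)
  expect_identical(a$sample_accuracy, b$sample_accuracy)
  expect_identical(a$gene_frequency, b$gene_frequency)
  expect_identical(a$summary, b$summary)
  # training-bias shape: mean training accuracy >= mean testing accuracy
  g <- glance(a)
  expect_gte(g$mean_train_accuracy, g$mean_test_accuracy)
  # tidy/autoplot surfaces
  td <- tidy(a)
  expect_true(all(c("sample_id", "class", "train_accuracy",
                    "test_accuracy") %in% names(td)))
  expect_s3_class(autoplot(a), "ggplot")
  expect_s3_class(plot_gene_frequency(a, 5), "ggplot")
})
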