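test_that("importance aggregation normalises, averages and breaks ties by index", {
  expect_identical(aggregate_importances(list(c(0.5, 0.3, 0.2))), c(1L, 2L, 3L))
  expect_identical(aggregate_importances(list(c(5, 3, 2), c(50, 30, 20))),
                   c(1L, 2L, 3L))
  # opposing votes average to a tie, resolved to the lower index
  expect_identical(aggregate_importances(list(c(1, 0), c(0, 1))), c(1L, 2L))
  # all-zero vectors carry no signal
  expect_error(aggregate_importances(list(c(0, 0), c(0, 0))), "no signal")
  # zero vectors are ignored, not averaged in
  expect_identical(aggregate_importances(list(c(0, 0, 0), c(1, 2, 3))),
                   c(3L, 2L, 1L))
  expect_error(aggregate_importances(list(c(1, 2), c(1, 2, 3))), "length")
})

test_that("the selection rule picks the smallest count attaining the maximum", {
  counts <- c(100L, 50L, 16L, 8L)
  accs <- c(0.90, 0.93, 0.93, 0.88)
  expect_identical(counts[refsig:::smallest_argmax(counts, accs)], 16L)
  expect_identical(refsig:::smallest_argmax(c(10L, 5L), c(0.8, 0.8)), 2L)
  expect_identical(refsig:::smallest_argmax(c(10L, 5L), c(0.9, 0.8)), 1L)
})

test_that("REFS keeps a perfectly separating feature and saturates the curve", {
  cfg <- refs_config(n_folds = 5, n_runs = 1)
  for (seed in 1:5) {
    tb <- separating_table(seed)
    res <- suppressWarnings(refs_single_run(tb, cfg, run_seed = seed))
    expect_true(colnames(tb$counts)[1] %in% res$selection)
    # the curve reports the MEAN accuracy of all 8 members, so a single
    # weak member missing a single sample caps it at 239/240
    expect_gte(max(res$accuracy_curve), 0.99)
  }
})

test_that("elimination is strictly monotone and the curve keys decrease", {
  tb <- separating_table(2, p = 40)
  res <- suppressWarnings(
    refs_single_run(tb, refs_config(n_folds = 5, n_runs = 1), run_seed = 1))
  sizes <- as.integer(names(res$accuracy_curve))
  expect_true(all(diff(sizes) < 0))
  expect_identical(sizes[length(sizes)], 2L)
  for (i in seq_along(res$feature_path)[-1])
    expect_true(all(res$feature_path[[i]] %in% res$feature_path[[i - 1]]) &&
                  length(res$feature_path[[i]]) < length(res$feature_path[[i - 1]]))
})

test_that("repeated REFS is deterministic and tracks selection frequency", {
  tb <- separating_table(3, p = 30)
  cfg <- refs_config(n_folds = 5, n_runs = 2, seed = 4)
  a <- suppressWarnings(refs_select(tb, cfg))
  b <- suppressWarnings(refs_select(tb, cfg))
  expect_identical(a$selected_ids, b$selected_ids)
  expect_identical(a$accuracy_curve, b$accuracy_curve)
  expect_identical(a$frequency, b$frequency)
  one <- suppressWarnings(refs_select(tb, refs_config(n_folds = 5, n_runs = 1)))
  expect_true(all(one$frequency == 1L))
  expect_true(all(a$frequency >= 1 & a$frequency <= 2))
})

test_that("shuffled labels cannot produce a high accuracy curve", {
  # Monte-Carlo null calibration (22v43 samples, 200 features, curve maxima
  # 0.74-0.81 across shuffles; majority-class rate alone is 0.66): a
  # shuffled table must stay below 0.88.
  sim <- generate_cohorts(simulation_config(
    n_features = 200, discovery_seq_len = 40, testing_seq_len = 70,
    n_testing_cohorts = 1, seed = 21))
  tb <- sim$discovery
  set.seed(99)
  tb$labels[] <- sample(tb$labels)
  res <- suppressWarnings(
    refs_single_run(tb, refs_config(n_runs = 1), run_seed = 1))
  expect_lt(max(res$accuracy_curve), 0.88)
})

test_that("degenerate tables are rejected", {
  tb <- random_table(5)
  one_class <- tb$labels
  one_class[] <- "breast_milk"
  tb1 <- asv_table(tb$counts, tb$sequences, one_class)
  expect_error(refs_single_run(tb1, refs_config()), "two groups")
  expect_error(refs_single_run(tb, refs_config(n_folds = 10)), "n_folds")
})
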