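test_that("auc_roc handles the canonical hand cases", {
  expect_equal(auc_roc(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_roc(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0.5)
  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(auc_roc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_roc(c(1, 2), c(TRUE, TRUE)), "both classes")
  expect_error(auc_roc(c(1, NA), c(TRUE, FALSE)), "finite")
})

test_that("auc_roc equals the all-pairs oracle on random instances", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(4:50, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) pos[c(1, n)] <- c(TRUE, FALSE)
    scores <- sample(round(rnorm(n), 1))  # coarse values force ties
    expect_equal(auc_roc(scores, pos), auc_pairs_oracle(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("auc_roc respects complement symmetry and monotone invariance", {
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(6:30, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- rnorm(n)  # tie-free almost surely
    a <- auc_roc(scores, pos)
    expect_equal(a + auc_roc(-scores, pos), 1, tolerance = 1e-12)
    expect_equal(auc_roc(exp(3 * scores) + 2, pos), a, tolerance = 1e-12)
  }
})

test_that("the validation module reports five classifiers and finds a clean signal", {
  tb <- separating_table(1, n_per_group = 10, p = 5)
  rep <- suppressWarnings(
    validate_features(tb, colnames(tb$counts)[1], n_repeats = 3, seed = 1,
                      n_folds = 5))
  expect_identical(nrow(rep$summary), 5L)
  expect_true(all(c("mlp", "adaboost", "extra_trees") %in% rep$summary$classifier))
  expect_equal(rep$best_mean_auc, 1.0)
  expect_true(all(rep$per_repeat >= 0 & rep$per_repeat <= 1))
  expect_true(all(rep$summary$sd_auc >= 0))
  expect_identical(rep$summary$mean_auc[rep$summary$classifier == rep$best_classifier],
                   max(rep$summary$mean_auc))
})

test_that("validation rejects empty or unknown feature sets", {
  tb <- random_table(2, n = 12)
  expect_error(validate_features(tb, character(0)), "empty")
  expect_error(validate_features(tb, "nope"), "not in table")
})

test_that("diagnostic grades follow the lower-inclusive bands", {
  expect_identical(diagnostic_grade(0.93), "excellent")
  expect_identical(diagnostic_grade(0.69), "sufficient")
  expect_identical(diagnostic_grade(1.0), "excellent")
  expect_identical(diagnostic_grade(0.9), "excellent")
  expect_identical(diagnostic_grade(0.85), "very good")
  expect_identical(diagnostic_grade(0.8), "very good")
  expect_identical(diagnostic_grade(0.75), "good")
  expect_identical(diagnostic_grade(0.6), "sufficient")
  expect_identical(diagnostic_grade(0.59), "bad")
  expect_error(diagnostic_grade(1.2), "\\[0, 1\\]")
})

test_that("adaboost stumps learn a separable rule and weight errors correctly", {
  set.seed(5)
  X <- cbind(x1 = c(rnorm(20, 0), rnorm(20, 4)), x2 = rnorm(40))
  y01 <- rep(c(0, 1), each = 20)
  m <- refsig:::fit_ada_stumps(X, y01, n_rounds = 10)
  expect_true(all((refsig:::predict_ada_stumps(m, X) > 0) == (y01 == 1)))
  expect_identical(m$stumps[[1]]$feature, 1L)
  # first stump threshold separates the two clusters
  expect_true(m$stumps[[1]]$threshold > max(X[1:20, 1]) - 1 &&
                m$stumps[[1]]$threshold < min(X[21:40, 1]) + 1)
})
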