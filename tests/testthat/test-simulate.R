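test_that("generation is deterministic for a fixed seed", {
  a <- small_sim(42)
  b <- small_sim(42)
  expect_identical(a$discovery$counts, b$discovery$counts)
  expect_identical(a$discovery$sequences, b$discovery$sequences)
  expect_identical(lapply(a$testing, `[[`, "counts"),
                   lapply(b$testing, `[[`, "counts"))
  expect_identical(a$truth, b$truth)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_features = 10, n_planted = 16), "n_planted")
  expect_error(simulation_config(discovery_seq_len = 400, testing_seq_len = 300),
               "shorter")
  expect_error(simulation_config(fold_change = 0.5), "fold_change")
  expect_error(simulation_config(shared_fraction = 1.2), "shared_fraction")
})

test_that("truth-linked pairs pass containment and unlinked ones fail it", {
  sim <- small_sim(7)
  dseq <- sim$discovery$sequences
  expect_identical(sort(unname(sim$truth$planted_ids)),
                   sort(intersect(sim$truth$planted_ids, names(dseq))))
  for (cid in names(sim$testing)) {
    tseq <- sim$testing[[cid]]$sequences
    links <- sim$truth$links[[cid]]
    expect_true(all(mapply(function(d, t) grepl(dseq[[d]], tseq[[t]], fixed = TRUE),
                           names(links), links)))
    unlinked <- setdiff(names(dseq), names(links))
    expect_false(any(vapply(dseq[unlinked],
                            function(s) any(grepl(s, tseq, fixed = TRUE)),
                            logical(1))))
  }
})

test_that("linked feature counts match the configured shared fraction", {
  sim <- small_sim(3, n_features = 100, n_planted = 10)
  for (cid in names(sim$testing)) {
    links <- sim$truth$links[[cid]]
    expect_identical(sum(names(links) %in% sim$truth$planted_ids),
                     as.integer(round(0.8 * 10)))
    expect_length(links, round(0.8 * 10) + round(0.8 * 90))
  }
})

test_that("planted features shift group means in the truth direction", {
  ok <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- small_sim(seed, n_features = 80, n_planted = 6,
                     n_samples_per_group = c(15, 20))
    rel <- to_relative_abundance(sim$discovery)
    breast <- rel$labels == "breast_milk"
    dirs <- sim$truth$directions$discovery
    for (id in names(dirs)) {
      diff <- mean(rel$values[breast, id]) - mean(rel$values[!breast, id])
      total <- total + 1L
      if (sign(diff) == dirs[[id]]) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("a null simulation leaves single-feature AUCs near chance", {
  sim <- generate_cohorts(simulation_config(
    n_features = 300, fold_change = 1, discovery_seq_len = 40,
    testing_seq_len = 70, n_testing_cohorts = 1, seed = 9))
  rel <- to_relative_abundance(sim$discovery)
  pos <- rel$labels == "breast_milk"
  aucs <- apply(rel$values, 2, function(v) auc_roc(v, pos))
  expect_gte(mean(aucs >= 0.35 & aucs <= 0.65), 0.9)
})

test_that("label noise flips exactly the requested number of labels", {
  tb <- small_sim(5)$discovery
  expect_identical(inject_label_noise(tb, 0, seed = 1)$labels, tb$labels)
  flipped <- inject_label_noise(tb, 1, seed = 1)
  expect_true(all(flipped$labels != tb$labels))
  tb40 <- make_table(matrix(rpois(40 * 3, 30), 40, 3),
                     labels = rep(c("breast_milk", "formula"), 20))
  half <- inject_label_noise(tb40, 0.5, seed = 2)
  expect_identical(sum(half$labels != tb40$labels), 20L)
  expect_identical(inject_label_noise(tb40, 0.5, seed = 2)$labels, half$labels)
})
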