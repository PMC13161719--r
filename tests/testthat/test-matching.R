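test_that("multiple hits sum their abundances per sample", {
  counts <- cbind(t1 = c(5, 2), t2 = c(7, 4), t3 = c(1, 1))
  seqs <- c(t1 = "AAACGTAAA", t2 = "CCACGTCC", t3 = "GGGGGGGG")
  tb <- make_table(counts, labels = c("breast_milk", "formula"),
                   sequences = seqs, cohort_id = "test")
  res <- match_signature(c(f1 = "ACGT", f2 = "TTTT"), tb)
  expect_identical(res$hits$f1, c("t1", "t2"))
  expect_identical(unname(res$matched_table[, "f1"]), c(12, 6))
  expect_identical(res$missing_ids, "f2")
  expect_false("f2" %in% colnames(res$matched_table))
})

test_that("containment includes exact equality and respects strand mode", {
  seqs <- c(t1 = "ACGTACGT", t2 = "GGGTTTCC")
  tb <- make_table(cbind(t1 = c(3, 1), t2 = c(2, 2)),
                   labels = c("breast_milk", "formula"), sequences = seqs)
  res <- match_signature(c(f = "ACGTACGT"), tb)
  expect_identical(res$hits$f, "t1")
  fwd <- match_signature(c(f = "GGTTTC"), tb)
  expect_identical(fwd$hits$f, "t2")
  # GGAAAC occurs only as a reverse complement (GTTTCC) inside t2
  expect_identical(match_signature(c(f = "GGAAAC"), tb)$found_ids, character(0))
  rc <- match_signature(c(f = "GGAAAC"), tb, strand_mode = "forward_and_revcomp")
  expect_identical(rc$hits$f, "t2")
})

test_that("invalid signature characters are rejected by record", {
  tb <- random_table(1)
  expect_error(match_signature(c(ok = "ACGT", bad = "ACGU"), tb), "bad")
})

test_that("matching equals the brute-force double loop on synthetic cohorts", {
  for (seed in 1:30) {
    sim <- small_sim(seed, n_features = 40, n_planted = 4,
                     n_samples_per_group = c(4, 4), n_testing_cohorts = 1)
    sig <- signature_of(sim$discovery, names(sim$discovery$sequences))
    testing <- sim$testing[[1]]
    got <- match_signature(sig, testing)
    want <- match_oracle(sig, testing)
    expect_identical(got$hits[lengths(got$hits) > 0],
                     want$hits[lengths(want$hits) > 0])
    expect_identical(sort(got$found_ids), sort(want$found))
    expect_equal(got$matched_table[, sort(got$found_ids), drop = FALSE],
                 want$matched[, sort(want$found), drop = FALSE])
  }
})

test_that("matching is independent of testing ASV order and is linear", {
  sim <- small_sim(4, n_features = 30, n_planted = 3,
                   n_samples_per_group = c(3, 3), n_testing_cohorts = 1)
  testing <- sim$testing[[1]]
  sig <- signature_of(sim$discovery, sim$truth$planted_ids)
  res <- match_signature(sig, testing)

  perm <- sample(ncol(testing$counts))
  shuffled <- asv_table(testing$counts[, perm], testing$sequences,
                        testing$labels, cohort_id = testing$cohort_id)
  res2 <- match_signature(sig, shuffled)
  expect_identical(res$hits, res2$hits)
  expect_equal(res$matched_table, res2$matched_table)

  doubled <- testing$counts
  doubled[2, ] <- doubled[2, ] * 3
  res3 <- match_signature(sig, asv_table(doubled, testing$sequences,
                                         testing$labels))
  expect_equal(res3$matched_table[2, ], 3 * res$matched_table[2, ])
})

test_that("transfer validation requires at least one found feature", {
  sim <- small_sim(6, n_features = 30, n_planted = 3,
                   n_samples_per_group = c(12, 12), n_testing_cohorts = 1)
  testing <- sim$testing[[1]]
  none <- match_signature(c(f = paste(rep("ACGT", 20), collapse = "")), testing)
  expect_error(transfer_validate(none, testing), "impossible")

  sig <- signature_of(sim$discovery, sim$truth$planted_ids)
  found <- match_signature(sig, testing)
  rep <- suppressWarnings(
    transfer_validate(found, testing, n_repeats = 2, seed = 1, n_folds = 5))
  expect_s3_class(rep, "validation_report")
  expect_true(rep$best_mean_auc >= 0 && rep$best_mean_auc <= 1)
})
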