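# Fixture builders and independent oracles shared across the test files.

bases <- c("A", "C", "G", "T")

rand_seq <- function(len) paste(sample(bases, len, replace = TRUE), collapse = "")

# Small hand-controllable ASV table. `counts` samples x ASVs.
make_table <- function(counts, labels, seq_len = 30, cohort_id = "toy",
                       sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("A%02d", seq_len(ncol(counts)))
  if (is.null(sequences))
    sequences <- stats::setNames(
      vapply(seq_len(ncol(counts)), function(i) rand_seq(seq_len), ""),
      colnames(counts))
  if (is.null(names(labels))) names(labels) <- rownames(counts)
  asv_table(counts, sequences, labels, cohort_id = cohort_id)
}

random_table <- function(seed, n = 8, p = 6, seq_len = 25) {
  set.seed(seed)
  counts <- matrix(rpois(n * p, 40), n, p)
  counts[1, 1] <- 0  # keep a structural zero around
  make_table(counts,
             labels = rep(c("breast_milk", "formula"), length.out = n),
             seq_len = seq_len, cohort_id = sprintf("rand%d", seed))
}

# Two-group table whose first feature separates the groups perfectly and
# whose remaining features are independent noise.
separating_table <- function(seed, n_per_group = 15, p = 60) {
  set.seed(seed)
  n <- 2 * n_per_group
  counts <- matrix(rpois(n * p, 50), n, p)
  labels <- rep(c("breast_milk", "formula"), each = n_per_group)
  counts[, 1] <- ifelse(labels == "breast_milk",
                        rpois(n, 400), rpois(n, 5))
  make_table(counts, labels, cohort_id = "sep")
}

small_sim <- function(seed, n_features = 120, n_planted = 8,
                      n_samples_per_group = c(12, 18), ...) {
  generate_cohorts(simulation_config(
    n_features = n_features, n_planted = n_planted,
    n_samples_per_group = n_samples_per_group,
    discovery_seq_len = 40, testing_seq_len = 70, seed = seed, ...))
}

# --- independent oracles -------------------------------------------------

# AUC by explicit enumeration of all positive-negative pairs.
auc_pairs_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Substring containment by explicit window comparison (no grepl/regex).
contains_oracle <- function(needle, haystack) {
  ln <- nchar(needle); lh <- nchar(haystack)
  if (ln > lh) return(FALSE)
  for (off in 0:(lh - ln))
    if (substr(haystack, off + 1, off + ln) == needle) return(TRUE)
  FALSE
}

# Brute-force signature matching over all (feature, ASV) pairs.
match_oracle <- function(signature, testing) {
  seqs <- testing$sequences[colnames(testing$counts)]
  hits <- lapply(signature, function(q)
    sort(names(seqs)[vapply(seqs, contains_oracle, logical(1), needle = q)]))
  found <- names(hits)[lengths(hits) > 0]
  matched <- sapply(found, function(id)
    rowSums(testing$counts[, hits[[id]], drop = FALSE]))
  list(hits = hits, found = found,
       matched = if (length(found)) as.matrix(matched) else
         matrix(0, nrow(testing$counts), 0))
}
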