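#' REFS configuration
#'
#' @param ensemble named list of base learners (default
#'   [default_refs_ensemble()], eight classifiers).
#' @param n_folds folds of the stratified cross-validation (default 10).
#' @param elimination_fraction fraction of the current features dropped per
#'   iteration (at least one feature is always dropped).
#' @param min_features elimination stops once the set reaches this size.
#' @param n_runs number of repeated REFS runs for the stability analysis.
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param input_scale `"relative_abundance"` (total-sum scaled, default) or
#'   `"raw_counts"`.
#' @return A `refs_config` list.
#' @export
refs_config <- function(ensemble = default_refs_ensemble(),
                        n_folds = 10, elimination_fraction = 0.2,
                        min_features = 2, n_runs = 10, seed = 1,
                        input_scale = c("relative_abundance", "raw_counts")) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (elimination_fraction <= 0 || elimination_fraction >= 1)
    stop("elimination_fraction must lie in (0, 1)")
  if (min_features < 1) stop("min_features must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(ensemble = ensemble, n_folds = n_folds,
                 elimination_fraction = elimination_fraction,
                 min_features = min_features, n_runs = n_runs, seed = seed,
                 input_scale = match.arg(input_scale)),
            class = "refs_config")
}

# Index of the smallest feature count whose accuracy equals the curve
# maximum (the "red line" rule: highest accuracy, minimal features).
smallest_argmax <- function(counts, accs) {
  stopifnot(length(counts) == length(accs))
  best <- max(accs)
  which(counts == min(counts[accs == best]) & accs == best)[1]
}

# Stratified k-fold assignment: within each class, shuffled indices are
# dealt round-robin across folds, so fold class ratios match the data.
stratified_folds <- function(y, k) {
  folds <- vector("list", k)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    grp <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  folds
}

feature_matrix <- function(table, input_scale) {
  if (input_scale == "raw_counts") table$counts
  else to_relative_abundance(table)$values
}

#' Aggregate per-classifier importances into a single feature ranking
#'
#' Each importance vector is normalised to sum 1 (scale-free aggregation
#' across heterogeneous learners), the normalised vectors are averaged
#' element-wise, and features are ranked by decreasing average score with
#' ties broken by ascending feature index. All-zero vectors carry no signal
#' and are excluded from the average.
#'
#' @param importances list of equal-length non-negative numeric vectors.
#' @return Integer vector of feature indices, most important first.
#' @export
aggregate_importances <- function(importances) {
  stopifnot(is.list(importances), length(importances) > 0)
  p <- length(importances[[1]])
  mats <- lapply(importances, function(v) {
    if (length(v) != p) stop("importance vectors differ in length")
    if (any(v < 0)) stop("importances must be non-negative")
    s <- sum(v)
    if (s > 0) v / s else NULL
  })
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats))
    stop("all importance vectors are zero; no signal to rank")
  avg <- Reduce(`+`, mats) / length(mats)
  order(-avg, seq_len(p))
}

#' One REFS run: recursive ensemble elimination under cross-validation
#'
#' At each iteration the current feature set is scored by stratified
#' `n_folds` cross-validation — every ensemble member is trained on the
#' training folds and its held-out accuracy recorded; the ensemble accuracy
#' is the mean over members and folds. The members are then refit on the
#' full cohort, their normalised importances averaged, and the least
#' important `elimination_fraction` of features (at least one) dropped.
#' After reaching `min_features`, the smallest feature count whose curve
#' value equals the curve maximum wins, and the feature set current at that
#' point is returned.
#'
#' @param table an [asv_table]; both groups need at least `n_folds` samples.
#' @param config a [refs_config()].
#' @param run_seed integer seed for this run.
#' @return List with `selection` (character ids), `accuracy_curve` (named
#'   numeric, names = feature counts in elimination order) and
#'   `feature_path` (list of the feature-id sets along the path).
#' @export
refs_single_run <- function(table, config = refs_config(), run_seed = config$seed) {
  stopifnot(inherits(table, "asv_table"))
  X_full <- feature_matrix(table, config$input_scale)
  if (ncol(X_full) < 2) stop("need at least two features")
  y <- binary_factor(table$labels, positive_label(table$labels))
  if (any(table(y) < config$n_folds))
    stop("each group needs at least n_folds samples for stratified CV")

  set.seed(run_seed)
  current <- colnames(X_full)
  curve <- numeric(0)
  path <- list()
  accs <- numeric(0)
  repeat {
    X <- X_full[, current, drop = FALSE]
    folds <- stratified_folds(y, config$n_folds)
    fold_acc <- vapply(folds, function(test_idx) {
      Xtr <- X[-test_idx, , drop = FALSE]
      ytr <- y[-test_idx]
      Xte <- X[test_idx, , drop = FALSE]
      yte <- y[test_idx]
      mean(vapply(config$ensemble, function(l) {
        m <- l$fit(Xtr, ytr)
        mean(l$predict(m, Xte) == yte)
      }, numeric(1)))
    }, numeric(1))
    k <- length(current)
    path[[length(path) + 1]] <- current
    accs <- c(accs, mean(fold_acc))
    curve[as.character(k)] <- mean(fold_acc)

    if (k <= config$min_features) break
    imps <- lapply(config$ensemble, function(l) {
      m <- l$fit(X, y)
      unname(l$importance(m))
    })
    ranking <- aggregate_importances(imps)
    n_drop <- max(1L, floor(config$elimination_fraction * k))
    keep_n <- max(config$min_features, k - n_drop)
    current <- current[sort(ranking[seq_len(keep_n)])]
  }

  sel_idx <- smallest_argmax(vapply(path, length, integer(1)), accs)
  list(selection = path[[sel_idx]], accuracy_curve = curve,
       feature_path = path)
}

#' Repeated REFS with selection-stability analysis
#'
#' Executes `n_runs` independent REFS runs (run r seeded `seed + r - 1`).
#' The canonical selection is the one from the run whose accuracy-curve
#' maximum is highest (ties resolved to the lower run index); the frequency
#' table counts, for each canonical feature, the number of runs whose
#' selection contained it.
#'
#' @param table an [asv_table].
#' @param config a [refs_config()].
#' @return A `refs_result`: `selected_ids`, `accuracy_curve` (canonical
#'   run), `per_run_selections`, `frequency` (named integer), `best_run`,
#'   `runs` (full per-run outputs).
#' @export
refs_select <- function(table, config = refs_config()) {
  runs <- lapply(seq_len(config$n_runs), function(r)
    refs_single_run(table, config, run_seed = config$seed + r - 1))
  maxima <- vapply(runs, function(r) max(r$accuracy_curve), numeric(1))
  best_run <- which.max(maxima)  # first index on ties
  selected <- runs[[best_run]]$selection
  per_run <- lapply(runs, `[[`, "selection")
  freq <- vapply(selected, function(id)
    sum(vapply(per_run, function(s) id %in% s, logical(1))), integer(1))
  structure(list(selected_ids = selected,
                 accuracy_curve = runs[[best_run]]$accuracy_curve,
                 per_run_selections = per_run,
                 frequency = freq,
                 best_run = best_run,
                 runs = runs),
            class = "refs_result")
}

#' @export
print.refs_result <- function(x, ...) {
  cat(sprintf("REFS selection: %d features (curve max %.3f over %d run%s)\n",
              length(x$selected_ids), max(x$accuracy_curve),
              length(x$per_run_selections),
              if (length(x$per_run_selections) > 1) "s" else ""))
  cat("stable in all runs:",
      sum(x$frequency == length(x$per_run_selections)), "feature(s)\n")
  invisible(x)
}

#' Per-feature one-way ANOVA F statistics for two groups
#'
#' Closed-form two-group F: between-group mean square over within-group
#' mean square. Features constant across all samples get F = 0 by
#' convention (0/0 carries no signal).
#'
#' @param table an [asv_table]; each group needs >= 2 samples.
#' @param input_scale as in [refs_config()].
#' @return Named numeric vector of F statistics.
#' @export
anova_f_scores <- function(table, input_scale = "relative_abundance") {
  X <- feature_matrix(table, input_scale)
  y <- as.character(table$labels)
  groups <- sort(unique(y))
  if (length(groups) != 2) stop("exactly two groups required")
  if (any(table(y) < 2)) stop("each group needs at least 2 samples")
  n <- nrow(X)
  m1 <- colMeans(X[y == groups[1], , drop = FALSE])
  m2 <- colMeans(X[y == groups[2], , drop = FALSE])
  n1 <- sum(y == groups[1]); n2 <- sum(y == groups[2])
  grand <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- colSums((t(t(X[y == groups[1], , drop = FALSE]) - m1))^2) +
    colSums((t(t(X[y == groups[2], , drop = FALSE]) - m2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- 0
  constant <- apply(X, 2, function(v) all(v == v[1]))
  f[constant] <- 0
  f
}

#' Univariate k-best baseline
#'
#' The k features with the highest two-group ANOVA F scores; ties broken by
#' ascending feature index. Deterministic.
#'
#' @param table an [asv_table].
#' @param k number of features to keep.
#' @param input_scale as in [refs_config()].
#' @return Character vector of k ASV ids, best first.
#' @export
select_k_best <- function(table, k, input_scale = "relative_abundance") {
  f <- anova_f_scores(table, input_scale)
  if (k > length(f)) stop("k exceeds the number of features (", length(f), ")")
  names(f)[order(-f, seq_along(f))][seq_len(k)]
}
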