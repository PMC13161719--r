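#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC-ROC computed as the normalised Mann-Whitney statistic: the fraction
#' of (positive, negative) sample pairs in which the positive sample scores
#' higher, counting ties as half.
#'
#' @param scores numeric vector, larger = more positive-class.
#' @param labels logical/0-1 vector (`TRUE`/1 = positive), or a character/
#'   factor vector combined with `positive`.
#' @param positive the positive class label when `labels` is not logical.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels) && !(is.numeric(labels) && all(labels %in% c(0, 1)))) {
    pos <- positive_label(labels, positive)
    labels <- as.character(labels) == pos
  }
  pos <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as half-pairs
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Shared engine: repeated stratified CV over a feature matrix, pooling
# held-out scores across folds into one AUC per classifier per repeat.
validate_matrix <- function(values, labels, classifiers, n_repeats, n_folds,
                            seed, positive_class = NULL) {
  pos <- positive_label(labels, positive_class)
  y <- binary_factor(labels, pos)
  if (any(table(y) < n_folds))
    stop("each group needs at least n_folds samples for stratified CV")
  aucs <- matrix(NA_real_, n_repeats, length(classifiers),
                 dimnames = list(NULL, names(classifiers)))
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r - 1)
    folds <- stratified_folds(y, n_folds)
    scores <- matrix(NA_real_, length(y), length(classifiers))
    for (f in folds) {
      Xtr <- values[-f, , drop = FALSE]; ytr <- y[-f]
      Xte <- values[f, , drop = FALSE]
      for (ci in seq_along(classifiers)) {
        m <- classifiers[[ci]]$fit(Xtr, ytr)
        scores[f, ci] <- classifiers[[ci]]$score(m, Xte)
      }
    }
    for (ci in seq_along(classifiers))
      aucs[r, ci] <- auc_roc(scores[, ci], y == pos)
  }
  summary <- data.frame(
    classifier = names(classifiers),
    mean_auc = colMeans(aucs),
    sd_auc = apply(aucs, 2, stats::sd),
    row.names = NULL)
  best <- summary$classifier[which.max(summary$mean_auc)]
  structure(list(summary = summary, per_repeat = aucs,
                 best_classifier = best,
                 best_mean_auc = max(summary$mean_auc),
                 n_repeats = n_repeats, positive_class = pos),
            class = "validation_report")
}

#' Validate a feature set with the five-classifier module
#'
#' Restricts the cohort to `feature_ids` on the relative-abundance scale
#' and grades its discriminative power: for each repeat, a stratified
#' 10-fold cross-validation (seeded `seed + repeat - 1`) trains every
#' classifier of the module and pools its held-out scores across folds into
#' a single AUC-ROC; per-classifier means over repeats and the best
#' classifier are reported.
#'
#' @param table an [asv_table].
#' @param feature_ids non-empty character vector of ASV ids to validate.
#' @param n_repeats repeats of the cross-validation (default 10).
#' @param seed integer seed.
#' @param classifiers named learner list (default
#'   [default_validation_classifiers()]).
#' @param n_folds folds per repeat (default 10).
#' @param positive_class label treated as positive for AUC.
#' @return A `validation_report`: `summary` data frame (classifier,
#'   mean_auc, sd_auc), `per_repeat` AUC matrix, `best_classifier`,
#'   `best_mean_auc`, `n_repeats`, `positive_class`.
#' @export
validate_features <- function(table, feature_ids, n_repeats = 10, seed = 1,
                              classifiers = default_validation_classifiers(),
                              n_folds = 10, positive_class = NULL) {
  stopifnot(inherits(table, "asv_table"))
  if (length(feature_ids) == 0) stop("feature set is empty")
  missing <- setdiff(feature_ids, colnames(table$counts))
  if (length(missing))
    stop("feature(s) not in table: ", paste(utils::head(missing, 5), collapse = ", "))
  rel <- to_relative_abundance(table)
  validate_matrix(rel$values[, feature_ids, drop = FALSE], rel$labels,
                  classifiers, n_repeats, n_folds, seed, positive_class)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation module (%d classifiers, %d repeats, positive = %s)\n",
              nrow(x$summary), x$n_repeats, x$positive_class))
  s <- x$summary
  for (i in order(-s$mean_auc))
    cat(sprintf("  %-20s AUC-ROC %.3f (sd %.3f)%s\n", s$classifier[i],
                s$mean_auc[i], s$sd_auc[i],
                if (s$classifier[i] == x$best_classifier) "  <- best" else ""))
  cat(sprintf("diagnostic accuracy: %s\n", diagnostic_grade(x$best_mean_auc)))
  invisible(x)
}

#' Diagnostic-accuracy grade of an AUC-ROC value
#'
#' Conventional bands, lower bound inclusive: 0.9-1.0 excellent, 0.8-0.9
#' very good, 0.7-0.8 good, 0.6-0.7 sufficient, below 0.6 bad.
#'
#' @param auc value in `[0, 1]`.
#' @return One of `"excellent"`, `"very good"`, `"good"`, `"sufficient"`,
#'   `"bad"`.
#' @export
diagnostic_grade <- function(auc) {
  if (!is.numeric(auc) || is.na(auc) || auc < 0 || auc > 1)
    stop("auc must lie in [0, 1]")
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "very good"
  else if (auc >= 0.7) "good"
  else if (auc >= 0.6) "sufficient"
  else "bad"
}
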