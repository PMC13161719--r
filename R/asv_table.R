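#' ASV count table with sequences and sample labels
#'
#' The exchange object of the package: a samples x ASVs matrix of
#' non-negative integer read counts, the nucleotide sequence of every ASV,
#' and a binary group label per sample. All downstream stages (selection,
#' validation, matching, reporting) consume this object.
#'
#' @param counts integer matrix, samples in rows, ASVs in columns; both
#'   dimensions must be named.
#' @param sequences named character vector mapping ASV id to an uppercase
#'   DNA string over \code{A,C,G,T}; must cover every column of
#'   \code{counts}.
#' @param labels named character vector mapping sample id to its group
#'   (e.g. \code{"breast_milk"} / \code{"formula"}); at most two distinct
#'   groups; must cover every row of \code{counts}.
#' @param cohort_id single string identifying the cohort.
#'
#' @return An object of class \code{asv_table}.
#' @export
asv_table <- function(counts, sequences, labels, cohort_id = "cohort") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample ids as rownames and ASV ids as colnames")
  storage.mode(counts) <- "double"
  x <- structure(
    list(counts = counts,
         sequences = sequences[colnames(counts)],
         labels = labels[rownames(counts)],
         cohort_id = as.character(cohort_id)[1]),
    class = "asv_table")
  validate_asv_table(x)
  x
}

validate_asv_table <- function(x) {
  counts <- x$counts
  if (any(is.na(counts)))
    stop("counts contain missing values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  missing_seq <- setdiff(colnames(counts), names(x$sequences)[!is.na(x$sequences)])
  if (length(missing_seq))
    stop("no sequence for ASV(s): ", paste(utils::head(missing_seq, 5), collapse = ", "))
  bad <- !grepl("^[ACGT]+$", x$sequences)
  if (any(bad))
    stop("sequence for ", names(x$sequences)[which(bad)[1]],
         " contains characters outside {A,C,G,T}")
  missing_lab <- setdiff(rownames(counts), names(x$labels)[!is.na(x$labels)])
  if (length(missing_lab))
    stop("no group label for sample(s): ", paste(utils::head(missing_lab, 5), collapse = ", "))
  if (length(unique(x$labels)) > 2)
    stop("more than two group labels present: ",
         paste(unique(x$labels), collapse = ", "))
  invisible(x)
}

#' @export
print.asv_table <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("asv_table '%s': %d samples x %d ASVs (%s)\n",
              x$cohort_id, nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Total-sum scaling to relative abundance
#'
#' Divides each sample's counts by its total, yielding compositional
#' proportions that sum to 1 per sample.
#'
#' @param table an [asv_table].
#' @return An object of class \code{rel_abundance}: list with `values`
#'   (samples x ASVs, rows summing to 1), `labels`, `cohort_id`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("sample(s) with all-zero counts: ",
         paste(utils::head(rownames(table$counts)[totals == 0], 5), collapse = ", "))
  rel_abundance(table$counts / totals, table$labels, table$cohort_id)
}

rel_abundance <- function(values, labels, cohort_id) {
  structure(list(values = values, labels = labels[rownames(values)],
                 cohort_id = cohort_id),
            class = "rel_abundance")
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat(sprintf("rel_abundance '%s': %d samples x %d features\n",
              x$cohort_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Resolve the positive class for AUC: explicit argument wins, then the
# conventional breast_milk label, then the alphabetically first group.
positive_label <- function(labels, positive_class = NULL) {
  groups <- sort(unique(as.character(labels)))
  if (!is.null(positive_class)) {
    if (!positive_class %in% groups)
      stop("positive class '", positive_class, "' not among labels: ",
           paste(groups, collapse = ", "))
    return(positive_class)
  }
  if ("breast_milk" %in% groups) "breast_milk" else groups[1]
}

# Two-level factor with the positive class as the LAST level (the level
# glmnet/xgboost model the probability of).
binary_factor <- function(labels, positive) {
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2)
    stop("exactly two groups required, got: ", paste(groups, collapse = ", "))
  factor(as.character(labels), levels = c(setdiff(groups, positive), positive))
}
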