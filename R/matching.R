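#' Locate a discovery signature inside a testing cohort by containment
#'
#' A discovery feature hits a testing ASV iff the feature's sequence is an
#' exact contiguous substring of the testing ASV's sequence (containment
#' includes equality); with `strand_mode = "forward_and_revcomp"` the
#' reverse complement of the feature sequence is also searched. For every
#' found feature, the counts of all its hit ASVs are summed per sample —
#' a feature appearing multiple times in the testing cohort contributes
#' the sum of its occurrences.
#'
#' @param signature named character vector mapping discovery ASV id to its
#'   sequence, or a data frame with columns `asv_id` and `sequence`.
#' @param testing an [asv_table] to search in.
#' @param strand_mode `"forward"` (default) or `"forward_and_revcomp"`.
#' @return A `signature_match`: `hits` (named list, discovery id -> sorted
#'   testing ids), `found_ids`, `missing_ids`, `matched_table` (samples x
#'   found features, summed counts), `testing_cohort`.
#' @export
match_signature <- function(signature, testing,
                            strand_mode = c("forward", "forward_and_revcomp")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(testing, "asv_table"))
  if (is.data.frame(signature)) {
    if (!all(c("asv_id", "sequence") %in% names(signature)))
      stop("signature data frame needs columns asv_id, sequence")
    signature <- stats::setNames(as.character(signature$sequence),
                                 as.character(signature$asv_id))
  }
  if (length(signature) == 0) stop("signature is empty")
  bad <- !grepl("^[ACGT]+$", signature)
  if (any(bad))
    stop("signature sequence for ", names(signature)[which(bad)[1]],
         " contains characters outside {A,C,G,T}")

  test_seqs <- testing$sequences[colnames(testing$counts)]
  hits <- lapply(names(signature), function(id) {
    q <- signature[[id]]
    hit <- grepl(q, test_seqs, fixed = TRUE)
    if (strand_mode == "forward_and_revcomp") {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
      hit <- hit | grepl(rc, test_seqs, fixed = TRUE)
    }
    sort(names(test_seqs)[hit])
  })
  names(hits) <- names(signature)

  found <- names(hits)[lengths(hits) > 0]
  missing <- setdiff(names(signature), found)
  matched <- matrix(0, nrow(testing$counts), length(found),
                    dimnames = list(rownames(testing$counts), found))
  for (id in found)
    matched[, id] <- rowSums(testing$counts[, hits[[id]], drop = FALSE])

  structure(list(hits = hits, found_ids = found, missing_ids = missing,
                 matched_table = matched,
                 testing_cohort = testing$cohort_id,
                 strand_mode = strand_mode),
            class = "signature_match")
}

#' @export
print.signature_match <- function(x, ...) {
  cat(sprintf("signature match in '%s': %d of %d features found\n",
              x$testing_cohort, length(x$found_ids),
              length(x$found_ids) + length(x$missing_ids)))
  invisible(x)
}

# Relative-abundance view of the matched features: each matched column is
# scaled by the testing sample's TOTAL count over all its ASVs, preserving
# the compositional meaning of the original cohort.
matched_rel_abundance <- function(match_result, testing) {
  totals <- rowSums(testing$counts)
  if (any(totals == 0))
    stop("sample(s) with all-zero counts: ",
         paste(utils::head(rownames(testing$counts)[totals == 0], 5), collapse = ", "))
  rel_abundance(match_result$matched_table / totals, testing$labels,
                testing$cohort_id)
}

#' Transfer validation of a matched signature on a testing cohort
#'
#' Builds the relative-abundance view of the found features (scaled by
#' each sample's total count over all its ASVs) and grades it with the
#' five-classifier validation module on the testing cohort's labels.
#'
#' @param match_result a [match_signature()] result with >= 1 found feature.
#' @param testing the [asv_table] the signature was matched into.
#' @inheritParams validate_features
#' @return A `validation_report`.
#' @export
transfer_validate <- function(match_result, testing, n_repeats = 10, seed = 1,
                              classifiers = default_validation_classifiers(),
                              n_folds = 10, positive_class = NULL) {
  stopifnot(inherits(match_result, "signature_match"),
            inherits(testing, "asv_table"))
  if (length(match_result$found_ids) == 0)
    stop("no signature feature was found in '", testing$cohort_id,
         "'; transfer validation is impossible")
  rel <- matched_rel_abundance(match_result, testing)
  validate_matrix(rel$values, rel$labels, classifiers, n_repeats, n_folds,
                  seed, positive_class)
}

#' Extract the signature (id -> sequence) of a feature selection
#'
#' @param table the discovery [asv_table].
#' @param ids character vector of selected ASV ids.
#' @return Named character vector of sequences.
#' @export
signature_of <- function(table, ids) {
  stopifnot(inherits(table, "asv_table"))
  missing <- setdiff(ids, names(table$sequences))
  if (length(missing))
    stop("id(s) without sequence: ", paste(utils::head(missing, 5), collapse = ", "))
  table$sequences[ids]
}
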