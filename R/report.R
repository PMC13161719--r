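#' Group-mean relative abundance and direction per cohort and feature
#'
#' For every cohort and selected feature, the arithmetic mean of the
#' per-sample relative abundances is computed within the breast-milk and
#' formula groups, and the direction of the difference is recorded:
#' `higher_in_breast` (strictly), `lower_in_breast`, `absent` (feature id
#' missing from that cohort), or a tie (equal means, including the all-zero
#' case) flagged by the `tie` column with `NA` direction.
#'
#' @param tables list of cohorts: [asv_table] or `rel_abundance` objects
#'   (e.g. matched testing views); names default to their cohort ids.
#' @param feature_ids non-empty character vector of feature ids.
#' @param positive_class group treated as "breast"; defaults to
#'   `breast_milk` when present.
#' @return An `abundance_summary`: data frame with columns `cohort`,
#'   `feature`, `mean_breast`, `mean_formula`, `direction`, `tie`.
#' @export
summarize_abundance <- function(tables, feature_ids, positive_class = NULL) {
  if (length(feature_ids) == 0) stop("feature set is empty")
  rels <- lapply(tables, function(tb) {
    if (inherits(tb, "asv_table")) to_relative_abundance(tb)
    else if (inherits(tb, "rel_abundance")) tb
    else stop("tables must be asv_table or rel_abundance objects")
  })
  if (is.null(names(rels)) || any(!nzchar(names(rels))))
    names(rels) <- vapply(rels, `[[`, character(1), "cohort_id")

  rows <- list()
  for (cid in names(rels)) {
    rel <- rels[[cid]]
    pos <- positive_label(rel$labels, positive_class)
    is_breast <- rel$labels == pos
    if (all(is_breast) || !any(is_breast))
      stop("cohort '", cid, "' does not contain both groups")
    for (fid in feature_ids) {
      if (!fid %in% colnames(rel$values)) {
        rows[[length(rows) + 1]] <- data.frame(
          cohort = cid, feature = fid, mean_breast = NA_real_,
          mean_formula = NA_real_, direction = "absent", tie = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      mb <- mean(rel$values[is_breast, fid])
      mf <- mean(rel$values[!is_breast, fid])
      dir <- if (mb > mf) "higher_in_breast"
             else if (mb < mf) "lower_in_breast"
             else NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        cohort = cid, feature = fid, mean_breast = mb, mean_formula = mf,
        direction = dir, tie = mb == mf, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("abundance_summary", "data.frame"))
}

# cohort x feature direction codes: +1 higher in breast, -1 lower, 0 tie,
# NA absent — the matrix behind the heatmap, and its round-trippable form.
direction_matrix <- function(summary) {
  cohorts <- unique(summary$cohort)
  feats <- unique(summary$feature)
  m <- matrix(NA_real_, length(cohorts), length(feats),
              dimnames = list(cohorts, feats))
  for (i in seq_len(nrow(summary))) {
    v <- if (isTRUE(summary$tie[i])) 0
         else switch(summary$direction[i],
                     higher_in_breast = 1, lower_in_breast = -1, absent = NA_real_)
    m[summary$cohort[i], summary$feature[i]] <- v
  }
  m
}

#' Render the cohort-by-feature abundance-direction heatmap
#'
#' Writes the direction matrix (+1 feature higher in breast milk, -1
#' lower, 0 tie, NA absent from the cohort) both as a TSV — the testable
#' artifact — and as a PNG heatmap (dark blue = higher in breast milk,
#' light blue = lower, white = tie, grey = absent). Descriptive only; no
#' hypothesis test is attached.
#'
#' @param summary an [summarize_abundance()] result.
#' @param out_path output path; the extension is replaced to produce
#'   `<stem>.tsv` and `<stem>.png`.
#' @return Named character vector with the `tsv` and `png` paths, invisibly.
#' @export
render_heatmap <- function(summary, out_path) {
  stopifnot(inherits(summary, "abundance_summary"), nrow(summary) > 0)
  m <- direction_matrix(summary)
  stem <- sub("\\.(tsv|png|svg|pdf)$", "", out_path)
  tsv <- paste0(stem, ".tsv")
  png_path <- paste0(stem, ".png")

  df <- data.frame(cohort = rownames(m), m, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  grDevices::png(png_path, width = 200 + 40 * ncol(m),
                 height = 160 + 40 * nrow(m))
  op <- graphics::par(mar = c(7, 8, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  plot_m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(plot_m),
                  zlim = c(-1, 1), col = c("#c6dbef", "white", "#08306b"),
                  breaks = c(-1.5, -0.5, 0.5, 1.5), axes = FALSE,
                  xlab = "", ylab = "", main = "relative abundance direction")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 1)
  graphics::box()
  invisible(c(tsv = tsv, png = png_path))
}
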