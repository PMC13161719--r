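#' Read an ASV table from counts TSV + FASTA + metadata CSV
#'
#' Expected dialect: `counts_path` is a tab-separated table whose header row
#' holds ASV ids and whose first column is `sample_id` (samples as rows,
#' ASVs as columns); `fasta_path` holds one record per ASV keyed by id;
#' `metadata_path` is a CSV with columns `sample_id,group`.
#'
#' @param counts_path path to the counts TSV.
#' @param fasta_path path to the ASV FASTA.
#' @param metadata_path path to the sample metadata CSV.
#' @param cohort_id cohort identifier stored on the returned object;
#'   defaults to the counts file's directory name.
#' @param transpose set `TRUE` if the counts file is oriented ASVs x samples.
#' @return An [asv_table].
#' @export
read_asv_table <- function(counts_path, fasta_path, metadata_path,
                           cohort_id = NULL, transpose = FALSE) {
  for (p in c(counts_path, fasta_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)

  counts_df <- tryCatch(
    utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV '", counts_path, "': ",
                             conditionMessage(e)))
  if (ncol(counts_df) < 2)
    stop("malformed TSV '", counts_path, "': expected sample_id column plus ASV columns")
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- as.character(counts_df[[1]])
  if (transpose) counts <- t(counts)
  if (!is.numeric(counts))
    stop("non-numeric count in '", counts_path, "'")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("negative or non-integer count in '", counts_path, "'")

  seqs_set <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                       error = function(e) stop("malformed FASTA '", fasta_path,
                                                "': ", conditionMessage(e)))
  sequences <- as.character(seqs_set)
  names(sequences) <- sub("\\s.*$", "", names(sequences))

  meta <- tryCatch(
    utils::read.csv(metadata_path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", metadata_path, "': ",
                             conditionMessage(e)))
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata '", metadata_path, "' must have columns sample_id, group")
  labels <- stats::setNames(as.character(meta$group), as.character(meta$sample_id))

  missing_meta <- setdiff(rownames(counts), names(labels))
  if (length(missing_meta))
    stop("sample(s) in counts but absent from metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  missing_fa <- setdiff(colnames(counts), names(sequences))
  if (length(missing_fa))
    stop("ASV(s) in counts but absent from FASTA: ",
         paste(utils::head(missing_fa, 5), collapse = ", "))

  if (is.null(cohort_id)) cohort_id <- basename(dirname(normalizePath(counts_path)))
  asv_table(counts, sequences, labels, cohort_id = cohort_id)
}

#' Write an ASV table as counts TSV + FASTA + metadata CSV
#'
#' Emits `counts.tsv`, `sequences.fasta` and `metadata.csv` into `out_dir`,
#' in exactly the dialect [read_asv_table()] accepts, so that a write/read
#' round trip is lossless. All-zero ASV columns are preserved, never dropped.
#'
#' @param table an [asv_table].
#' @param out_dir output directory; created if missing.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_asv_table <- function(table, out_dir) {
  stopifnot(inherits(table, "asv_table"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  counts_path <- file.path(out_dir, "counts.tsv")
  fasta_path <- file.path(out_dir, "sequences.fasta")
  meta_path <- file.path(out_dir, "metadata.csv")

  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(table$sequences), fasta_path)
  utils::write.csv(
    data.frame(sample_id = names(table$labels), group = unname(table$labels),
               stringsAsFactors = FALSE),
    meta_path, row.names = FALSE, quote = FALSE)

  invisible(c(counts = counts_path, fasta = fasta_path, metadata = meta_path))
}
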