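#' Pipeline configuration
#'
#' Drives the full discovery -> selection -> validation -> matching ->
#' transfer -> report flow. Cohorts come either from the simulator
#' (`simulation` config) or from files/objects (`discovery`, `testing`).
#'
#' @param out_dir output directory for all artifacts.
#' @param simulation a [simulation_config()] used when `discovery` is NULL.
#' @param discovery optional [asv_table], or a directory holding
#'   `counts.tsv`, `sequences.fasta`, `metadata.csv`.
#' @param testing optional list of [asv_table]s or directories; at least
#'   one testing cohort is required for the transfer stage.
#' @param refs a [refs_config()].
#' @param validation_repeats repeats of the validation module.
#' @param run_baseline also run the univariate k-best baseline with k equal
#'   to the REFS selection size, and log the selection overlap.
#' @param strand_mode containment mode for [match_signature()].
#' @param positive_class positive group for AUC.
#' @param seed global pipeline seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulation = simulation_config(),
                            discovery = NULL, testing = NULL,
                            refs = refs_config(), validation_repeats = 10,
                            run_baseline = TRUE,
                            strand_mode = "forward",
                            positive_class = NULL, seed = 1) {
  structure(list(out_dir = out_dir, simulation = simulation,
                 discovery = discovery, testing = testing, refs = refs,
                 validation_repeats = validation_repeats,
                 run_baseline = run_baseline, strand_mode = strand_mode,
                 positive_class = positive_class, seed = seed),
            class = "pipeline_config")
}

load_cohort <- function(x, cohort_id = NULL) {
  if (inherits(x, "asv_table")) return(x)
  if (is.character(x) && dir.exists(x))
    return(read_asv_table(file.path(x, "counts.tsv"),
                          file.path(x, "sequences.fasta"),
                          file.path(x, "metadata.csv"),
                          cohort_id = cohort_id))
  stop("cohort must be an asv_table or a directory with ",
       "counts.tsv/sequences.fasta/metadata.csv")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

report_json <- function(report) {
  list(classifiers = report$summary,
       best_classifier = report$best_classifier,
       best_mean_auc = report$best_mean_auc,
       diagnostic_grade = diagnostic_grade(report$best_mean_auc),
       n_repeats = report$n_repeats,
       positive_class = report$positive_class)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: cohort acquisition (simulation or loading), REFS
#' selection on the discovery cohort, the univariate k-best baseline at the
#' matched k, discovery validation of both selections, signature matching
#' of both selections into every testing cohort, transfer validation,
#' abundance-direction reporting, and a manifest with every seed and
#' artifact hash. Idempotent for a fixed seed: re-running produces a
#' byte-identical `summary.json`. Testing-cohort labels are read only by
#' the transfer-validation and report stages.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest (named list), invisibly; all artifacts are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  seed <- config$seed
  artifacts <- character(0)
  add_artifact <- function(p) artifacts <<- c(artifacts, p)

  truth <- NULL
  if (is.null(config$discovery)) {
    cohorts <- run_stage("simulate", out_dir, {
      sim <- config$simulation
      sim$seed <- seed
      generate_cohorts(sim)
    })
    discovery <- cohorts$discovery
    testing <- cohorts$testing
    truth <- cohorts$truth
    for (tb in c(list(discovery), testing))
      add_artifact(write_asv_table(tb, file.path(out_dir, "cohorts", tb$cohort_id)))
    add_artifact(write_json_file(
      list(planted_ids = truth$planted_ids,
           directions = lapply(truth$directions, as.list),
           links = lapply(truth$links, as.list),
           fold_change = truth$fold_change),
      file.path(out_dir, "cohorts", "truth.json")))
  } else {
    discovery <- run_stage("load_discovery", out_dir,
                           load_cohort(config$discovery, "discovery"))
    testing <- run_stage("load_testing", out_dir, {
      tst <- config$testing
      if (is.null(tst) || length(tst) == 0)
        stop("at least one testing cohort is required")
      tst <- lapply(seq_along(tst), function(i)
        load_cohort(tst[[i]], sprintf("testing%d", i)))
      stats::setNames(tst, vapply(tst, `[[`, character(1), "cohort_id"))
    })
  }

  refs_cfg <- config$refs
  refs_cfg$seed <- seed + 100
  refs_res <- run_stage("refs_select", out_dir,
                        refs_select(discovery, refs_cfg))
  add_artifact(write_json_file(
    list(selected_ids = refs_res$selected_ids,
         accuracy_curve = as.list(refs_res$accuracy_curve),
         frequency = as.list(refs_res$frequency),
         per_run_selections = refs_res$per_run_selections,
         best_run = refs_res$best_run),
    file.path(out_dir, "selection.json")))

  k <- length(refs_res$selected_ids)
  baseline_ids <- NULL
  if (isTRUE(config$run_baseline)) {
    baseline_ids <- run_stage("select_k_best", out_dir,
                              select_k_best(discovery, k))
    add_artifact(write_json_file(
      list(selected_ids = baseline_ids, k = k,
           overlap_with_refs = intersect(refs_res$selected_ids, baseline_ids)),
      file.path(out_dir, "baseline_selection.json")))
  }

  val_disc <- run_stage("validate_discovery", out_dir,
    validate_features(discovery, refs_res$selected_ids,
                      n_repeats = config$validation_repeats, seed = seed + 200,
                      positive_class = config$positive_class))
  add_artifact(write_json_file(report_json(val_disc),
                               file.path(out_dir, "validation_discovery.json")))
  val_base <- NULL
  if (!is.null(baseline_ids)) {
    val_base <- run_stage("validate_baseline", out_dir,
      validate_features(discovery, baseline_ids,
                        n_repeats = config$validation_repeats, seed = seed + 300,
                        positive_class = config$positive_class))
    add_artifact(write_json_file(
      report_json(val_base), file.path(out_dir, "validation_baseline.json")))
  }

  signature <- signature_of(discovery, refs_res$selected_ids)
  transfer <- list()
  for (i in seq_along(testing)) {
    tb <- testing[[i]]
    cid <- tb$cohort_id
    match_res <- run_stage(paste0("match_", cid), out_dir,
                           match_signature(signature, tb,
                                           strand_mode = config$strand_mode))
    add_artifact(write_json_file(
      list(found_ids = match_res$found_ids,
           missing_ids = match_res$missing_ids,
           hits = match_res$hits),
      file.path(out_dir, sprintf("match_%s.json", cid))))
    val_t <- run_stage(paste0("transfer_validate_", cid), out_dir,
      transfer_validate(match_res, tb, n_repeats = config$validation_repeats,
                        seed = seed + 400 + i,
                        positive_class = config$positive_class))
    add_artifact(write_json_file(
      report_json(val_t),
      file.path(out_dir, sprintf("transfer_validation_%s.json", cid))))
    transfer[[cid]] <- list(match = match_res, validation = val_t)
  }

  summary_tabs <- c(list(to_relative_abundance(discovery)),
                    lapply(transfer, function(t)
                      matched_rel_abundance(t$match,
                                            testing[[t$match$testing_cohort]])))
  abund <- run_stage("abundance_report", out_dir,
                     summarize_abundance(summary_tabs, refs_res$selected_ids,
                                         positive_class = config$positive_class))
  hm <- run_stage("render_heatmap", out_dir,
                  render_heatmap(abund, file.path(out_dir, "abundance_directions")))
  add_artifact(hm)

  summary <- list(
    seed = seed,
    discovery_cohort = discovery$cohort_id,
    n_features = ncol(discovery$counts),
    refs = list(
      n_selected = k,
      selected_ids = refs_res$selected_ids,
      curve_max = max(refs_res$accuracy_curve),
      frequency = as.list(refs_res$frequency),
      discovery_auc = val_disc$best_mean_auc,
      discovery_best_classifier = val_disc$best_classifier,
      discovery_grade = diagnostic_grade(val_disc$best_mean_auc)),
    baseline = if (!is.null(baseline_ids)) list(
      k = k,
      selected_ids = baseline_ids,
      overlap_with_refs = intersect(refs_res$selected_ids, baseline_ids),
      n_overlap = length(intersect(refs_res$selected_ids, baseline_ids)),
      discovery_auc = val_base$best_mean_auc,
      discovery_best_classifier = val_base$best_classifier),
    transfer = lapply(transfer, function(t) list(
      n_found = length(t$match$found_ids),
      n_missing = length(t$match$missing_ids),
      found_ids = t$match$found_ids,
      auc = t$validation$best_mean_auc,
      best_classifier = t$validation$best_classifier,
      grade = diagnostic_grade(t$validation$best_mean_auc))),
    planted_recovery = if (!is.null(truth)) list(
      n_planted = length(truth$planted_ids),
      n_recovered = length(intersect(refs_res$selected_ids, truth$planted_ids)),
      precision = length(intersect(refs_res$selected_ids, truth$planted_ids)) /
        min(k, length(truth$planted_ids))))
  summary_path <- write_json_file(summary, file.path(out_dir, "summary.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("refsig")),
    seed = seed,
    stage_seeds = list(simulate = seed, refs_select = seed + 100,
                       validate_discovery = seed + 200,
                       validate_baseline = seed + 300,
                       transfer_validate = seed + 400 + seq_along(testing)),
    artifacts = {
      paths <- c(unlist(artifacts, use.names = FALSE), summary_path)
      data.frame(path = sub("^/?", "", sub(out_dir, "", paths, fixed = TRUE)),
                 md5 = unname(tools::md5sum(paths)),
                 stringsAsFactors = FALSE)
    })
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
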