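#' Configuration for the multi-cohort ASV simulator
#'
#' The generator emulates the structure of a two-group (breast-milk vs
#' formula) infant-gut 16S study: one discovery cohort sequenced on a short
#' amplicon region and several testing cohorts sequenced on a longer region
#' that contains the short one, so that discovery sequences can be located
#' inside testing sequences by exact substring containment.
#'
#' Generative model, per cohort: each feature j has a baseline
#' log-abundance `mu_j ~ Normal(0, base_abundance_log_sd)`; planted
#' discriminative features are multiplied by `fold_change` in their enriched
#' group; testing cohorts additionally receive a per-feature batch
#' multiplier `~ LogNormal(0, batch_effect_log_sd)` (the discovery cohort is
#' the reference batch) and a `direction_flip_fraction` of planted features
#' swap their enriched group there. Per-sample overdispersion is lognormal
#' with sd `sample_noise_log_sd`. Sample compositions are the normalised
#' perturbed abundances and counts are drawn
#' `Multinomial(depth, composition)` with
#' `depth ~ round(LogNormal(log(sequencing_depth), depth_log_sd))`.
#'
#' @param n_features total number of ASVs per cohort.
#' @param n_planted number of planted discriminative ASVs.
#' @param n_samples_per_group discovery group sizes `c(breast_milk, formula)`.
#' @param testing_samples_per_group testing-cohort group sizes.
#' @param n_testing_cohorts number of testing cohorts.
#' @param fold_change multiplicative group effect (>= 1) of planted features.
#' @param sequencing_depth mean reads per sample.
#' @param depth_log_sd lognormal sd of per-sample depth.
#' @param base_abundance_log_sd sd of baseline log-abundances.
#' @param batch_effect_log_sd sd of per-cohort per-feature log batch
#'   multipliers (testing cohorts only).
#' @param sample_noise_log_sd per-sample per-feature lognormal
#'   overdispersion sd.
#' @param direction_flip_fraction fraction of planted features whose
#'   enriched group is swapped in each testing cohort.
#' @param discovery_seq_len discovery amplicon length (V4-like, ~250 bp).
#' @param testing_seq_len testing amplicon length (V3-V4-like, ~400 bp).
#' @param shared_fraction fraction of discovery features (planted and noise
#'   alike) whose sequence is embedded in some testing-cohort sequence.
#' @param seed integer seed; all randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_features = 1200,
                              n_planted = 16,
                              n_samples_per_group = c(22, 43),
                              testing_samples_per_group = c(20, 20),
                              n_testing_cohorts = 2,
                              fold_change = 4,
                              sequencing_depth = 20000,
                              depth_log_sd = 0.3,
                              base_abundance_log_sd = 1.5,
                              batch_effect_log_sd = 0.5,
                              sample_noise_log_sd = 0.7,
                              direction_flip_fraction = 0.25,
                              discovery_seq_len = 250,
                              testing_seq_len = 400,
                              shared_fraction = 0.8,
                              seed = 1) {
  cfg <- list(n_features = n_features, n_planted = n_planted,
              n_samples_per_group = n_samples_per_group,
              testing_samples_per_group = testing_samples_per_group,
              n_testing_cohorts = n_testing_cohorts,
              fold_change = fold_change,
              sequencing_depth = sequencing_depth, depth_log_sd = depth_log_sd,
              base_abundance_log_sd = base_abundance_log_sd,
              batch_effect_log_sd = batch_effect_log_sd,
              sample_noise_log_sd = sample_noise_log_sd,
              direction_flip_fraction = direction_flip_fraction,
              discovery_seq_len = discovery_seq_len,
              testing_seq_len = testing_seq_len,
              shared_fraction = shared_fraction, seed = seed)
  if (cfg$n_planted > cfg$n_features)
    stop("n_planted must not exceed n_features")
  if (cfg$discovery_seq_len >= cfg$testing_seq_len)
    stop("discovery_seq_len must be shorter than testing_seq_len")
  for (f in c("depth_log_sd", "base_abundance_log_sd", "batch_effect_log_sd",
              "sample_noise_log_sd"))
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  if (cfg$fold_change < 1) stop("fold_change must be >= 1")
  if (cfg$direction_flip_fraction < 0 || cfg$direction_flip_fraction > 1)
    stop("direction_flip_fraction must lie in [0, 1]")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (length(cfg$n_samples_per_group) != 2 || any(cfg$n_samples_per_group < 1))
    stop("n_samples_per_group must be two positive integers")
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""),
         character(1))
}

# One cohort's counts. `enriched`: +1 = breast-enriched, -1 = formula-enriched,
# 0 = not planted (length n_features).
simulate_cohort_counts <- function(cfg, mu, enriched, batch, group_sizes,
                                   cohort_id, asv_ids) {
  p <- cfg$n_features
  groups <- c("breast_milk", "formula")
  n <- sum(group_sizes)
  sample_ids <- sprintf("%s_S%03d", cohort_id, seq_len(n))
  labels <- stats::setNames(rep(groups, group_sizes), sample_ids)
  lfc <- log(cfg$fold_change)
  counts <- matrix(0, n, p, dimnames = list(sample_ids, asv_ids))
  for (i in seq_len(n)) {
    eff <- ifelse(enriched == ifelse(labels[i] == "breast_milk", 1, -1), lfc, 0)
    loglam <- mu + eff + log(batch) +
      stats::rnorm(p, 0, cfg$sample_noise_log_sd)
    comp <- exp(loglam - max(loglam))
    comp <- comp / sum(comp)
    depth <- max(1L, round(stats::rlnorm(1, log(cfg$sequencing_depth),
                                         cfg$depth_log_sd)))
    counts[i, ] <- stats::rmultinom(1, depth, comp)
  }
  sequences <- attr(asv_ids, "sequences")
  asv_table(counts, sequences, labels, cohort_id = cohort_id)
}

#' Generate discovery and testing cohorts with known ground truth
#'
#' Returns a discovery cohort, `n_testing_cohorts` testing cohorts, and a
#' ground-truth object recording the planted discriminative ASVs, their
#' per-cohort effect directions, and the discovery-to-testing sequence
#' links. A `shared_fraction` of discovery features (planted and noise
#' alike) have their sequence embedded verbatim at a random offset inside a
#' longer testing-cohort sequence; the remaining discovery sequences are
#' contained in no testing sequence.
#'
#' @param config a [simulation_config()].
#' @return List with elements `discovery` ([asv_table]), `testing` (named
#'   list of [asv_table]s) and `truth` (class `ground_truth`: `planted_ids`,
#'   `directions` — named per-cohort vectors, +1 breast-enriched /
#'   -1 formula-enriched —, `links` — per-testing-cohort named maps
#'   discovery id -> testing id —, and `fold_change`).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  p <- cfg$n_features

  disc_ids <- sprintf("ASV%04d", seq_len(p))
  disc_seqs <- stats::setNames(random_dna(p, cfg$discovery_seq_len), disc_ids)
  while (anyDuplicated(disc_seqs))
    disc_seqs[duplicated(disc_seqs)] <-
      random_dna(sum(duplicated(disc_seqs)), cfg$discovery_seq_len)

  planted_pos <- sort(sample.int(p, cfg$n_planted))
  planted_ids <- disc_ids[planted_pos]
  disc_dir <- integer(p)
  disc_dir[planted_pos] <- sample(c(1L, -1L), cfg$n_planted, replace = TRUE)

  mu <- stats::rnorm(p, 0, cfg$base_abundance_log_sd)

  ids_attr <- function(ids, seqs) { attr(ids, "sequences") <- seqs; ids }
  discovery <- simulate_cohort_counts(
    cfg, mu, disc_dir, batch = rep(1, p), group_sizes = cfg$n_samples_per_group,
    cohort_id = "discovery", asv_ids = ids_attr(disc_ids, disc_seqs))

  testing <- list()
  links <- list()
  directions <- list(discovery = stats::setNames(disc_dir[planted_pos], planted_ids))
  n_flip <- round(cfg$direction_flip_fraction * cfg$n_planted)
  n_link_planted <- round(cfg$shared_fraction * cfg$n_planted)
  n_link_noise <- round(cfg$shared_fraction * (p - cfg$n_planted))

  for (t in seq_len(cfg$n_testing_cohorts)) {
    cid <- sprintf("testing%d", t)
    test_ids <- sprintf("T%d_ASV%04d", t, seq_len(p))

    dir_t <- disc_dir
    if (n_flip > 0) {
      flip_pos <- planted_pos[sample.int(cfg$n_planted, n_flip)]
      dir_t[flip_pos] <- -dir_t[flip_pos]
    }

    noise_pos <- setdiff(seq_len(p), planted_pos)
    linked_pos <- sort(c(planted_pos[sample.int(cfg$n_planted, n_link_planted)],
                         noise_pos[sample.int(length(noise_pos), n_link_noise)]))
    linked <- logical(p)
    linked[linked_pos] <- TRUE

    # unlinked testing features are fresh noise, not the discovery feature
    mu_t <- ifelse(linked, mu, stats::rnorm(p, 0, cfg$base_abundance_log_sd))
    dir_t[!linked] <- 0L

    embed <- function(short) {
      pad <- cfg$testing_seq_len - nchar(short)
      left <- sample.int(pad + 1, 1) - 1
      paste0(paste(sample(c("A", "C", "G", "T"), left, replace = TRUE), collapse = ""),
             short,
             paste(sample(c("A", "C", "G", "T"), pad - left, replace = TRUE),
                   collapse = ""))
    }
    test_seqs <- character(p)
    test_seqs[linked] <- vapply(disc_seqs[linked], embed, character(1))
    test_seqs[!linked] <- random_dna(sum(!linked), cfg$testing_seq_len)

    # guarantee unlinked discovery sequences occur in no testing sequence
    for (attempt in 1:5) {
      hit_any <- vapply(disc_seqs[!linked],
                        function(s) any(grepl(s, test_seqs, fixed = TRUE)),
                        logical(1))
      if (!any(hit_any)) break
      offenders <- which(vapply(test_seqs, function(ts)
        any(vapply(disc_seqs[!linked][hit_any], grepl, logical(1),
                   x = ts, fixed = TRUE)), logical(1)) & !linked)
      test_seqs[offenders] <- random_dna(length(offenders), cfg$testing_seq_len)
      if (attempt == 5) stop("could not build containment-free testing sequences")
    }
    test_seqs <- stats::setNames(test_seqs, test_ids)

    batch_t <- stats::rlnorm(p, 0, cfg$batch_effect_log_sd)
    testing[[cid]] <- simulate_cohort_counts(
      cfg, mu_t, dir_t, batch = batch_t,
      group_sizes = cfg$testing_samples_per_group,
      cohort_id = cid, asv_ids = ids_attr(test_ids, test_seqs))

    links[[cid]] <- stats::setNames(test_ids[linked], disc_ids[linked])
    directions[[cid]] <- stats::setNames(dir_t[planted_pos], planted_ids)
  }

  truth <- structure(
    list(planted_ids = planted_ids, directions = directions, links = links,
         fold_change = cfg$fold_change),
    class = "ground_truth")
  list(discovery = discovery, testing = testing, truth = truth)
}

#' Randomly swap a fraction of sample labels
#'
#' Robustness harness: flips exactly `round(flip_fraction * n_samples)`
#' labels to the opposite group, deterministically for a given seed.
#'
#' @param table an [asv_table] with two groups.
#' @param flip_fraction fraction of samples to flip, in `[0, 1]`.
#' @param seed integer seed.
#' @return A new [asv_table] with modified labels.
#' @export
inject_label_noise <- function(table, flip_fraction, seed) {
  stopifnot(inherits(table, "asv_table"))
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("flip_fraction must lie in [0, 1]")
  groups <- sort(unique(table$labels))
  if (length(groups) != 2) stop("label noise requires exactly two groups")
  set.seed(seed)
  n <- nrow(table$counts)
  k <- round(flip_fraction * n)
  idx <- sample.int(n, k)
  labels <- table$labels
  labels[idx] <- ifelse(labels[idx] == groups[1], groups[2], groups[1])
  asv_table(table$counts, table$sequences, labels, cohort_id = table$cohort_id)
}
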