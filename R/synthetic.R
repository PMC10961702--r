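# Synthetic-data generator: emulates every input the workflow consumes --
# ground-truth AR classes at realistic prevalences, noisy per-assay hit
# calls with planted mode-specific detector assays, structural fingerprints
# with planted clusters, QSAR-like predictions, Henry's law constants --
# plus a surrogate pathway-AUC rule consistent with the hit calls, and
# fixtures encoding published summary tables.

#' Configuration for the synthetic AR dataset generator
#'
#' Defaults mirror the study conditions of the published AR model set: 1,820
#' chemicals with 244 antagonists and 22 agonists (6 of them active in both
#' modes), ~560 structural clusters with agonists confined to a small
#' fraction of them, and 729-bit fingerprints.
#'
#' The hit-call mechanism plants indispensable mode-specific detector
#' assays: every active chemical is assigned one primary detector among its
#' mode's detector assays (A9/A11 for agonists, A12/A13/A14 for
#' antagonists), which fires with probability `tpr_primary`; the remaining
#' same-mode-specific assays fire only at `tpr_secondary` and the shared
#' upstream assays A1-A6 at `tpr_shared`. Inactive chemical-assay pairs fire
#' at the false-positive rate `fpr`.
#'
#' @param n_chemicals Number of chemicals.
#' @param prevalence Named vector of class prevalences
#'   (`antagonist`, `agonist`, `both`); the remainder is inactive.
#' @param n_clusters Number of planted structural clusters.
#' @param agonist_cluster_fraction Fraction of clusters allowed to contain
#'   agonists.
#' @param fingerprint_length,prototype_density,flip_noise Fingerprint bits,
#'   per-bit density of cluster prototypes, and per-bit flip probability.
#' @param tpr_primary,tpr_secondary,tpr_shared,fpr Per-assay hit rates (see
#'   Details).
#' @param potency_active,potency_inactive Ranges of the per-chemical,
#'   per-mode potency multiplying the surrogate AUC.
#' @param agonist_detectors,antagonist_detectors Planted detector assays.
#' @param qsar_sensitivity,qsar_false_positive_rate Error rates of the
#'   QSAR-like prediction columns (false-positive-biased, i.e. conservative).
#' @param henry_log10_range log10 range (atm m^3/mol) of the Henry's law
#'   constants, spanning all volatility categories.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_chemicals = 1820L,
                             prevalence = c(antagonist = 0.131,
                                            agonist = 0.009,
                                            both = 0.003),
                             n_clusters = 560L,
                             agonist_cluster_fraction = 10 / 560,
                             fingerprint_length = 729L,
                             prototype_density = 0.2,
                             flip_noise = 0.02,
                             tpr_primary = 0.98,
                             tpr_secondary = 0.05,
                             tpr_shared = 0.30,
                             fpr = 0.01,
                             potency_active = c(0.25, 1),
                             potency_inactive = c(0, 0.095),
                             agonist_detectors = c("A9", "A11"),
                             antagonist_detectors = c("A12", "A13", "A14"),
                             qsar_sensitivity = 0.95,
                             qsar_false_positive_rate = 0.03,
                             henry_log10_range = c(-9, -1)) {
  cfg <- list(
    n_chemicals = as.integer(n_chemicals),
    prevalence = prevalence,
    n_clusters = as.integer(n_clusters),
    agonist_cluster_fraction = agonist_cluster_fraction,
    fingerprint_length = as.integer(fingerprint_length),
    prototype_density = prototype_density,
    flip_noise = flip_noise,
    tpr_primary = tpr_primary, tpr_secondary = tpr_secondary,
    tpr_shared = tpr_shared, fpr = fpr,
    potency_active = potency_active,
    potency_inactive = potency_inactive,
    agonist_detectors = agonist_detectors,
    antagonist_detectors = antagonist_detectors,
    qsar_sensitivity = qsar_sensitivity,
    qsar_false_positive_rate = qsar_false_positive_rate,
    henry_log10_range = henry_log10_range
  )
  if (cfg$n_chemicals < 1L) stop("n_chemicals must be positive")
  if (cfg$n_clusters < 1L) stop("n_clusters must be positive")
  if (!all(c("antagonist", "agonist", "both") %in% names(prevalence))) {
    stop("prevalence must name antagonist, agonist and both")
  }
  if (any(prevalence < 0) || sum(prevalence) > 1) {
    stop("prevalences must be non-negative and sum to at most 1")
  }
  rates <- c(cfg$tpr_primary, cfg$tpr_secondary, cfg$tpr_shared, cfg$fpr,
             cfg$flip_noise, cfg$prototype_density,
             cfg$qsar_sensitivity, cfg$qsar_false_positive_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("all rates must lie in [0, 1]")
  }
  bad <- setdiff(c(cfg$agonist_detectors, cfg$antagonist_detectors),
                 assay_ids())
  if (length(bad) > 0L) stop("unknown detector assay(s): ",
                             paste(bad, collapse = ", "))
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic AR screening dataset
#'
#' Draws ground-truth classes, planted structural clusters and
#' fingerprints, noisy hit calls for the 14 assays, per-mode potencies,
#' QSAR-like predictions and Henry's law constants. Deterministic given
#' (`config`, `seed`).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param roster Assay roster.
#' @return Object of class `synthetic_ar_dataset`: list with `chemicals`
#'   (data frame), `fingerprints` (chemicals x bits matrix), `hit_calls`
#'   (chemicals x 14 matrix), `potency` (chemicals x 2 matrix), `config`,
#'   `seed`.
#' @export
generate_synthetic_dataset <- function(config = generator_config(),
                                       seed = 1L,
                                       roster = ar_roster()) {
  stopifnot(inherits(config, "generator_config"))
  validate_roster(roster)
  set.seed(seed)
  n <- config$n_chemicals
  K <- config$n_clusters
  ids <- sprintf("CHEM%05d", seq_len(n))

  prev <- config$prevalence
  classes <- sample(c("antagonist", "agonist", "both", "inactive"), n,
                    replace = TRUE,
                    prob = c(prev["antagonist"], prev["agonist"],
                             prev["both"], 1 - sum(prev)))
  ag_active <- classes %in% c("agonist", "both")
  ant_active <- classes %in% c("antagonist", "both")

  # clusters: agonist-bearing chemicals are confined to a designated small
  # set of clusters; all other chemicals are spread uniformly
  n_ag_clusters <- max(1L, round(config$agonist_cluster_fraction * K))
  cluster <- sample.int(K, n, replace = TRUE)
  cluster[ag_active] <- sample.int(n_ag_clusters, sum(ag_active),
                                   replace = TRUE)

  # fingerprints: cluster prototype with independent per-bit flips
  L <- config$fingerprint_length
  prototypes <- matrix(
    stats::rbinom(K * L, 1L, config$prototype_density), nrow = K)
  flips <- matrix(stats::rbinom(n * L, 1L, config$flip_noise), nrow = n)
  fingerprints <- abs(prototypes[cluster, , drop = FALSE] - flips)
  rownames(fingerprints) <- ids

  # planted primary detectors
  ag_detector <- rep(NA_character_, n)
  ag_detector[ag_active] <- sample(config$agonist_detectors,
                                   sum(ag_active), replace = TRUE)
  ant_detector <- rep(NA_character_, n)
  ant_detector[ant_active] <- sample(config$antagonist_detectors,
                                     sum(ant_active), replace = TRUE)

  # per chemical-assay hit probabilities
  shared <- shared_assays(roster)
  ag_specific <- setdiff(roster$assay[roster$in_agonist_pathway == 1L], shared)
  ant_specific <- setdiff(roster$assay[roster$in_antagonist_pathway == 1L],
                          shared)
  p <- matrix(config$fpr, nrow = n, ncol = N_ASSAYS,
              dimnames = list(ids, assay_ids()))
  active_any <- ag_active | ant_active
  p[active_any, shared] <- config$tpr_shared
  p[ag_active, ag_specific] <- config$tpr_secondary
  p[ant_active, ant_specific] <- config$tpr_secondary
  p[cbind(which(ag_active), match(ag_detector[ag_active], assay_ids()))] <-
    config$tpr_primary
  p[cbind(which(ant_active), match(ant_detector[ant_active], assay_ids()))] <-
    config$tpr_primary
  hit_calls <- matrix(
    as.integer(stats::runif(n * N_ASSAYS) < p), nrow = n,
    dimnames = dimnames(p))

  runif_range <- function(m, range) stats::runif(m, range[1L], range[2L])
  potency <- cbind(
    agonist = ifelse(ag_active,
                     runif_range(n, config$potency_active),
                     runif_range(n, config$potency_inactive)),
    antagonist = ifelse(ant_active,
                        runif_range(n, config$potency_active),
                        runif_range(n, config$potency_inactive))
  )
  rownames(potency) <- ids

  qsar <- function(active) {
    as.integer(ifelse(active,
                      stats::runif(n) < config$qsar_sensitivity,
                      stats::runif(n) < config$qsar_false_positive_rate))
  }
  henry <- 10^runif_range(n, config$henry_log10_range)

  chemicals <- data.frame(
    chemical_id = ids,
    truth_class = classes,
    cluster_id = cluster,
    agonist_detector = ag_detector,
    antagonist_detector = ant_detector,
    qsar_agonist = qsar(ag_active),
    qsar_antagonist = qsar(ant_active),
    henrys_law_constant = henry,
    stringsAsFactors = FALSE
  )
  structure(list(
    chemicals = chemicals,
    fingerprints = fingerprints,
    hit_calls = hit_calls,
    potency = potency,
    config = config,
    seed = seed
  ), class = "synthetic_ar_dataset")
}

#' @export
print.synthetic_ar_dataset <- function(x, ...) {
  tab <- table(x$chemicals$truth_class)
  cat("Synthetic AR dataset:", nrow(x$chemicals), "chemicals, seed",
      x$seed, "\n")
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  clusters:", length(unique(x$chemicals$cluster_id)),
      " fingerprint bits:", ncol(x$fingerprints), "\n")
  invisible(x)
}

#' Surrogate pathway AUC for one chemical and model
#'
#' Deliberately simple stand-in for a full pathway-deconvolution AUC: the
#' fraction of the model's mode-pathway assays with a hit, multiplied by the
#' chemical's per-mode potency. It is NOT the published network model --
#' only the binarized calls and their ordering are meaningful. Zero when the
#' model's mode pathway is empty, and monotone non-decreasing in the number
#' of active pathway assays.
#'
#' @param hits Named 0/1 vector of the chemical's 14 hit calls.
#' @param model Subset model (object or name).
#' @param mode `"agonist"` or `"antagonist"`.
#' @param potency Non-negative scalar potency of the chemical in this mode.
#' @param roster Assay roster.
#' @return Non-negative surrogate AUC.
#' @export
surrogate_auc <- function(hits, model, mode = c("agonist", "antagonist"),
                          potency = 1, roster = ar_roster()) {
  mode <- match.arg(mode)
  path <- pathway_assays(model, mode, roster)
  if (length(path) == 0L) return(0)
  potency * mean(hits[path])
}

#' Surrogate AUC matrix for a dataset
#'
#' Vectorized [surrogate_auc()] over all chemicals of a synthetic dataset
#' and a set of subset models, for one mode.
#'
#' @param dataset A `synthetic_ar_dataset`.
#' @param models Character vector of model names.
#' @param mode `"agonist"` or `"antagonist"`.
#' @param roster Assay roster.
#' @return Chemicals x models matrix of surrogate AUC scores.
#' @export
surrogate_auc_matrix <- function(dataset, models,
                                 mode = c("agonist", "antagonist"),
                                 roster = ar_roster()) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "synthetic_ar_dataset"))
  path <- roster$assay[roster[[paste0("in_", mode, "_pathway")]] == 1L]
  mm <- model_membership(models)
  mm[, setdiff(assay_ids(), path)] <- 0L
  sizes <- rowSums(mm)
  H <- dataset$hit_calls
  storage.mode(H) <- "double"
  frac <- H %*% t(mm)
  frac <- sweep(frac, 2L, pmax(sizes, 1L), "/")
  frac[, sizes == 0L] <- 0
  auc <- frac * dataset$potency[, mode]
  dimnames(auc) <- list(rownames(H), models)
  auc
}

#' Printed-table fixtures
#'
#' Small in-memory datasets realizing published summary tables: the
#' 1,817-chemical two-model agreement cells for each mode, the 9-assay
#' battery's 13 antagonist + 1 agonist model names with their printed
#' performance, the constrained 5-9-assay battery models, and the testing
#' scenario cost definitions.
#'
#' @return Named list: `table1_antagonist` / `table1_agonist` (paired call
#'   vectors `calls_11`, `calls_14` named by synthetic chemical ids),
#'   `table4_pairs`, `table5_batteries`, `table6_scenarios`.
#' @export
ar_fixtures <- function() {
  make_calls <- function(both_active, only_14, only_11, both_inactive) {
    n <- both_active + only_14 + only_11 + both_inactive
    ids <- sprintf("CHEM%04d", seq_len(n))
    calls_14 <- c(rep(1L, both_active), rep(1L, only_14),
                  rep(0L, only_11), rep(0L, both_inactive))
    calls_11 <- c(rep(1L, both_active), rep(0L, only_14),
                  rep(1L, only_11), rep(0L, both_inactive))
    list(calls_11 = stats::setNames(calls_11, ids),
         calls_14 = stats::setNames(calls_14, ids))
  }
  table4_pairs <- data.frame(
    agonist_model = rep("A00101011101000", 13L),
    antagonist_model = c(
      "A00101000000111", "A00001010000111", "A00001000001111",
      "A00001001000111", "A00101000001111", "A00101010000111",
      "A00001001001111", "A00001011000111", "A00001010001111",
      "A00101010001111", "A00001011001111", "A00101010101111",
      "A00101011101111"),
    union_size = rep(9L, 13L),
    hamming = c(7L, 7L, 7L, 7L, 6L, 6L, 6L, 6L, 6L, 5L, 5L, 4L, 3L),
    antagonist_sensitivity = rep(0.952, 13L),
    antagonist_specificity = c(0.952, 0.934, 0.934, 0.934, 0.955, 0.954,
                               0.936, 0.936, 0.934, 0.955, 0.936, 0.957,
                               0.959),
    stringsAsFactors = FALSE
  )
  table5_batteries <- data.frame(
    battery_size = 5:9,
    antagonist_model = c("A00001000001111", "A00001011000111",
                         "A00001011001111", "A00101010101111",
                         "A00101011101111"),
    agonist_model = c("A00000000001001", "A00001011000000",
                      "A00001011001001", "A00101010101101",
                      "A00101011101000"),
    agonist_sensitivity = c(64.30, 71.40, 71.40, 85, 96),
    agonist_specificity = c(92.60, 98.90, 99.00, 99, 97.70),
    stringsAsFactors = FALSE
  )
  table6_scenarios <- data.frame(
    scenario = c("13-assay single model", "9-assay battery",
                 "6-assay battery", "cluster-based testing",
                 "multi-stage testing"),
    stringsAsFactors = FALSE
  )
  table6_scenarios$stage_chemicals <- list(
    4235, 4235, 4235, c(387, 3848), c(4235, 988))
  table6_scenarios$stage_batteries <- list(13, 9, 6, c(9, 5), c(6, 3))
  table6_scenarios$n_chemicals <- 4235L
  list(
    table1_antagonist = make_calls(173L, 74L, 10L, 1560L),
    table1_agonist = make_calls(21L, 7L, 12L, 1777L),
    table4_pairs = table4_pairs,
    table5_batteries = table5_batteries,
    table6_scenarios = table6_scenarios
  )
}
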