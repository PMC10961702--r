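# Prioritization scenarios: chemical-assay-pair cost accounting, overall
# sensitivity weighting, cluster-based battery assignment, and the
# multi-stage Monte-Carlo testing simulation.

#' Chemical-assay pair cost of a testing scenario
#'
#' The cost unit of a testing scenario is the number of chemical-assay
#' pairs, `sum(chemicals_i * assays_i)` over the stages.
#'
#' @param stage_chemical_counts,stage_battery_sizes Equal-length non-negative
#'   integer vectors.
#' @return Total chemical-assay pairs.
#' @export
#' @examples
#' scenario_cost(4235, 13)            # 55055
#' scenario_cost(c(387, 3848), c(9, 5))  # 22723
scenario_cost <- function(stage_chemical_counts, stage_battery_sizes) {
  if (length(stage_chemical_counts) != length(stage_battery_sizes)) {
    stop("stage chemical counts and battery sizes must have equal length")
  }
  if (any(stage_chemical_counts < 0) || any(stage_battery_sizes < 0)) {
    stop("stage counts must be non-negative")
  }
  sum(as.numeric(stage_chemical_counts) * as.numeric(stage_battery_sizes))
}

#' Scenario cost as a percentage of the full-battery maximum
#'
#' Expresses a chemical-assay pair count relative to running every chemical
#' through the full battery (14 assays by default); rounded to the nearest
#' integer percent for reporting.
#'
#' @param pairs Chemical-assay pair count.
#' @param n_chemicals Number of chemicals (> 0).
#' @param full_battery Size of the full battery (default 14).
#' @param round Round to the nearest integer percent (default TRUE).
#' @return Percentage.
#' @export
#' @examples
#' percent_of_max(55055, 4235)  # 93
#' percent_of_max(25410, 4235)  # 43
percent_of_max <- function(pairs, n_chemicals, full_battery = 14L,
                           round = TRUE) {
  if (n_chemicals <= 0) stop("n_chemicals must be positive")
  p <- 100 * pairs / (n_chemicals * full_battery)
  if (round) round(p) else p
}

#' Prevalence-weighted overall sensitivity
#'
#' Combines per-mode sensitivities by the prevalence of each mode among
#' active chemicals; around 90% of active calls are antagonists, so the
#' antagonist weight defaults to 0.9.
#'
#' @param s_antagonist,s_agonist Per-mode sensitivities (same units, e.g.
#'   percent).
#' @param antagonist_weight Weight between 0 and 1 (default 0.9).
#' @return Weighted overall sensitivity.
#' @export
#' @examples
#' overall_sensitivity(95, 70)    # 92.5
#' overall_sensitivity(95, 93.6)  # 94.86
overall_sensitivity <- function(s_antagonist, s_agonist,
                                antagonist_weight = 0.9) {
  if (antagonist_weight < 0 || antagonist_weight > 1) {
    stop("antagonist_weight must be in [0, 1]")
  }
  antagonist_weight * s_antagonist + (1 - antagonist_weight) * s_agonist
}

#' Cluster-based battery assignment
#'
#' Chemicals in clusters containing at least one prior agonist prediction
#' are tested with the larger battery (9 assays by default, hosting both the
#' agonist and antagonist subset models); all other chemicals get the
#' reduced antagonist-only battery (5 assays). Unclustered chemicals are
#' flagged and conservatively assigned the larger battery.
#'
#' @param cluster_labels Named vector mapping chemical_id to cluster id
#'   (`NA` = unclustered).
#' @param agonist_predictions Named 0/1 vector of prior (e.g. QSAR) agonist
#'   predictions.
#' @param full_size,reduced_size Battery sizes (defaults 9 and 5).
#' @return List with the per-chemical `assignment` data frame, the total
#'   chemical-assay pair `cost`, and counts `n_full`/`n_reduced`.
#' @export
cluster_based_assignment <- function(cluster_labels, agonist_predictions,
                                     full_size = 9L, reduced_size = 5L) {
  if (is.null(names(cluster_labels))) {
    stop("cluster_labels must be named by chemical_id")
  }
  chems <- names(cluster_labels)
  pred <- agonist_predictions[chems]
  pred[is.na(pred)] <- 0L
  cl <- as.character(cluster_labels)
  flagged_clusters <- unique(cl[!is.na(cluster_labels) & pred == 1L])
  unclustered <- is.na(cluster_labels)
  if (any(unclustered)) {
    message(sum(unclustered),
            " unclustered chemical(s) assigned the full battery")
  }
  in_flagged <- !unclustered & cl %in% flagged_clusters
  battery <- ifelse(in_flagged | unclustered, full_size, reduced_size)
  assignment <- data.frame(
    chemical_id = chems,
    cluster_id = cluster_labels,
    battery_size = as.integer(battery),
    flagged_cluster = in_flagged,
    unclustered = unclustered,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  list(
    assignment = assignment,
    cost = sum(battery),
    n_full = sum(battery == full_size),
    n_reduced = sum(battery == reduced_size),
    flagged_clusters = flagged_clusters
  )
}

#' Stage specification for the multi-stage simulation
#'
#' @param battery_size Number of assays run at this stage (for stage 2 this
#'   is the number of additional assays on top of stage 1).
#' @param agonist_sensitivity,agonist_specificity Detection rates of the
#'   stage's agonist subset model, each between 0 and 1.
#' @param selector Which chemicals the stage tests.
#' @return A list of class `stage_spec`.
#' @export
stage_spec <- function(battery_size,
                       agonist_sensitivity, agonist_specificity,
                       selector = c("all-chemicals",
                                    "clusters-with-stage1-agonist-positives",
                                    "clusters-with-prior-agonist-prediction")) {
  selector <- match.arg(selector)
  stopifnot(battery_size >= 1L, battery_size <= 14L,
            agonist_sensitivity >= 0, agonist_sensitivity <= 1,
            agonist_specificity >= 0, agonist_specificity <= 1)
  structure(list(battery_size = as.integer(battery_size),
                 agonist_sensitivity = agonist_sensitivity,
                 agonist_specificity = agonist_specificity,
                 selector = selector),
            class = "stage_spec")
}

#' Multi-stage testing Monte-Carlo simulation
#'
#' Simulates the two-stage agonist testing workflow: stage 1 screens all
#' chemicals with a small battery whose agonist submodel has moderate
#' sensitivity; clusters containing at least one stage-1 agonist positive
#' (true or false) are carried into stage 2, where all their chemicals are
#' re-tested with the additional assays at the stage-2 rates. Within
#' selected clusters the stage-2 call supersedes stage 1; antagonist
#' detection is treated as complete at stage 1 and only agonist detection is
#' tracked.
#'
#' Sampling is exact-fraction without replacement by default: stage 1 draws
#' `round(sens * n_pos)` true positives and `round((1-spec) * n_neg)` false
#' positives (R's round-half-to-even applies to the rare exact .5 cases);
#' `sampling = "bernoulli"` draws each chemical independently instead.
#'
#' @param chemicals Data frame with columns `chemical_id`, `cluster_id`, and
#'   `agonist` (0/1 truth labels, i.e. the confirmed designations).
#' @param stage1,stage2 [stage_spec()] objects. Defaults mirror a 6-assay
#'   stage-1 battery whose 3-assay agonist model has sensitivity 0.714 and
#'   specificity 0.989, and a stage-2 upgrade of 3 assays whose 6-assay
#'   agonist model has sensitivity 0.96 and specificity 0.977.
#' @param n_runs Number of Monte-Carlo runs (default 1000).
#' @param seed Master seed; per-run seeds are derived from it, so identical
#'   inputs and seed give identical results.
#' @param sampling `"exact"` (default) or `"bernoulli"`.
#' @return Object of class `multistage_simulation`: per-run data frame
#'   (`runs`), aggregate `summary` (mean/median/min/max of the stage-2
#'   chemical count, chemical-assay pairs, and detection sensitivity), and a
#'   `settings` echo.
#' @export
simulate_multistage <- function(chemicals,
                                stage1 = stage_spec(6L, 0.714, 0.989),
                                stage2 = stage_spec(3L, 0.960, 0.977,
                                  selector = "clusters-with-stage1-agonist-positives"),
                                n_runs = 1000L, seed = 1L,
                                sampling = c("exact", "bernoulli")) {
  sampling <- match.arg(sampling)
  required <- c("chemical_id", "cluster_id", "agonist")
  missing <- setdiff(required, names(chemicals))
  if (length(missing) > 0L) {
    stop("chemicals missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1L)
  n <- nrow(chemicals)
  truth <- as.integer(chemicals$agonist)
  cl <- as.character(chemicals$cluster_id)
  pos <- which(truth == 1L)
  neg <- which(truth == 0L)
  n_pos <- length(pos); n_neg <- length(neg)

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  draw <- function(idx, p) {
    if (sampling == "exact") {
      k <- round(p * length(idx))
      idx[sample.int(length(idx), k)]
    } else {
      idx[stats::runif(length(idx)) < p]
    }
  }

  res <- matrix(NA_real_, nrow = n_runs, ncol = 4L,
                dimnames = list(NULL, c("n_stage1_positive",
                                        "n_stage2_chemicals",
                                        "chemical_assay_pairs",
                                        "agonist_detection_sensitivity")))
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    if (n_pos == 0L) {
      res[r, ] <- c(0, 0, stage1$battery_size * n, NA_real_)
      next
    }
    tp1 <- draw(pos, stage1$agonist_sensitivity)
    fp1 <- draw(neg, 1 - stage1$agonist_specificity)
    stage1_pos <- c(tp1, fp1)
    sel_clusters <- unique(cl[stage1_pos])
    in2 <- cl %in% sel_clusters
    n2 <- sum(in2)
    pos2 <- which(in2 & truth == 1L)
    detected <- if (length(pos2) == 0L) integer(0) else {
      draw(pos2, stage2$agonist_sensitivity)
    }
    res[r, ] <- c(
      length(stage1_pos),
      n2,
      stage1$battery_size * n + stage2$battery_size * n2,
      length(detected) / n_pos
    )
  }
  runs <- as.data.frame(res)
  runs <- cbind(run = seq_len(n_runs), runs)
  agg <- function(x) {
    c(mean = mean(x), median = stats::median(x), min = min(x), max = max(x))
  }
  summary <- list(
    n_stage2_chemicals = agg(runs$n_stage2_chemicals),
    chemical_assay_pairs = agg(runs$chemical_assay_pairs),
    agonist_detection_sensitivity =
      if (n_pos == 0L) NULL else agg(runs$agonist_detection_sensitivity)
  )
  structure(list(
    runs = runs,
    summary = summary,
    settings = list(stage1 = stage1, stage2 = stage2, n_runs = n_runs,
                    seed = seed, sampling = sampling,
                    n_chemicals = n, n_agonists = n_pos,
                    final_call = "stage-2 call supersedes stage 1 within selected clusters")
  ), class = "multistage_simulation")
}

#' @export
print.multistage_simulation <- function(x, ...) {
  s <- x$summary
  cat("Multi-stage testing simulation (", x$settings$n_runs, " runs, ",
      x$settings$n_chemicals, " chemicals, ", x$settings$n_agonists,
      " true agonists)\n", sep = "")
  cat(sprintf("  stage-2 chemicals: mean %.1f (median %.0f, range %.0f-%.0f)\n",
              s$n_stage2_chemicals["mean"], s$n_stage2_chemicals["median"],
              s$n_stage2_chemicals["min"], s$n_stage2_chemicals["max"]))
  cat(sprintf("  chemical-assay pairs: mean %.1f\n",
              s$chemical_assay_pairs["mean"]))
  if (!is.null(s$agonist_detection_sensitivity)) {
    cat(sprintf("  agonist detection sensitivity: mean %.3f (range %.3f-%.3f)\n",
                s$agonist_detection_sensitivity["mean"],
                s$agonist_detection_sensitivity["min"],
                s$agonist_detection_sensitivity["max"]))
  } else {
    cat("  agonist detection sensitivity: undefined (no true agonists)\n")
  }
  invisible(x)
}
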