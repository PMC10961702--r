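# Battery optimization: cross products of qualifying agonist x antagonist
# subset models, minimal-union batteries, constrained fixed-size battery
# search, and the assay-exclusion qualification landscape.

#' Enumerate agonist x antagonist model pairs
#'
#' Full cross product of a qualifying agonist model set and a qualifying
#' antagonist model set, with the assay-union size and Hamming distance of
#' every pair. With 109 agonist and 537 antagonist models this yields the
#' 58,533 evaluated pairs.
#'
#' @param agonist_models,antagonist_models Character vectors of model names
#'   (e.g. from [qualify_models()]).
#' @param agonist_summaries,antagonist_summaries Optional summary data frames
#'   (from [evaluate_all_models()]) used to annotate each pair with per-mode
#'   sensitivity and specificity.
#' @return Data frame of class `model_pairs` with columns `agonist_model`,
#'   `antagonist_model`, `union_size`, `hamming`, and, when summaries are
#'   supplied, the four performance columns.
#' @export
enumerate_pairs <- function(agonist_models, antagonist_models,
                            agonist_summaries = NULL,
                            antagonist_summaries = NULL) {
  if (length(agonist_models) == 0L || length(antagonist_models) == 0L) {
    stop("both qualifying model sets must be non-empty")
  }
  ag_val <- model_int(agonist_models)
  ant_val <- model_int(antagonist_models)
  i <- rep(seq_along(agonist_models), times = length(antagonist_models))
  j <- rep(seq_along(antagonist_models), each = length(agonist_models))
  or_val <- bitwOr(ag_val[i], ant_val[j])
  xor_val <- bitwXor(ag_val[i], ant_val[j])
  out <- data.frame(
    agonist_model = agonist_models[i],
    antagonist_model = antagonist_models[j],
    union_size = popcount14(or_val),
    hamming = popcount14(xor_val),
    stringsAsFactors = FALSE
  )
  if (!is.null(agonist_summaries)) {
    k <- match(out$agonist_model, agonist_summaries$model_name)
    out$agonist_sensitivity <- agonist_summaries$sensitivity[k]
    out$agonist_specificity <- agonist_summaries$specificity[k]
  }
  if (!is.null(antagonist_summaries)) {
    k <- match(out$antagonist_model, antagonist_summaries$model_name)
    out$antagonist_sensitivity <- antagonist_summaries$sensitivity[k]
    out$antagonist_specificity <- antagonist_summaries$specificity[k]
  }
  class(out) <- c("model_pairs", "data.frame")
  out
}

#' Minimal assay battery from a pair collection
#'
#' Finds the smallest union size over all agonist/antagonist model pairs and
#' returns every pair achieving it. All ties are reported; the ordering
#' (ascending Hamming distance, then descending antagonist specificity when
#' available, then model names) is presentational only.
#'
#' @param pairs A `model_pairs` data frame from [enumerate_pairs()].
#' @return An object of class `minimal_battery`: list with `union_size` and
#'   the achieving `pairs`.
#' @export
minimal_battery <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop("pairs must be a non-empty model_pairs data frame")
  }
  mn <- min(pairs$union_size)
  sel <- pairs[pairs$union_size == mn, , drop = FALSE]
  ord_spec <- if ("antagonist_specificity" %in% names(sel)) {
    -sel$antagonist_specificity
  } else {
    rep(0, nrow(sel))
  }
  sel <- sel[order(sel$hamming, ord_spec,
                   sel$antagonist_model, sel$agonist_model), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(union_size = mn, pairs = sel), class = "minimal_battery")
}

#' @export
print.minimal_battery <- function(x, ...) {
  cat("Minimal assay battery: ", x$union_size, " assays (",
      nrow(x$pairs), " model pair(s) achieve it)\n", sep = "")
  print(utils::head(x$pairs, 20L))
  if (nrow(x$pairs) > 20L) cat("...\n")
  invisible(x)
}

#' Minimal battery without materializing all pairs
#'
#' Memory-light equivalent of `minimal_battery(enumerate_pairs(...))` for
#' large qualifying sets: scans the cross product with bit arithmetic and
#' only materializes the pairs achieving the minimal union size.
#'
#' @inheritParams enumerate_pairs
#' @return A `minimal_battery` object.
#' @export
minimal_battery_search <- function(agonist_models, antagonist_models,
                                   agonist_summaries = NULL,
                                   antagonist_summaries = NULL) {
  if (length(agonist_models) == 0L || length(antagonist_models) == 0L) {
    stop("both qualifying model sets must be non-empty")
  }
  ag_val <- model_int(agonist_models)
  ant_val <- model_int(antagonist_models)
  best <- N_ASSAYS + 1L
  keep_i <- integer(0)
  keep_j <- integer(0)
  for (jj in seq_along(ant_val)) {
    u <- popcount14(bitwOr(ag_val, ant_val[jj]))
    m <- min(u)
    if (m < best) {
      best <- m
      keep_i <- which(u == m)
      keep_j <- rep(jj, length(keep_i))
    } else if (m == best) {
      w <- which(u == m)
      keep_i <- c(keep_i, w)
      keep_j <- c(keep_j, rep(jj, length(w)))
    }
  }
  pairs <- data.frame(
    agonist_model = agonist_models[keep_i],
    antagonist_model = antagonist_models[keep_j],
    union_size = popcount14(bitwOr(ag_val[keep_i], ant_val[keep_j])),
    hamming = popcount14(bitwXor(ag_val[keep_i], ant_val[keep_j])),
    stringsAsFactors = FALSE
  )
  if (!is.null(agonist_summaries)) {
    k <- match(pairs$agonist_model, agonist_summaries$model_name)
    pairs$agonist_sensitivity <- agonist_summaries$sensitivity[k]
    pairs$agonist_specificity <- agonist_summaries$specificity[k]
  }
  if (!is.null(antagonist_summaries)) {
    k <- match(pairs$antagonist_model, antagonist_summaries$model_name)
    pairs$antagonist_sensitivity <- antagonist_summaries$sensitivity[k]
    pairs$antagonist_specificity <- antagonist_summaries$specificity[k]
  }
  class(pairs) <- c("model_pairs", "data.frame")
  minimal_battery(pairs)
}

battery_name <- function(assay_idx) {
  membership <- integer(N_ASSAYS)
  membership[assay_idx] <- 1L
  paste0("A", paste(membership, collapse = ""))
}

#' Constrained fixed-size battery search
#'
#' Over all assay sets of a given size that contain at least one qualifying
#' antagonist subset model, returns the battery whose best contained agonist
#' subset model has maximal sensitivity (ties broken by agonist specificity,
#' then lexicographic battery name). The agonist model is not required to
#' meet the qualification criteria -- the search reports the best agonist
#' performance attainable once acceptable antagonist detection is locked in.
#'
#' @param agonist_summaries,antagonist_summaries Data frames from
#'   [evaluate_all_models()] covering the candidate models for each mode.
#' @param battery_size Number of assays in the battery (1..14).
#' @param criteria [qualification_criteria()] applied to the antagonist
#'   models.
#' @return An object of class `assay_battery`: the battery assays, the best
#'   agonist model (name, sensitivity, specificity) and the best qualifying
#'   antagonist model it contains.
#' @export
constrained_battery_search <- function(agonist_summaries,
                                       antagonist_summaries,
                                       battery_size,
                                       criteria = qualification_criteria()) {
  battery_size <- as.integer(battery_size)
  if (is.na(battery_size) || battery_size < 1L || battery_size > N_ASSAYS) {
    stop("battery_size must be between 1 and ", N_ASSAYS)
  }
  qual_ant <- qualify_models(antagonist_summaries, criteria)
  if (length(qual_ant) == 0L) {
    stop("infeasible: no antagonist subset model meets the criteria")
  }
  ant_val <- model_int(qual_ant)
  ant_sizes <- popcount14(ant_val)
  if (min(ant_sizes) > battery_size) {
    stop("infeasible: the smallest qualifying antagonist model has ",
         min(ant_sizes), " assays, larger than the requested battery size ",
         battery_size)
  }
  ag_val <- model_int(agonist_summaries$model_name)
  full_mask <- 2L^N_ASSAYS - 1L
  sets <- utils::combn(N_ASSAYS, battery_size)
  best <- NULL
  for (s in seq_len(ncol(sets))) {
    idx <- sets[, s]
    set_val <- sum(bitwShiftL(1L, N_ASSAYS - idx))
    compl <- bitwAnd(full_mask, bitwNot(set_val))
    if (!any(bitwAnd(ant_val, compl) == 0L)) next
    in_ag <- bitwAnd(ag_val, compl) == 0L
    if (!any(in_ag)) next
    sens <- agonist_summaries$sensitivity[in_ag]
    spec <- agonist_summaries$specificity[in_ag]
    nm <- agonist_summaries$model_name[in_ag]
    o <- order(-sens, -spec, nm)[1L]
    cand <- list(idx = idx, name = battery_name(idx),
                 ag_name = nm[o], ag_sens = sens[o], ag_spec = spec[o])
    if (is.null(best) ||
        cand$ag_sens > best$ag_sens ||
        (cand$ag_sens == best$ag_sens && cand$ag_spec > best$ag_spec) ||
        (cand$ag_sens == best$ag_sens && cand$ag_spec == best$ag_spec &&
         cand$name < best$name)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("infeasible: no assay set of size ", battery_size,
         " contains both a qualifying antagonist model and any agonist model")
  }
  # best qualifying antagonist model inside the chosen battery
  set_val <- sum(bitwShiftL(1L, N_ASSAYS - best$idx))
  compl <- bitwAnd(full_mask, bitwNot(set_val))
  in_ant <- bitwAnd(ant_val, compl) == 0L
  k <- match(qual_ant[in_ant], antagonist_summaries$model_name)
  sens <- antagonist_summaries$sensitivity[k]
  spec <- antagonist_summaries$specificity[k]
  o <- order(-sens, -spec, qual_ant[in_ant])[1L]
  structure(list(
    assays = assay_ids()[best$idx],
    size = battery_size,
    name = best$name,
    agonist_model = list(name = best$ag_name,
                         sensitivity = best$ag_sens,
                         specificity = best$ag_spec),
    antagonist_model = list(name = qual_ant[in_ant][o],
                            sensitivity = sens[o],
                            specificity = spec[o])
  ), class = "assay_battery")
}

#' @export
print.assay_battery <- function(x, ...) {
  cat("Assay battery ", x$name, " (", x$size, " assays: ",
      paste(x$assays, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  agonist model    %s  sens %.3f  spec %.3f\n",
              x$agonist_model$name, x$agonist_model$sensitivity,
              x$agonist_model$specificity))
  cat(sprintf("  antagonist model %s  sens %.3f  spec %.3f\n",
              x$antagonist_model$name, x$antagonist_model$sensitivity,
              x$antagonist_model$specificity))
  invisible(x)
}

#' Qualification landscape after excluding assays
#'
#' Restricts both modes' model summaries to models disjoint from the
#' excluded assay set (e.g. the three no-longer-available receptor-binding
#' assays A1-A3) and reports, per mode, the best achievable sensitivity, the
#' model(s) achieving it, and the models still meeting the criteria.
#'
#' @param agonist_summaries,antagonist_summaries Data frames from
#'   [evaluate_all_models()].
#' @param excluded Assay ids to remove; empty vector reproduces the global
#'   qualification.
#' @param criteria [qualification_criteria()].
#' @return List with one entry per mode (`max_sensitivity`, `best_models`,
#'   `best_specificity`, `qualifying`) plus the `excluded` set.
#' @export
exclude_assay_analysis <- function(agonist_summaries, antagonist_summaries,
                                   excluded = character(0),
                                   criteria = qualification_criteria()) {
  one_mode <- function(summaries) {
    if (length(excluded) > 0L) {
      mm <- model_membership(summaries$model_name)
      keep <- rowSums(mm[, excluded, drop = FALSE]) == 0L
      summaries <- summaries[keep, , drop = FALSE]
    }
    if (nrow(summaries) == 0L) {
      return(list(max_sensitivity = NA_real_, best_models = character(0),
                  best_specificity = NA_real_, qualifying = character(0)))
    }
    mx <- max(summaries$sensitivity, na.rm = TRUE)
    at <- !is.na(summaries$sensitivity) & summaries$sensitivity == mx
    list(
      max_sensitivity = mx,
      best_models = summaries$model_name[at],
      best_specificity = max(summaries$specificity[at]),
      qualifying = qualify_models(summaries, criteria)
    )
  }
  if (is.numeric(excluded)) excluded <- paste0("A", as.integer(excluded))
  bad <- setdiff(excluded, assay_ids())
  if (length(bad) > 0L) {
    stop("unknown assay id(s): ", paste(bad, collapse = ", "))
  }
  list(agonist = one_mode(agonist_summaries),
       antagonist = one_mode(antagonist_summaries),
       excluded = excluded)
}
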