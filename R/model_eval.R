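# Scoring subset models against the full-model reference: AUC binarization,
# 2x2 confusion summaries, model agreement, qualification by
# sensitivity/specificity criteria, assay prevalence among qualifying models
# and leave-one-assay-out maxima.

#' Binarize pathway AUC scores
#'
#' AUC values at or above the cutoff become active calls (1); values below
#' become inactive calls (0). The default cutoff of 0.1 corresponds to the
#' upper testing concentration limit of the underlying in vitro assays.
#'
#' @param auc Numeric vector of non-negative pathway AUC scores.
#' @param cutoff Positive binarization cutoff (default 0.1).
#' @return Integer vector of 0/1 calls.
#' @export
#' @examples
#' binarize_auc(c(0, 0.099, 0.1, 0.4))  # 0 0 1 1
binarize_auc <- function(auc, cutoff = 0.1) {
  if (!is.numeric(auc)) stop("auc must be numeric")
  if (any(auc < 0, na.rm = TRUE)) {
    stop("AUC values must be non-negative; got negative value(s)")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  out <- as.integer(auc >= cutoff)
  names(out) <- names(auc)
  out
}

#' Qualification criteria for subset models
#'
#' @param min_sensitivity,min_specificity Thresholds in (0,1); defaults 0.95
#'   and 0.85.
#' @param strict Use strict (`>`) comparison (default), i.e. "greater than
#'   95%"; set `FALSE` for inclusive (`>=`).
#' @return A list of class `qualification_criteria`.
#' @export
qualification_criteria <- function(min_sensitivity = 0.95,
                                   min_specificity = 0.85,
                                   strict = TRUE) {
  stopifnot(is.numeric(min_sensitivity), length(min_sensitivity) == 1L,
            min_sensitivity > 0, min_sensitivity < 1,
            is.numeric(min_specificity), length(min_specificity) == 1L,
            min_specificity > 0, min_specificity < 1,
            is.logical(strict), length(strict) == 1L)
  structure(list(min_sensitivity = min_sensitivity,
                 min_specificity = min_specificity,
                 strict = strict),
            class = "qualification_criteria")
}

# vectorized 2x2 metrics; MCC defined as 0 when any marginal is empty
binary_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
  ba <- (sens + spec) / 2
  list(sensitivity = sens, specificity = spec, mcc = mcc,
       balanced_accuracy = ba)
}

#' Confusion summary from 2x2 counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_summary` with the counts, sensitivity = TP/(TP+FN),
#'   specificity = TN/(TN+FP), Matthews correlation coefficient (0 when a
#'   marginal is empty) and balanced accuracy.
#' @export
#' @examples
#' confusion_from_counts(tp = 238, fn = 12, fp = 0, tn = 0)$sensitivity
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  m <- binary_metrics(tp, fp, tn, fn)
  structure(
    c(list(tp = as.integer(tp), fp = as.integer(fp),
           tn = as.integer(tn), fn = as.integer(fn),
           n = as.integer(tp + fp + tn + fn)),
      m),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, digits = 4, ...) {
  cat("Confusion summary (n =", x$n, "chemicals)\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.*f  specificity %.*f\n",
              digits, x$sensitivity, digits, x$specificity))
  cat(sprintf("  MCC %.*f  balanced accuracy %.*f\n",
              digits, x$mcc, digits, x$balanced_accuracy))
  invisible(x)
}

# Align two named call vectors; mismatching chemical sets are an error,
# listing the missing ids. Unnamed vectors of equal length pass through.
align_pair <- function(predicted, reference) {
  if (is.null(names(predicted)) || is.null(names(reference))) {
    if (length(predicted) != length(reference)) {
      stop("call vectors are unnamed and of different lengths; ",
           "name them by chemical_id to enable alignment")
    }
    return(list(predicted = predicted, reference = reference))
  }
  miss_ref <- setdiff(names(predicted), names(reference))
  miss_pred <- setdiff(names(reference), names(predicted))
  if (length(miss_ref) > 0L || length(miss_pred) > 0L) {
    stop("chemical sets differ between call vectors; ",
         "missing from reference: ",
         paste(utils::head(miss_ref, 5L), collapse = ", "),
         if (length(miss_ref) > 5L) " ..." else "",
         "; missing from predicted: ",
         paste(utils::head(miss_pred, 5L), collapse = ", "),
         if (length(miss_pred) > 5L) " ..." else "",
         ". Use align_calls() to intersect explicitly.")
  }
  list(predicted = predicted, reference = reference[names(predicted)])
}

#' Explicitly align two call vectors on their common chemicals
#'
#' Chemicals present in only one vector are dropped and reported; use this
#' before [confusion()] when the two datasets intentionally cover different
#' chemical sets (e.g. 1,817 chemicals common to two published models).
#'
#' @param a,b Named 0/1 call vectors.
#' @return List with aligned `a`, `b`, and the dropped ids `dropped_a`,
#'   `dropped_b`.
#' @export
align_calls <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    stop("align_calls requires vectors named by chemical_id")
  }
  common <- intersect(names(a), names(b))
  list(a = a[common], b = b[common],
       dropped_a = setdiff(names(a), common),
       dropped_b = setdiff(names(b), common))
}

#' Confusion summary of predicted vs reference activity calls
#'
#' Tabulates a predicted 0/1 call vector against a reference (truth) call
#' vector over the same chemicals and computes sensitivity, specificity, MCC
#' and balanced accuracy. Vectors named by chemical are aligned by name;
#' mismatching chemical sets are an error (see [align_calls()]).
#'
#' @param predicted,reference 0/1 call vectors, ideally named by chemical_id.
#' @return A `confusion_summary`.
#' @export
confusion <- function(predicted, reference) {
  al <- align_pair(predicted, reference)
  p <- as.integer(al$predicted); r <- as.integer(al$reference)
  if (!all(p %in% c(0L, 1L)) || !all(r %in% c(0L, 1L))) {
    stop("calls must be binary 0/1")
  }
  confusion_from_counts(
    tp = sum(p == 1L & r == 1L),
    fp = sum(p == 1L & r == 0L),
    tn = sum(p == 0L & r == 0L),
    fn = sum(p == 0L & r == 1L)
  )
}

#' Agreement table between two models' call vectors
#'
#' Cross-tabulates two call vectors (e.g. an 11-assay and a 14-assay model)
#' into both-active / both-inactive / a-only / b-only cells, the agreement
#' count, and the MCC of the 2x2 table.
#'
#' @param calls_a,calls_b 0/1 call vectors over the same chemicals.
#' @return List with the four cells, `agreement`, `n`, and `mcc`.
#' @export
agreement_table <- function(calls_a, calls_b) {
  al <- align_pair(calls_a, calls_b)
  a <- as.integer(al$predicted); b <- as.integer(al$reference)
  both_active <- sum(a == 1L & b == 1L)
  both_inactive <- sum(a == 0L & b == 0L)
  a_only <- sum(a == 1L & b == 0L)
  b_only <- sum(a == 0L & b == 1L)
  m <- binary_metrics(tp = both_active, fp = a_only,
                      tn = both_inactive, fn = b_only)
  list(both_active = both_active, both_inactive = both_inactive,
       a_only = a_only, b_only = b_only,
       agreement = both_active + both_inactive,
       n = length(a), mcc = m$mcc)
}

# Coerce a long AUC table (chemical_id, model_name, mode, auc) for one mode
# into a chemicals x models matrix. Missing combinations are an error.
auc_long_to_matrix <- function(auc_table, mode = NULL) {
  required <- c("chemical_id", "model_name", "mode", "auc")
  missing <- setdiff(required, names(auc_table))
  if (length(missing) > 0L) {
    stop("AUC table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(mode)) {
    modes <- unique(auc_table$mode)
    if (length(modes) > 1L) {
      stop("AUC table contains multiple modes (",
           paste(modes, collapse = ", "), "); supply `mode`")
    }
    mode <- modes
  }
  tab <- auc_table[auc_table$mode == mode, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no AUC records for mode '", mode, "'")
  chems <- unique(tab$chemical_id)
  models <- unique(tab$model_name)
  m <- matrix(NA_real_, nrow = length(chems), ncol = length(models),
              dimnames = list(chems, models))
  m[cbind(match(tab$chemical_id, chems), match(tab$model_name, models))] <-
    tab$auc
  if (anyNA(m)) {
    stop("AUC table is incomplete: every (chemical, model) pair must have ",
         "one record for mode '", mode, "'")
  }
  m
}

#' Evaluate all subset models against a reference model
#'
#' Binarizes an AUC table and scores every subset model's calls against the
#' binarized calls of the reference model (the full 14-assay model by
#' default) as truth, returning one confusion summary per model.
#'
#' @param auc Either a long-format data frame with columns `chemical_id`,
#'   `model_name`, `mode`, `auc`, or a chemicals x models numeric matrix of
#'   AUC scores for a single mode (rownames chemicals, colnames model names).
#' @param reference_model Nomenclature string of the reference model.
#' @param mode Mode to evaluate (`"agonist"`/`"antagonist"`); required when
#'   `auc` is a long data frame containing several modes.
#' @param cutoff Binarization cutoff, see [binarize_auc()].
#' @param include_reference Keep the reference model's (perfect) row?
#' @return Data frame with one row per model: `model_name`, `mode`, the 2x2
#'   counts, `sensitivity`, `specificity`, `mcc`, `balanced_accuracy`.
#' @export
evaluate_all_models <- function(auc, reference_model,
                                mode = NULL, cutoff = 0.1,
                                include_reference = FALSE) {
  if (is.data.frame(auc)) {
    m <- auc_long_to_matrix(auc, mode)
    if (is.null(mode)) mode <- unique(auc$mode)
  } else if (is.matrix(auc)) {
    m <- auc
    if (is.null(mode)) mode <- NA_character_
  } else {
    stop("auc must be a long data frame or a chemicals x models matrix")
  }
  if (is.null(colnames(m))) stop("AUC matrix must have model-name colnames")
  if (!reference_model %in% colnames(m)) {
    stop("reference model ", reference_model, " not present in AUC table")
  }
  calls <- matrix(as.numeric(m >= cutoff), nrow = nrow(m),
                  dimnames = dimnames(m))
  if (any(m < 0)) stop("AUC values must be non-negative")
  ref <- calls[, reference_model]
  tp <- drop(crossprod(calls, ref))
  pred_pos <- colSums(calls)
  n <- nrow(calls)
  pos <- sum(ref)
  fp <- pred_pos - tp
  fn <- pos - tp
  tn <- n - tp - fp - fn
  met <- binary_metrics(tp, fp, tn, fn)
  out <- data.frame(
    model_name = colnames(m),
    mode = mode,
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    sensitivity = met$sensitivity,
    specificity = met$specificity,
    mcc = met$mcc,
    balanced_accuracy = met$balanced_accuracy,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (!include_reference) {
    out <- out[out$model_name != reference_model, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Qualify subset models by sensitivity/specificity criteria
#'
#' Returns the models whose sensitivity and specificity both exceed the
#' criteria (strictly by default, i.e. sensitivity > 95% and specificity >
#' 85%). Tightening the criteria can only shrink the qualifying set.
#'
#' @param summaries Data frame from [evaluate_all_models()].
#' @param criteria A [qualification_criteria()] object.
#' @return Character vector of qualifying model names.
#' @export
qualify_models <- function(summaries, criteria = qualification_criteria()) {
  stopifnot(inherits(criteria, "qualification_criteria"))
  cmp <- if (criteria$strict) `>` else `>=`
  ok <- cmp(summaries$sensitivity, criteria$min_sensitivity) &
    cmp(summaries$specificity, criteria$min_specificity)
  ok[is.na(ok)] <- FALSE
  summaries$model_name[ok]
}

#' Per-assay prevalence within a set of qualifying models
#'
#' For each assay Ai, the fraction of the qualifying models that contain it.
#' Assays present in every qualifying model (prevalence 1) are candidates
#' for being indispensable to that mode.
#'
#' @param qualifying Non-empty character vector of model names.
#' @return Named numeric vector (A1..A14) of fractions between 0 and 1.
#' @export
assay_prevalence <- function(qualifying) {
  if (length(qualifying) == 0L) {
    stop("qualifying model set is empty; prevalence is undefined")
  }
  colMeans(model_membership(qualifying))
}

#' Maximum sensitivity after excluding assays
#'
#' Restricts the evaluated models to those containing none of the excluded
#' assays and reports the maximum sensitivity over the restricted set, along
#' with the model(s) achieving it. Used to measure how indispensable an
#' assay (or assay group) is for a mode.
#'
#' @param summaries Data frame from [evaluate_all_models()].
#' @param excluded Assay ids (e.g. `"A12"` or `c("A1","A2","A3")`) or
#'   integer indices.
#' @return List with `max_sensitivity`, `models` (the argmax model names)
#'   and `n_models` (size of the restricted set).
#' @export
leave_one_out_max_sensitivity <- function(summaries, excluded) {
  if (is.numeric(excluded)) excluded <- paste0("A", as.integer(excluded))
  bad <- setdiff(excluded, assay_ids())
  if (length(bad) > 0L) {
    stop("unknown assay id(s): ", paste(bad, collapse = ", "))
  }
  mm <- model_membership(summaries$model_name)
  keep <- rowSums(mm[, excluded, drop = FALSE]) == 0L
  if (!any(keep)) {
    stop("excluding ", paste(excluded, collapse = ", "),
         " leaves no subset models")
  }
  s <- summaries[keep, , drop = FALSE]
  mx <- max(s$sensitivity, na.rm = TRUE)
  list(
    max_sensitivity = mx,
    models = s$model_name[!is.na(s$sensitivity) & s$sensitivity == mx],
    n_models = nrow(s)
  )
}
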