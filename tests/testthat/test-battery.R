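test_that("pair enumeration is a full cross product with set-algebra unions", {
  ag <- rand_models(3, seed = 1)
  ant <- rand_models(4, seed = 2)
  pairs <- enumerate_pairs(ag, ant)
  expect_equal(nrow(pairs), 12L)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$agonist_model[i]; b <- pairs$antagonist_model[i]
    expect_equal(pairs$union_size[i],
                 length(union(model_assays(a), model_assays(b))))
    expect_equal(pairs$hamming[i], hamming_distance(a, b))
    # cross-module consistency with the scalar op
    expect_equal(pairs$union_size[i], union_size(a, b))
  }
  expect_equal(nrow(enumerate_pairs("A11000000000000", "A00110000000000")), 1L)
  expect_error(enumerate_pairs(character(0), ant), "non-empty")
})

test_that("the printed 9-assay battery table is recovered from its model names", {
  fx <- ar_fixtures()
  pairs <- enumerate_pairs(unique(fx$table4_pairs$agonist_model),
                           fx$table4_pairs$antagonist_model)
  expect_equal(nrow(pairs), 13L)
  mb <- minimal_battery(pairs)
  expect_equal(mb$union_size, 9L)
  expect_equal(nrow(mb$pairs), 13L)
  # union sizes and Hamming distances match the printed values row by row
  k <- match(fx$table4_pairs$antagonist_model, pairs$antagonist_model)
  expect_equal(pairs$union_size[k], fx$table4_pairs$union_size)
  expect_equal(pairs$hamming[k], fx$table4_pairs$hamming)
})

test_that("minimal battery is invariant to pair order and monotone in the sets", {
  ag <- rand_models(6, seed = 3)
  ant <- rand_models(8, seed = 4)
  pairs <- enumerate_pairs(ag, ant)
  mb1 <- minimal_battery(pairs)
  mb2 <- minimal_battery(pairs[sample(nrow(pairs)), ])
  expect_equal(mb1$union_size, mb2$union_size)
  expect_equal(mb1$pairs$agonist_model, mb2$pairs$agonist_model)
  expect_equal(mb1$pairs$antagonist_model, mb2$pairs$antagonist_model)
  # enlarging a qualifying set cannot increase the minimal union
  mb3 <- minimal_battery(enumerate_pairs(c(ag, rand_models(4, seed = 5)), ant))
  expect_lte(mb3$union_size, mb1$union_size)
  # nested pair: agonist model contained in the antagonist model
  nested <- enumerate_pairs("A11000000000000", "A11110000000000")
  expect_equal(minimal_battery(nested)$union_size, 4L)
})

test_that("minimal battery equals an exhaustive scan over a 6-assay universe", {
  set.seed(6)
  ag <- unique(rand_models(8, n_assays = 6))
  ant <- unique(rand_models(10, n_assays = 6))
  mb <- minimal_battery(enumerate_pairs(ag, ant))
  # independent oracle: direct loop over the cross product with set algebra
  best <- Inf; best_pairs <- character(0)
  for (a in ag) for (b in ant) {
    u <- length(union(model_assays(a), model_assays(b)))
    if (u < best) { best <- u; best_pairs <- paste(a, b) }
    else if (u == best) best_pairs <- c(best_pairs, paste(a, b))
  }
  expect_equal(mb$union_size, best)
  expect_setequal(paste(mb$pairs$agonist_model, mb$pairs$antagonist_model),
                  best_pairs)
  # the memory-light search agrees with the materialized cross product
  mbs <- minimal_battery_search(ag, ant)
  expect_equal(mbs$union_size, mb$union_size)
  expect_setequal(paste(mbs$pairs$agonist_model, mbs$pairs$antagonist_model),
                  paste(mb$pairs$agonist_model, mb$pairs$antagonist_model))
})

make_summaries <- function(models, sens, spec) {
  data.frame(model_name = models, mode = "x",
             tp = 0L, fp = 0L, tn = 0L, fn = 0L,
             sensitivity = sens, specificity = spec,
             mcc = 0, balanced_accuracy = (sens + spec) / 2)
}

test_that("constrained battery search matches exhaustive enumeration on small instances", {
  set.seed(8)
  ag_models <- unique(rand_models(12, n_assays = 6))
  ant_models <- unique(rand_models(12, n_assays = 6))
  ag <- make_summaries(ag_models, runif(12), runif(12))
  ant <- make_summaries(ant_models, runif(12, 0.9, 1), runif(12, 0.86, 1))
  crit <- qualification_criteria(0.9, 0.85)
  for (k in 3:5) {
    got <- tryCatch(constrained_battery_search(ag, ant, k, crit),
                    error = function(e) e)
    # oracle: enumerate every k-assay set, apply the same rules directly
    qual_ant <- qualify_models(ant, crit)
    best <- NULL
    for (set in utils::combn(14, k, simplify = FALSE)) {
      battery <- assay_ids()[set]
      has_ant <- any(vapply(qual_ant, function(m)
        all(model_assays(m) %in% battery), logical(1)))
      if (!has_ant) next
      in_ag <- vapply(ag$model_name, function(m)
        all(model_assays(m) %in% battery), logical(1))
      if (!any(in_ag)) next
      cand <- ag[in_ag, ]
      cand <- cand[order(-cand$sensitivity, -cand$specificity,
                         cand$model_name), ][1, ]
      nm <- paste0("A", paste(as.integer(seq_len(14) %in% set),
                              collapse = ""))
      if (is.null(best) ||
          cand$sensitivity > best$sens ||
          (cand$sensitivity == best$sens && cand$specificity > best$spec) ||
          (cand$sensitivity == best$sens && cand$specificity == best$spec &&
           nm < best$nm)) {
        best <- list(sens = cand$sensitivity, spec = cand$specificity,
                     nm = nm, ag = cand$model_name)
      }
    }
    if (is.null(best)) {
      expect_s3_class(got, "error")
    } else {
      expect_s3_class(got, "assay_battery")
      expect_equal(got$agonist_model$sensitivity, best$sens)
      expect_equal(got$agonist_model$specificity, best$spec)
      expect_equal(got$name, best$nm)
      expect_equal(got$agonist_model$name, best$ag)
    }
  }
})

test_that("an unconstrained (14-assay) battery returns the globally best agonist model", {
  set.seed(10)
  ag <- make_summaries(rand_models(20), runif(20), runif(20))
  ant <- make_summaries(rand_models(5), runif(5, 0.96, 1), runif(5, 0.9, 1))
  got <- constrained_battery_search(ag, ant, 14)
  o <- order(-ag$sensitivity, -ag$specificity, ag$model_name)[1]
  expect_equal(got$agonist_model$name, ag$model_name[o])
  expect_equal(got$agonist_model$sensitivity, max(ag$sensitivity))
})

test_that("infeasible constrained searches report infeasibility", {
  ag <- make_summaries("A11111100000000", 0.9, 0.9)
  ant <- make_summaries("A11111111111100", 0.99, 0.99)
  expect_error(constrained_battery_search(ag, ant, 5), "infeasible")
  none <- make_summaries("A11000000000000", 0.2, 0.2)
  expect_error(constrained_battery_search(ag, none, 10), "infeasible")
})

test_that("batteries hosting a qualifying antagonist model always contain the planted antagonist assays", {
  ds <- generate_synthetic_dataset(small_config(n_chemicals = 400L), seed = 31)
  models <- enumerate_subset_models(min_size = 3, include_full = FALSE)
  # restrict to small models to keep the evaluation light
  models <- models[parse_model_name("A11111111111111")$size -
                     nchar(gsub("1", "", substring(models, 2))) <= 6]
  auc_ant <- surrogate_auc_matrix(ds, c(models, "A11111111111111"),
                                  "antagonist")
  auc_ag <- surrogate_auc_matrix(ds, c(models, "A11111111111111"), "agonist")
  ant <- evaluate_all_models(auc_ant, "A11111111111111", mode = "antagonist")
  ag <- evaluate_all_models(auc_ag, "A11111111111111", mode = "agonist")
  expect_gt(length(qualify_models(ant)), 0)
  for (k in 5:7) {
    bat <- constrained_battery_search(ag, ant, k)
    expect_true(all(c("A12", "A13", "A14") %in% bat$assays))
  }
})

test_that("assay exclusion with an empty set reproduces the global qualification", {
  set.seed(12)
  ag <- make_summaries(rand_models(30), runif(30), runif(30))
  ant <- make_summaries(rand_models(30), runif(30), runif(30))
  crit <- qualification_criteria(0.5, 0.5)
  res <- exclude_assay_analysis(ag, ant, character(0), crit)
  expect_equal(res$agonist$max_sensitivity, max(ag$sensitivity))
  expect_equal(res$antagonist$qualifying, qualify_models(ant, crit))
})

test_that("assay exclusion equals brute-force filter-then-qualify", {
  set.seed(14)
  ag <- make_summaries(rand_models(50), runif(50), runif(50))
  ant <- make_summaries(rand_models(50), runif(50), runif(50))
  crit <- qualification_criteria(0.6, 0.4)
  excluded <- c("A1", "A2", "A3")
  res <- exclude_assay_analysis(ag, ant, excluded, crit)
  for (mode in c("agonist", "antagonist")) {
    s <- if (mode == "agonist") ag else ant
    keep <- !vapply(s$model_name, function(m)
      any(excluded %in% model_assays(m)), logical(1))
    expect_equal(res[[mode]]$max_sensitivity, max(s$sensitivity[keep]))
    expect_equal(res[[mode]]$qualifying, qualify_models(s[keep, ], crit))
  }
})

test_that("losing all receptor-binding assays breaks agonism but not antagonism detection", {
  # generator scenario in which part of the agonists are detected only by a
  # receptor-binding assay
  cfg <- small_config(n_chemicals = 600L,
                      agonist_detectors = c("A2", "A9", "A11"))
  ds <- generate_synthetic_dataset(cfg, seed = 17)
  models <- enumerate_subset_models(min_size = 2, include_full = FALSE)
  ant <- evaluate_all_models(
    surrogate_auc_matrix(ds, c(models, "A11111111111111"), "antagonist"),
    "A11111111111111", mode = "antagonist")
  ag <- evaluate_all_models(
    surrogate_auc_matrix(ds, c(models, "A11111111111111"), "agonist"),
    "A11111111111111", mode = "agonist")
  res <- exclude_assay_analysis(ag, ant, c("A1", "A2", "A3"))
  expect_lt(res$agonist$max_sensitivity, 0.95)
  expect_gt(res$antagonist$max_sensitivity, 0.95)
})
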