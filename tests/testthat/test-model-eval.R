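test_that("AUC binarization uses an inclusive 0.1 cutoff", {
  expect_equal(binarize_auc(c(0, 0.099, 0.1, 0.5)), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_auc(0.25, cutoff = 0.3), 0L)
  expect_error(binarize_auc(-0.1), "non-negative")
  expect_error(binarize_auc(0.5, cutoff = 0), "positive")
})

test_that("confusion reproduces hand-tabulated counts and metrics", {
  pred <- c(1, 1, 0, 0, 1, 0, 0, 0)
  ref <- c(1, 0, 1, 0, 1, 0, 0, 1)
  cs <- confusion(pred, ref)
  bc <- brute_confusion(pred, ref)
  expect_equal(cs$tp, unname(bc$tp))
  expect_equal(cs$fp, unname(bc$fp))
  expect_equal(cs$tn, unname(bc$tn))
  expect_equal(cs$fn, unname(bc$fn))
  expect_equal(cs$sensitivity, 2 / 4)
  expect_equal(cs$specificity, 3 / 4)
  expect_equal(cs$balanced_accuracy, (0.5 + 0.75) / 2)

  perfect <- confusion(ref, ref)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mcc, 1)
})

test_that("the worked sensitivity example holds: 238 of 250", {
  cs <- confusion_from_counts(tp = 238, fn = 12, fp = 100, tn = 1470)
  expect_equal(cs$sensitivity, 0.952)
})

test_that("MCC is symmetric, zero-denominator-safe and matches the printed agreement values", {
  fx <- ar_fixtures()
  ant <- confusion(fx$table1_antagonist$calls_11, fx$table1_antagonist$calls_14)
  ag <- confusion(fx$table1_agonist$calls_11, fx$table1_agonist$calls_14)
  expect_equal(round(ant$mcc, 2), 0.79)
  # exact recomputation from the table cells gives 0.6856;
  # the printed value is 0.68
  expect_lt(abs(ag$mcc - 0.68), 0.01)
  # symmetry under swapping predicted and reference
  ant_sw <- confusion(fx$table1_antagonist$calls_14,
                      fx$table1_antagonist$calls_11)
  expect_equal(ant$mcc, ant_sw$mcc)
  # all-negative vectors: every marginal empty on the positive side
  expect_equal(confusion(rep(0, 5), rep(0, 5))$mcc, 0)
})

test_that("agreement tables recover the printed two-model comparison", {
  fx <- ar_fixtures()
  ant <- agreement_table(fx$table1_antagonist$calls_11,
                         fx$table1_antagonist$calls_14)
  expect_equal(ant$both_active, 173L)
  expect_equal(ant$b_only, 74L)
  expect_equal(ant$a_only, 10L)
  expect_equal(ant$both_inactive, 1560L)
  expect_equal(ant$agreement, 1733L)
  expect_equal(ant$n, 1817L)
  ag <- agreement_table(fx$table1_agonist$calls_11,
                        fx$table1_agonist$calls_14)
  expect_equal(ag$agreement, 1798L)
  # exact recomputation from the table cells gives 0.6856;
  # the printed value is 0.68
  expect_lt(abs(ag$mcc - 0.68), 0.01)
  ident <- agreement_table(c(a = 1, b = 0), c(a = 1, b = 0))
  expect_equal(ident$agreement, 2L)
})

test_that("mismatching chemical sets are an alignment error; align_calls intersects", {
  a <- c(x1 = 1, x2 = 0, x3 = 1)
  b <- c(x2 = 1, x3 = 0, x4 = 1)
  expect_error(confusion(a, b), "x4")
  al <- align_calls(a, b)
  expect_equal(names(al$a), c("x2", "x3"))
  expect_equal(al$dropped_a, "x1")
  expect_equal(al$dropped_b, "x4")
  expect_s3_class(confusion(al$a, al$b), "confusion_summary")
})

test_that("evaluate_all_models matches a hand-set three-model toy table", {
  chems <- paste0("c", 1:4)
  ref_auc <- c(0.5, 0.2, 0.05, 0.0)   # calls 1 1 0 0
  m1_auc <- c(0.4, 0.15, 0.02, 0.0)   # calls 1 1 0 0 -> perfect
  m2_auc <- c(0.4, 0.05, 0.3, 0.0)    # calls 1 0 1 0 -> tp1 fn1 fp1 tn1
  tab <- data.frame(
    chemical_id = rep(chems, 3),
    model_name = rep(c("A11111111111111", "A10000000000000",
                       "A01000000000000"), each = 4),
    mode = "antagonist",
    auc = c(ref_auc, m1_auc, m2_auc)
  )
  out <- evaluate_all_models(tab, "A11111111111111", mode = "antagonist")
  expect_equal(nrow(out), 2L)
  m1 <- out[out$model_name == "A10000000000000", ]
  expect_equal(c(m1$tp, m1$fp, m1$tn, m1$fn), c(2L, 0L, 2L, 0L))
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$mcc, 1)
  m2 <- out[out$model_name == "A01000000000000", ]
  expect_equal(c(m2$tp, m2$fp, m2$tn, m2$fn), c(1L, 1L, 1L, 1L))
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)
  expect_equal(m2$mcc, 0)
  expect_error(evaluate_all_models(tab, "A00000000000011"), "not present")
})

test_that("evaluate_all_models equals independent per-model re-tabulation on synthetic data", {
  ds <- generate_synthetic_dataset(small_config(), seed = 7)
  models <- c("A11111111111111", rand_models(25, seed = 11))
  for (mode in c("agonist", "antagonist")) {
    auc <- surrogate_auc_matrix(ds, models, mode)
    out <- evaluate_all_models(auc, "A11111111111111", mode = mode)
    ref_calls <- binarize_auc(auc[, "A11111111111111"])
    for (m in setdiff(models, "A11111111111111")) {
      bc <- brute_confusion(binarize_auc(auc[, m]), ref_calls)
      row <- out[out$model_name == m, ]
      expect_equal(c(row$tp, row$fp, row$tn, row$fn),
                   unname(c(bc$tp, bc$fp, bc$tn, bc$fn)))
    }
    # a model sharing the reference's AUCs scores perfectly
    auc2 <- cbind(auc, A99 = auc[, "A11111111111111"])
    colnames(auc2)[ncol(auc2)] <- "A11111111111110"
    out2 <- evaluate_all_models(auc2, "A11111111111111", mode = mode)
    twin <- out2[out2$model_name == "A11111111111110", ]
    expect_equal(twin$sensitivity, 1)
    expect_equal(twin$specificity, 1)
  }
})

test_that("metrics are invariant to chemical ordering of the AUC table", {
  ds <- generate_synthetic_dataset(small_config(n_chemicals = 80L), seed = 3)
  models <- c("A11111111111111", rand_models(10, seed = 5))
  auc <- surrogate_auc_matrix(ds, models, "antagonist")
  perm <- sample(nrow(auc))
  out1 <- evaluate_all_models(auc, "A11111111111111")
  out2 <- evaluate_all_models(auc[perm, ], "A11111111111111")
  expect_equal(out1, out2)
})

test_that("qualification is strict by default and monotone in the criteria", {
  summaries <- data.frame(
    model_name = c("A11000000000000", "A10100000000000", "A10010000000000"),
    sensitivity = c(0.952, 0.95, 0.96),
    specificity = c(0.934, 0.99, 0.84)
  )
  expect_equal(qualify_models(summaries), "A11000000000000")
  # boundary: exactly 0.95 fails strict, passes inclusive
  incl <- qualification_criteria(strict = FALSE)
  expect_true("A10100000000000" %in% qualify_models(summaries, incl))
  # brute-force filter equality and monotonicity on random summaries
  set.seed(9)
  rs <- data.frame(model_name = rand_models(40),
                   sensitivity = runif(40), specificity = runif(40))
  for (th in list(c(0.5, 0.5), c(0.7, 0.3), c(0.9, 0.8))) {
    crit <- qualification_criteria(th[1], th[2])
    expect_equal(qualify_models(rs, crit),
                 rs$model_name[rs$sensitivity > th[1] &
                                 rs$specificity > th[2]])
  }
  loose <- qualify_models(rs, qualification_criteria(0.5, 0.5))
  tight <- qualify_models(rs, qualification_criteria(0.8, 0.6))
  expect_true(all(tight %in% loose))
})

test_that("assay prevalence counts model membership fractions", {
  # 109 qualifying models, 47 of which contain A14
  set.seed(13)
  with_a14 <- replicate(47, {
    bits <- integer(14); bits[14] <- 1L
    bits[sample(1:13, 3)] <- 1L
    paste0("A", paste(bits, collapse = ""))
  })
  without_a14 <- replicate(62, {
    bits <- integer(14)
    bits[sample(1:13, 4)] <- 1L
    paste0("A", paste(bits, collapse = ""))
  })
  prev <- assay_prevalence(c(with_a14, without_a14))
  expect_equal(round(100 * prev[["A14"]], 2), 43.12)
  all_contain <- rep("A10000000000011", 5)
  expect_equal(assay_prevalence(all_contain)[["A1"]], 1)
  expect_equal(assay_prevalence(all_contain)[["A2"]], 0)
  expect_error(assay_prevalence(character(0)), "empty")
})

test_that("leave-one-assay-out maxima equal a brute-force scan", {
  ds <- generate_synthetic_dataset(small_config(), seed = 21)
  models <- enumerate_subset_models(min_size = 10, include_full = FALSE)
  auc <- surrogate_auc_matrix(ds, c(models, "A11111111111111"), "antagonist")
  summaries <- evaluate_all_models(auc, "A11111111111111")
  mm <- model_membership(summaries$model_name)
  for (a in c("A1", "A7", "A12")) {
    res <- leave_one_out_max_sensitivity(summaries, a)
    keep <- mm[, a] == 0L
    expect_equal(res$max_sensitivity, max(summaries$sensitivity[keep]))
    expect_true(all(model_membership(res$models)[, a] == 0L))
  }
  # excluding an assay absent from the best model leaves the max unchanged
  best <- summaries$model_name[which.max(summaries$sensitivity)]
  absent <- setdiff(assay_ids(), model_assays(best))[1]
  res <- leave_one_out_max_sensitivity(summaries, absent)
  expect_equal(res$max_sensitivity, max(summaries$sensitivity))
  expect_error(leave_one_out_max_sensitivity(summaries, assay_ids()),
               "no subset models")
})

test_that("reference-chemical truth sets flow through the same confusion op", {
  # in-vivo-style reference set: 12 actives all detected, 23 of 27
  # inactives correctly negative
  truth <- c(rep(1L, 12), rep(0L, 27))
  pred <- c(rep(1L, 12), rep(1L, 4), rep(0L, 23))
  names(truth) <- names(pred) <- sprintf("REF%02d", seq_along(truth))
  cs <- confusion(pred, truth)
  expect_equal(cs$sensitivity, 1.0)
  expect_equal(round(100 * cs$specificity, 1), 85.2)
})
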