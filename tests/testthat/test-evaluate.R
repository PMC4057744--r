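# classification statistics and leave-one-out cross-validation

test_that("MCC handles perfect, inverted and degenerate matrices", {
  expect_identical(as.numeric(mcc(confusion_counts(10, 0, 0, 7))), 1)
  expect_identical(as.numeric(mcc(confusion_counts(0, 10, 7, 0))), -1)
  one_class <- mcc(confusion_counts(5, 3, 0, 0))
  expect_identical(as.numeric(one_class), 0)
  expect_true(attr(one_class, "degenerate"))
})

test_that("sensitivity/specificity follow their definitions with sentinels", {
  cm <- confusion_counts(6, 2, 4, 8)
  expect_equal(sensitivity_specificity(cm),
               c(sensitivity = 0.6, specificity = 0.8))
  # symmetric matrix: the two coincide
  expect_equal(unname(diff(sensitivity_specificity(confusion_counts(7, 3, 3, 7)))), 0)
  no_neg <- sensitivity_specificity(confusion_counts(5, 0, 0, 0))
  expect_true(is.na(no_neg[["specificity"]]))
})

test_that("chi-squared equals n * MCC^2 and matches the Pearson statistic", {
  cm <- confusion_counts(60, 25, 33, 41)
  expect_equal(chi_squared_vs_random(cm),
               cm$total * as.numeric(mcc(cm))^2, tolerance = 1e-9)
  pearson <- suppressWarnings(stats::chisq.test(
    matrix(c(60, 25, 33, 41), 2, byrow = TRUE), correct = FALSE))
  expect_equal(chi_squared_vs_random(cm), unname(pearson$statistic))
  # n * phi^2 scaling: multiplying all counts by 10 scales the statistic
  cm10 <- confusion_counts(600, 250, 330, 410)
  expect_equal(chi_squared_vs_random(cm10), 10 * chi_squared_vs_random(cm))
  expect_identical(chi_squared_vs_random(confusion_counts(5, 5, 5, 5)), 0)
})

test_that("confusion_matrix counts calls correctly", {
  cm <- confusion_matrix(c("D", "D", "N", "N", "D"),
                         c("D", "N", "D", "N", "D"))
  expect_identical(cm[c("tp", "fp", "fn", "tn")],
                   list(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  expect_error(confusion_matrix("X", "D"), "\"D\" or \"N\"")
})

test_that("ROC/AUC: separation, complement identity, chance level", {
  sep <- roc_auc(c(5, 6, 7, 1, 2, 3), c("D", "D", "D", "N", "N", "N"))
  expect_identical(sep$auc, 1)
  expect_equal(sep$curve[1, ], data.frame(fpr = 0, tpr = 0))
  flip <- roc_auc(c(5, 6, 7, 1, 2, 3), c("N", "N", "N", "D", "D", "D"))
  expect_equal(sep$auc + flip$auc, 1)
  set.seed(41)
  scores <- rnorm(4000)
  labels <- sample(c("D", "N"), 4000, replace = TRUE)
  expect_equal(roc_auc(scores, labels)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:3, c("D", "D", "D")), "both classes")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (rep in 1:5) {
    n <- 60
    labels <- sample(c("D", "N"), n, replace = TRUE, prob = c(0.4, 0.6))
    scores <- rnorm(n) + (labels == "D")  # overlapping classes with ties
    scores <- round(scores, 1)
    ours <- roc_auc(scores, labels)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("N", "D"),
      direction = "<")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("MCC sweep covers the score range and finds the peak", {
  set.seed(59)
  scores <- c(rnorm(300, 1), rnorm(300, -1))
  labels <- rep(c("D", "N"), each = 300)
  sw <- mcc_sweep(scores, labels)
  expect_true(min(sw$cutoff) < min(scores) && max(sw$cutoff) > max(scores))
  # symmetric two-normal scores centred at +-1: peak near 0
  expect_lt(abs(attr(sw, "peak")), 0.35)
  # cut-off below every score predicts all deleterious -> degenerate MCC 0
  expect_identical(sw$mcc[1], 0)
  expect_error(mcc_sweep(rep(1, 4), c("D", "D", "N", "N")), "distinct")
})

test_that("leave-one-out folds exclude the held-out variant and filter genes", {
  p1 <- generate_panel(synth_config(n_deleterious = 3, n_neutral = 3,
                                    gene = "G1"), seed = 6)
  p2 <- generate_panel(synth_config(n_deleterious = 2, n_neutral = 9,
                                    gene = "G2"), seed = 7)
  loo <- loo_cv(list(G1 = p1, G2 = p2), control = test_control(), seed = 3)
  expect_identical(nrow(loo$predictions), 6L)   # 3+3 folds for G1 only
  # every fold trained on the remaining 5 variants (2+3 or 3+2)
  expect_true(all(loo$predictions$fold_train_d +
                    loo$predictions$fold_train_n == 5L))
  expect_identical(sort(unique(loo$predictions$fold_train_d)), c(2L, 3L))
  expect_identical(loo$excluded$gene, "G2")
  expect_match(loo$excluded$reason, "insufficient deleterious")
  # reproducible under the master seed
  loo2 <- loo_cv(list(G1 = p1, G2 = p2), control = test_control(), seed = 3)
  expect_identical(loo$predictions$gm, loo2$predictions$gm)
  expect_error(loo_cv(list(G2 = p2), control = test_control()),
               "no gene passed")
})

test_that("compression adjustment does not hurt ranking on noisy panels", {
  # conserved columns carry substitution noise, so their diversity is
  # apparent rather than real; discounting it by compressibility should
  # rank deleterious variants at least as well as the unadjusted metric
  panel <- generate_panel(synth_config(noise = 0.1), seed = 4)
  adj <- evaluation_report(loo_cv(list(S = panel), r = 2.47,
                                  control = test_control(), seed = 104))
  raw <- evaluation_report(loo_cv(list(S = panel), r = 0,
                                  control = test_control(), seed = 104))
  expect_gte(adj$auc, raw$auc)
})
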