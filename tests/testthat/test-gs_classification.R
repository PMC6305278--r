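test_that("one-vs-rest labelling and its contracts", {
  expect_equal(one_vs_rest_labels(c(1, 2, 3, 1), 1), c(1L, 0L, 0L, 1L))
  lab <- one_vs_rest_labels(rep(1:3, c(5, 3, 2)), 3)
  expect_equal(sum(lab == 1), 2)
  expect_length(lab, 10)
  expect_error(one_vs_rest_labels(c(1, 2), 5), "absent")
  expect_error(one_vs_rest_labels(c(3, 3, 3), 3), "no negatives")
})

test_that("AUC equals the Mann-Whitney pairwise probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(3)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # with ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("cross-validation partitions are stratified and metrics consistent", {
  tab <- separable_table(n = 60)
  cfg <- rf_config(n_trees = 100, seed = 0)
  cv <- crossval_rf(tab, 1, cfg)
  # every patient in exactly one test fold; fold sizes differ by <= 1
  expect_length(cv$fold, 60)
  expect_true(all(table(cv$fold) %in% c(12)))
  for (k in 1:5) {
    expect_true(all(table(cv$labels[cv$fold == k]) >= 1))
  }
  # pooled confusion matrix covers everyone; accuracy identity
  expect_equal(sum(cv$confusion), 60)
  tn <- cv$confusion["0", "0"]; tp <- cv$confusion["1", "1"]
  fn <- cv$confusion["1", "0"]; fp <- cv$confusion["0", "1"]
  pooled_acc <- (tp + tn) / 60
  expect_equal(pooled_acc,
               mean(as.integer(cv$oof_scores >= 0.5) == cv$labels))
  if (tn + fn > 0) {
    expect_equal(unname(tn / (tn + fn)),
                 unname(gsradiomics:::binary_metrics(cv$oof_scores,
                                                     cv$labels)$npv))
  }
  # a label-copy feature makes the task near-perfectly separable
  expect_gte(cv$mean_metrics[["auc"]], 0.95)
  # determinism under a fixed seed
  cv2 <- crossval_rf(tab, 1, cfg)
  expect_equal(cv$oof_scores, cv2$oof_scores)
  expect_equal(cv$mean_metrics, cv2$mean_metrics)
})

test_that("label-permuted cross-validation hovers at chance AUC", {
  tab <- separable_table(n = 40, p_noise = 10)
  set.seed(17)
  aucs <- replicate(10, {
    perm <- feature_table(feature_matrix(tab), tab$patient_id,
                          sample(tab$group))
    cv <- crossval_rf(perm, 1, rf_config(n_trees = 60,
                                         seed = sample.int(1e6, 1)))
    cv$mean_metrics[["auc"]]
  })
  expect_true(abs(mean(aucs) - 0.5) < 0.1)
})

test_that("hold-out draws are balanced, disjoint, and separable cohorts score high", {
  tab <- separable_table(n = 70)
  ho <- holdout_rf(tab, 1, n_train = 40, n_test = 20,
                   cfg = rf_config(n_trees = 100, seed = 0))
  expect_length(intersect(ho$train_ids, ho$test_ids), 0)
  expect_equal(sum(tab$group[match(ho$train_ids, tab$patient_id)] == 1), 20)
  expect_equal(sum(tab$group[match(ho$test_ids, tab$patient_id)] == 1), 10)
  expect_equal(ho$n_unused, 10)
  expect_gte(ho$metrics$auc, 0.9)
  expect_error(holdout_rf(separable_table(n = 20), 1), "per class")
})

test_that("permutation importance finds the label copy and is name-stable", {
  tab <- separable_table(n = 60)
  cfg <- rf_config(n_trees = 200, seed = 0)
  imp <- permutation_importance(crossval_rf(tab, 1, cfg))
  expect_length(imp, 41)
  expect_equal(names(which.max(imp)), "label_copy")
  expect_gt(imp[["label_copy"]], 0)
  # reordering the noise columns does not dethrone the label copy
  m <- feature_matrix(tab)
  perm <- c(1, 1 + sample(40))
  tab2 <- feature_table(m[, perm], tab$patient_id, tab$group)
  imp2 <- permutation_importance(crossval_rf(tab2, 1, cfg))
  expect_equal(names(which.max(imp2)), "label_copy")
})

test_that("under permuted labels no feature is systematically important", {
  tab <- separable_table(n = 40, p_noise = 10)
  set.seed(29)
  imps <- replicate(10, {
    perm <- feature_table(feature_matrix(tab), tab$patient_id,
                          sample(tab$group))
    permutation_importance(
      crossval_rf(perm, 1, rf_config(n_trees = 60,
                                     seed = sample.int(1e6, 1))))
  })
  # per-feature mean normalized importance stays well inside the
  # single-replicate spread, and positives are not systematic (one-sided
  # sign test across replicates x features)
  expect_lt(max(abs(rowMeans(imps))), sd(imps))
  expect_gt(binom.test(sum(imps > 0), length(imps),
                       alternative = "greater")$p.value, 0.01)
})

test_that("modality comparison requires aligned tables and ranks modalities", {
  # only the "T2" table carries signal; "ADC" is noise
  set.seed(0)
  n <- 70
  group <- rep(1:2, each = n / 2)
  signal <- cbind(sig = as.numeric(group == 1) + rnorm(n, sd = 0.1),
                  matrix(rnorm(n * 5), n))
  noise <- matrix(rnorm(n * 6), n)
  colnames(noise) <- colnames(signal) <- c("sig", paste0("f", 1:5))
  ids <- sprintf("P%02d", 1:n)
  t2 <- feature_table(signal, ids, group)
  adc <- feature_table(noise, ids, group)
  mean_tab <- feature_table((signal + noise) / 2, ids, group)
  res <- run_modality_comparison(list(mean = mean_tab, T2 = t2, ADC = adc),
                                 rf_config(n_trees = 100, seed = 0))
  m <- res$metrics
  t2_auc <- m$auc[m$modality == "T2" & m$task == "G1-vs-rest"]
  adc_auc <- m$auc[m$modality == "ADC" & m$task == "G1-vs-rest"]
  expect_gt(t2_auc, adc_auc)
  expect_equal(dim(res$importance$T2), c(6, 2))

  misaligned <- feature_table(noise[n:1, ], rev(ids), rev(group))
  expect_error(run_modality_comparison(list(mean = mean_tab, T2 = misaligned)),
               "not aligned")
})
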