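make_fm <- function(n_a, n_b, p = 12, seed = 1, sep = 0) {
  set.seed(seed)
  n <- n_a + n_b
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("P%03d", 1:n), sprintf("f%02d", 1:p)))
  labels <- c(rep("ASD", n_a), rep("DD", n_b))
  x[labels == "ASD", 1] <- x[labels == "ASD", 1] + sep
  structure(list(x = x, labels = setNames(labels, rownames(x)),
                 dataset_kind = "gene_dosage"), class = "feature_matrix")
}

test_that("class balancing downsamples the majority deterministically", {
  fm <- make_fm(10, 7)
  bal <- balance_classes(fm, seed = 4)
  expect_equal(as.integer(table(bal$labels)[c("ASD", "DD")]), c(7L, 7L))
  bal2 <- balance_classes(fm, seed = 4)
  expect_identical(rownames(bal$x), rownames(bal2$x))
  # already balanced input passes through (up to row order)
  fm_b <- make_fm(7, 7)
  expect_setequal(rownames(balance_classes(fm_b, seed = 1)$x),
                  rownames(fm_b$x))
  # a single-class matrix is rejected
  fm_one <- fm
  fm_one$labels[] <- "ASD"
  expect_error(balance_classes(fm_one, seed = 1), "2 classes")
})

test_that("train/test split is stratified, disjoint and exhaustive", {
  fm <- make_fm(10, 10)
  spl <- split_train_test(fm, 0.7, seed = 2)
  expect_equal(as.integer(table(spl$train$labels)), c(7L, 7L))
  expect_equal(as.integer(table(spl$test$labels)), c(3L, 3L))
  expect_length(intersect(rownames(spl$train$x), rownames(spl$test$x)), 0)
  expect_setequal(c(rownames(spl$train$x), rownames(spl$test$x)),
                  rownames(fm$x))
  spl2 <- split_train_test(fm, 0.7, seed = 2)
  expect_identical(rownames(spl$train$x), rownames(spl2$train$x))
  # the cohort-scale arithmetic: 1318/1318 -> 923+923 / 395+395
  expect_equal(round(0.7 * 1318), 923)
  fm_big <- make_fm(1318, 1318, p = 2)
  spl3 <- split_train_test(fm_big, 0.7, seed = 1)
  expect_equal(nrow(spl3$train$x), 1846)
  expect_equal(nrow(spl3$test$x), 790)
})

test_that("wrapper selection thresholds normalized importances", {
  fm <- make_fm(60, 60, p = 8, sep = 2)
  # threshold zero keeps every feature
  keep_all <- select_features(fm, threshold = 0, seed = 1)
  expect_setequal(keep_all, colnames(fm$x))
  # the planted discriminative feature survives a strict threshold
  keep <- select_features(fm, threshold = 0.15, seed = 1)
  expect_true("f01" %in% keep)
  expect_lt(length(keep), 8)
  # an impossible threshold falls back to the top 10 with a warning
  expect_warning(fb <- select_features(fm, threshold = 2, seed = 1),
                 "top 10")
  expect_equal(length(fb), 8)
})

test_that("per-repetition metrics are consistent with the confusion matrix", {
  fm <- make_fm(40, 40, sep = 1.5)
  ex <- run_experiment(fm, experiment_config(n_repetitions = 4, n_trees = 60,
                                             seed = 9))
  pr <- ex$per_repetition
  expect_equal(nrow(pr), 4)
  # counts tile the test set
  expect_true(all(pr$tn + pr$fp + pr$fn + pr$tp == 24))
  # recompute every derived metric from the stored counts
  expect_equal(pr$acc_test, (pr$tp + pr$tn) / 24, tolerance = 1e-12)
  expect_equal(pr$pos_precision, pr$tp / (pr$tp + pr$fp), tolerance = 1e-12)
  expect_equal(pr$pos_recall, pr$tp / (pr$tp + pr$fn), tolerance = 1e-12)
  expect_equal(pr$neg_precision, pr$tn / (pr$tn + pr$fn), tolerance = 1e-12)
  expect_equal(pr$neg_recall, pr$tn / (pr$tn + pr$fp), tolerance = 1e-12)
  expect_equal(pr$pos_f1,
               2 * pr$pos_precision * pr$pos_recall /
                 (pr$pos_precision + pr$pos_recall), tolerance = 1e-12)
  expect_true(all(pr$auc >= 0 & pr$auc <= 1))
  # aggregates are the sample mean/sd of the stored repetitions
  agg <- ex$aggregate
  expect_equal(agg$mean[agg$metric == "acc_test"], mean(pr$acc_test))
  expect_equal(agg$sd[agg$metric == "acc_test"], sd(pr$acc_test))
})

test_that("experiments are reproducible bit for bit under a master seed", {
  fm <- make_fm(30, 30, sep = 1)
  cfg <- experiment_config(n_repetitions = 3, n_trees = 40, seed = 123)
  e1 <- run_experiment(fm, cfg)
  e2 <- run_experiment(fm, cfg)
  expect_identical(e1$per_repetition, e2$per_repetition)
  expect_identical(e1$selected, e2$selected)
  e3 <- run_experiment(fm, experiment_config(n_repetitions = 3, n_trees = 40,
                                             seed = 124))
  expect_false(identical(e1$per_repetition, e3$per_repetition))
})

test_that("single and duplicated repetitions give zero spread", {
  fm <- make_fm(30, 30, sep = 1)
  ex <- run_experiment(fm, experiment_config(n_repetitions = 1, seed = 3))
  expect_true(all(ex$aggregate$sd == 0))
  s <- summarize_experiment(ex)
  expect_equal(s$mean[s$metric == "acc_test"],
               100 * ex$per_repetition$acc_test)
})

test_that("fully separable synthetic cohorts are classified almost perfectly", {
  co <- generate_separable_cohort(
    synthetic_config(n_per_class = 150, seed = 71), effect = 1)
  fm <- gene_features(co)
  ex <- run_experiment(fm, experiment_config(n_repetitions = 3, seed = 5))
  expect_gte(mean(ex$per_repetition$acc_test), 0.90)
  expect_gt(mean(ex$per_repetition$auc), 0.97)
})

test_that("label-shuffled features never classify above 55%", {
  accs <- vapply(1:20, function(s) {
    co <- generate_separable_cohort(
      synthetic_config(n_per_class = 400, seed = 200 + s), effect = 0.6)
    fm <- gene_features(co)
    set.seed(s)
    fm$labels <- setNames(sample(fm$labels), names(fm$labels))
    ex <- run_experiment(fm, experiment_config(n_repetitions = 3,
                                               n_trees = 60, seed = s))
    mean(ex$per_repetition$acc_test)
  }, numeric(1))
  expect_true(all(accs <= 0.55))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("GO features match gene accuracy with fewer selected features", {
  acc_gene <- acc_go <- nf_gene <- nf_go <- numeric(10)
  for (s in 1:10) {
    co <- generate_separable_cohort(
      synthetic_config(n_per_class = 200, seed = 300 + s), effect = 1)
    eg <- run_experiment(gene_features(co),
                         experiment_config(n_repetitions = 2, seed = s))
    et <- run_experiment(suppressWarnings(go_features(co)),
                         experiment_config(n_repetitions = 2, seed = s))
    acc_gene[s] <- mean(eg$per_repetition$acc_test)
    acc_go[s] <- mean(et$per_repetition$acc_test)
    nf_gene[s] <- mean(eg$per_repetition$n_features)
    nf_go[s] <- mean(et$per_repetition$n_features)
  }
  expect_lt(abs(mean(acc_go) - mean(acc_gene)), 0.05)
  expect_lt(mean(nf_go), mean(nf_gene))
})
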