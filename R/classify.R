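# Repeated balanced Random-Forest differential diagnosis: class balancing,
# stratified 70/30 splits, threshold-based wrapper feature selection, and
# aggregation of per-repetition confusion-matrix metrics.

#' Configuration for the repeated classification experiment
#'
#' @param n_repetitions number of repetitions of the balance / split /
#'   select / train / test cycle (default 100).
#' @param train_fraction fraction of each class used for training
#'   (default 0.7).
#' @param selection_threshold minimum normalized Random-Forest feature
#'   importance (importances scaled to sum 1) for a feature to be kept
#'   (default 1e-3).
#' @param n_trees trees per forest (default 100).
#' @param mtry features tried per split; `NULL` for the classification
#'   default `sqrt(p)`.
#' @param positive_class label treated as positive when computing the
#'   confusion matrix and AUC; `NULL` picks `"ASD"` when present, else the
#'   last class level.
#' @param seed master seed from which per-repetition seeds are derived.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_repetitions = 100, train_fraction = 0.7,
                              selection_threshold = 1e-3, n_trees = 100,
                              mtry = NULL, positive_class = NULL,
                              seed = 1L) {
  stopifnot(n_repetitions >= 1, train_fraction > 0, train_fraction < 1,
            selection_threshold >= 0, n_trees >= 1)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 train_fraction = train_fraction,
                 selection_threshold = selection_threshold,
                 n_trees = as.integer(n_trees), mtry = mtry,
                 positive_class = positive_class, seed = as.integer(seed)),
            class = "experiment_config")
}

.two_classes <- function(fm) {
  cls <- sort(unique(fm$labels))
  if (length(cls) != 2) {
    stop("expected exactly 2 classes, found: ", paste(cls, collapse = ", "))
  }
  cls
}

.subset_fm <- function(fm, rows) {
  fm$x <- fm$x[rows, , drop = FALSE]
  fm$labels <- fm$labels[rows]
  fm
}

#' Balance classes by random downsampling
#'
#' Randomly downsamples the majority class to the minority class size, so
#' the subsequent split and training see an equal class distribution.
#'
#' @param fm a `feature_matrix` with two classes.
#' @param seed integer seed (deterministic resampling).
#' @return A balanced `feature_matrix`.
#' @export
balance_classes <- function(fm, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  cls <- .two_classes(fm)
  set.seed(seed)
  n <- table(fm$labels)[cls]
  n_min <- min(n)
  keep <- unlist(lapply(cls, function(cl) {
    rows <- which(fm$labels == cl)
    if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
  }))
  .subset_fm(fm, sort(keep))
}

#' Stratified train/test split
#'
#' Splits a balanced feature matrix into disjoint, exhaustive train and test
#' sets, stratified by class with `round(train_fraction * class size)`
#' training rows per class.
#'
#' @param fm a `feature_matrix`.
#' @param train_fraction fraction per class assigned to training.
#' @param seed integer seed.
#' @return A list with `train` and `test` feature matrices.
#' @export
split_train_test <- function(fm, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"),
            train_fraction > 0, train_fraction < 1)
  cls <- .two_classes(fm)
  set.seed(seed)
  train_rows <- unlist(lapply(cls, function(cl) {
    rows <- which(fm$labels == cl)
    if (length(rows) < 2) stop("class '", cl, "' has fewer than 2 rows")
    sample(rows, round(train_fraction * length(rows)))
  }))
  train_rows <- sort(train_rows)
  test_rows <- setdiff(seq_along(fm$labels), train_rows)
  list(train = .subset_fm(fm, train_rows), test = .subset_fm(fm, test_rows))
}

.fit_rf <- function(x, y, config, seed) {
  set.seed(seed)
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else
    min(config$mtry, ncol(x))
  randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                             mtry = mtry)
}

#' Wrapper feature selection by Random-Forest importance
#'
#' Fits a Random Forest on all features of the training set, normalizes the
#' impurity-decrease importances to sum 1 and keeps the features at or above
#' the threshold (single pass). An empty selection falls back to the top 10
#' features with a warning.
#'
#' @param train a training `feature_matrix`.
#' @param threshold normalized importance threshold (default 1e-3).
#' @param seed integer seed for the forest.
#' @param config an [experiment_config()] supplying the forest
#'   hyperparameters.
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(train, threshold = 1e-3, seed = 1L,
                            config = experiment_config()) {
  stopifnot(inherits(train, "feature_matrix"), nrow(train$x) > 0)
  y <- factor(train$labels)
  rf <- .fit_rf(train$x, y, config, seed)
  imp <- rf$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  imp_norm <- if (total > 0) imp / total else imp
  keep <- colnames(train$x)[imp_norm >= threshold]
  if (length(keep) == 0) {
    warning("no feature reached the importance threshold; ",
            "falling back to the top 10")
    keep <- colnames(train$x)[order(imp_norm, decreasing = TRUE)]
    keep <- keep[seq_len(min(10, length(keep)))]
  }
  keep
}

.confusion_metrics <- function(truth, pred, positive, negative) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred == negative)
  fp <- sum(truth == negative & pred == positive)
  tn <- sum(truth == negative & pred == negative)
  prec <- function(tp, fp) if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- function(tp, fn) if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- function(p, r) if (!is.na(p) && !is.na(r) && p + r > 0)
    2 * p * r / (p + r) else NA_real_
  pos_prec <- prec(tp, fp); pos_rec <- rec(tp, fn)
  neg_prec <- prec(tn, fn); neg_rec <- rec(tn, fp)
  list(tn = tn, fp = fp, fn = fn, tp = tp,
       accuracy = (tp + tn) / length(truth),
       pos_precision = pos_prec, pos_recall = pos_rec,
       pos_f1 = f1(pos_prec, pos_rec),
       neg_precision = neg_prec, neg_recall = neg_rec,
       neg_f1 = f1(neg_prec, neg_rec))
}

#' Run the repeated balanced classification experiment
#'
#' For each repetition (with a seed derived from the master seed): balance
#' the classes by downsampling, split 70/30 stratified by class, select
#' features on the training set by normalized Random-Forest importance,
#' train a Random Forest on the selected features, and evaluate the held-out
#' test set (confusion matrix, accuracy, AUC from class probabilities,
#' per-class precision/recall/F1). Aggregates are the mean and sample
#' (n-1) standard deviation over repetitions.
#'
#' @param fm a two-class `feature_matrix`.
#' @param config an [experiment_config()].
#' @return An object of class `rf_experiment` with `per_repetition` (one
#'   row per repetition), `aggregate` (mean/sd per metric), `selected`
#'   (list of selected feature ids per repetition) and the config.
#' @export
run_experiment <- function(fm, config = experiment_config()) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(config, "experiment_config"))
  cls <- .two_classes(fm)
  positive <- config$positive_class
  if (is.null(positive)) positive <- if ("ASD" %in% cls) "ASD" else cls[2]
  if (!positive %in% cls) stop("positive class '", positive, "' not present")
  negative <- setdiff(cls, positive)

  set.seed(config$seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 4L * config$n_repetitions),
                      ncol = 4)
  rows <- vector("list", config$n_repetitions)
  selected <- vector("list", config$n_repetitions)
  for (r in seq_len(config$n_repetitions)) {
    res <- tryCatch({
      bal <- balance_classes(fm, seed = rep_seeds[r, 1])
      spl <- split_train_test(bal, config$train_fraction,
                              seed = rep_seeds[r, 2])
      feats <- select_features(spl$train, config$selection_threshold,
                               seed = rep_seeds[r, 3], config = config)
      xtr <- spl$train$x[, feats, drop = FALSE]
      xte <- spl$test$x[, feats, drop = FALSE]
      ytr <- factor(spl$train$labels, levels = c(negative, positive))
      yte <- factor(spl$test$labels, levels = c(negative, positive))
      rf <- .fit_rf(xtr, ytr, config, rep_seeds[r, 4])
      pred_tr <- predict(rf, xtr)
      pred_te <- predict(rf, xte)
      prob_te <- predict(rf, xte, type = "prob")[, positive]
      m <- .confusion_metrics(yte, pred_te, positive, negative)
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = yte, predictor = prob_te,
        levels = c(negative, positive), direction = "<", quiet = TRUE)))
      list(metrics = data.frame(
        repetition = r, tn = m$tn, fp = m$fp, fn = m$fn, tp = m$tp,
        n_features = length(feats),
        acc_train = mean(pred_tr == ytr), acc_test = m$accuracy,
        auc = auc,
        neg_precision = m$neg_precision, neg_recall = m$neg_recall,
        pos_precision = m$pos_precision, pos_recall = m$pos_recall,
        neg_f1 = m$neg_f1, pos_f1 = m$pos_f1), feats = feats)
    }, error = function(e) {
      stop("repetition ", r, " failed: ", conditionMessage(e))
    })
    rows[[r]] <- res$metrics
    selected[[r]] <- res$feats
  }
  per_rep <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_rep), "repetition")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(per_rep[metric_cols], mean, numeric(1)),
    sd = vapply(per_rep[metric_cols],
                function(v) if (length(v) > 1) sd(v) else 0, numeric(1)),
    row.names = NULL)
  structure(list(per_repetition = per_rep, aggregate = aggregate,
                 selected = selected, positive_class = positive,
                 negative_class = negative, config = config,
                 dataset_kind = fm$dataset_kind),
            class = "rf_experiment")
}

#' Summarize an experiment as a metrics table
#'
#' One row per metric with the mean and sample standard deviation over
#' repetitions; accuracies, precision, recall and F1 are reported in
#' percent, counts and AUC on their own scale.
#'
#' @param report an `rf_experiment`.
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
summarize_experiment <- function(report) {
  stopifnot(inherits(report, "rf_experiment"))
  agg <- report$aggregate
  pct <- agg$metric %in% c("acc_train", "acc_test", "neg_precision",
                           "neg_recall", "pos_precision", "pos_recall",
                           "neg_f1", "pos_f1")
  agg$mean[pct] <- agg$mean[pct] * 100
  agg$sd[pct] <- agg$sd[pct] * 100
  agg
}

#' @export
print.rf_experiment <- function(x, ...) {
  n <- nrow(x$per_repetition)
  acc <- x$aggregate[x$aggregate$metric == "acc_test", ]
  nf <- x$aggregate[x$aggregate$metric == "n_features", ]
  cat(sprintf(
    "Random-Forest experiment [%s]: %d repetition(s)\n", x$dataset_kind, n))
  cat(sprintf("  positive class: %s (negative: %s)\n",
              x$positive_class, x$negative_class))
  cat(sprintf("  test accuracy: %.2f%% (sd %.2f%%)  features: %.1f (sd %.1f)\n",
              100 * acc$mean, 100 * acc$sd, nf$mean, nf$sd))
  invisible(x)
}

#' @export
summary.rf_experiment <- function(object, ...) {
  out <- summarize_experiment(object)
  class(out) <- c("summary.rf_experiment", class(out))
  out
}

#' @export
print.summary.rf_experiment <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  df$mean <- round(df$mean, 2)
  df$sd <- round(df$sd, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
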