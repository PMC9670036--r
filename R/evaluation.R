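#' Per-class confusion metrics
#'
#' One-vs-rest TP/FP/FN/TN counts per class with precision = TP/(TP+FP),
#' recall (sensitivity) = TP/(TP+FN), specificity = TN/(TN+FP), plus overall
#' accuracy. A zero denominator yields 0 with a warning.
#'
#' @param y_true,y_pred integer class labels in 1..n_classes (or factors with
#'   identical levels), equal length.
#' @param n_classes number of classes.
#' @return list with `per_class` (data frame: class, precision, recall,
#'   specificity) and `accuracy`.
#' @export
confusion_metrics <- function(y_true, y_pred, n_classes = max(y_true)) {
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred must have equal length")
  if (any(c(y_true, y_pred) < 1) || any(c(y_true, y_pred) > n_classes)) {
    stop("labels out of range")
  }
  safe_div <- function(a, b, what, cl) {
    if (b == 0) {
      warning(sprintf("%s undefined for class %d (zero denominator); returning 0", what, cl))
      return(0)
    }
    a / b
  }
  rows <- lapply(seq_len(n_classes), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    data.frame(class = cl,
               precision = safe_div(tp, tp + fp, "precision", cl),
               recall = safe_div(tp, tp + fn, "recall", cl),
               specificity = safe_div(tn, tn + fp, "specificity", cl))
  })
  list(per_class = do.call(rbind, rows), accuracy = mean(y_true == y_pred))
}

# One-vs-rest ROC by threshold sweep over the unique scores; trapezoidal AUC
# (equals the rank-statistic with midpoint ties).
roc_curve_binary <- function(truth, score) {
  thr <- sort(unique(score), decreasing = TRUE)
  P <- sum(truth); N <- sum(!truth)
  tpr <- c(0, vapply(thr, function(t) sum(score >= t & truth) / P, numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) sum(score >= t & !truth) / N, numeric(1)), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# One-vs-rest PR with step interpolation (conservative): AUC is the sum of
# precision at each threshold times the recall increment.
pr_curve_binary <- function(truth, score) {
  thr <- sort(unique(score), decreasing = TRUE)
  P <- sum(truth)
  rec <- vapply(thr, function(t) sum(score >= t & truth) / P, numeric(1))
  prec <- vapply(thr, function(t) {
    np <- sum(score >= t)
    if (np == 0) 1 else sum(score >= t & truth) / np
  }, numeric(1))
  auc <- sum(diff(c(0, rec)) * prec)
  list(points = data.frame(recall = c(0, rec), precision = c(1, prec)), auc = auc)
}

#' One-vs-rest ROC and PR curves with AUCs
#'
#' Curves are built by sweeping thresholds over the unique predicted scores.
#' ROC AUC is trapezoidal (so tied scores contribute at the midpoint: all
#' scores identical gives AUC 0.5); PR AUC uses step interpolation. A class
#' absent from the truth is skipped with a warning.
#'
#' @param y_true integer labels in 1..n_classes (or a factor).
#' @param scores matrix of per-class probabilities, one column per class.
#' @return list with one element per class: `roc` (points + auc) and `pr`
#'   (points + auc), or NULL for skipped classes.
#' @export
roc_pr_curves <- function(y_true, scores) {
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  scores <- as.matrix(scores)
  if (length(y_true) != nrow(scores)) stop("y_true and scores must align")
  out <- vector("list", ncol(scores))
  names(out) <- colnames(scores) %||% paste0("class", seq_len(ncol(scores)))
  for (cl in seq_len(ncol(scores))) {
    truth <- y_true == cl
    if (!any(truth)) {
      warning(sprintf("class %d absent from y_true; curves skipped", cl))
      next
    }
    if (all(truth)) {
      warning(sprintf("class %d has no negatives; curves skipped", cl))
      next
    }
    out[[cl]] <- list(roc = roc_curve_binary(truth, scores[, cl]),
                      pr = pr_curve_binary(truth, scores[, cl]))
  }
  out
}

# Stratified fold assignment: per class, shuffled round-robin, so per-class
# fold sizes differ by at most one.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- which(labels == cl)
    if (length(ids) < n_folds) {
      stop(sprintf("class %s has %d members < %d folds; use fewer folds",
                   cl, length(ids), n_folds))
    }
    fold[sample(ids)] <- rep_len(seq_len(n_folds), length(ids))
  }
  fold
}

#' Stratified cross-validation of a slide classifier
#'
#' Splits slides into stratified folds, trains on the complement of each
#' fold and evaluates on the fold, then aggregates the per-fold metrics as
#' mean and standard deviation. Fold membership is reproducible given
#' `seed`. The trainer and predictor are injectable so the harness can be
#' exercised with any classifier; the defaults train a graph-transformer
#' with `config`.
#'
#' @param graphs list of `wsi_graph` objects.
#' @param labels class labels aligned with `graphs`.
#' @param config a [gtp_config()] for the default trainer.
#' @param n_folds number of folds (>= 2).
#' @param seed seed for fold assignment and training.
#' @param trainer `function(graphs, labels, config, seed)` returning a model.
#' @param predictor `function(model, graphs)` returning a probability matrix.
#' @return list with `folds` (per-fold list: report, auc_roc, auc_pr,
#'   fold indices), `fold_assignment`, and `aggregate` (mean and sd of
#'   accuracy and macro AUCs).
#' @export
cross_validate <- function(graphs, labels, config = gtp_config("desk"),
                           n_folds = 5L, seed = 1L,
                           trainer = NULL, predictor = NULL) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  labels <- as.factor(labels)
  n_classes <- nlevels(labels)
  if (is.null(trainer)) {
    trainer <- function(graphs, labels, config, seed) {
      cfg <- config; cfg$seed <- seed
      gtp_train(graphs, labels, cfg)
    }
  }
  if (is.null(predictor)) predictor <- function(model, graphs) predict(model, graphs)
  seeds <- derive_seeds(seed, n_folds)
  fold <- with_seed(seed, stratified_folds(as.integer(labels), n_folds))
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    model <- trainer(graphs[tr], droplevels(labels[tr]), config, seeds[f])
    P <- predictor(model, graphs[te])
    y_te <- as.integer(labels[te])
    y_hat <- max.col(P, ties.method = "first")
    rep <- confusion_metrics(y_te, y_hat, n_classes)
    curves <- roc_pr_curves(y_te, P)
    auc_roc <- vapply(curves, function(cl) if (is.null(cl)) NA_real_ else cl$roc$auc, numeric(1))
    auc_pr <- vapply(curves, function(cl) if (is.null(cl)) NA_real_ else cl$pr$auc, numeric(1))
    folds[[f]] <- list(report = rep, auc_roc = auc_roc, auc_pr = auc_pr,
                       test_idx = te, curves = curves)
  }
  acc <- vapply(folds, function(f) f$report$accuracy, numeric(1))
  mroc <- vapply(folds, function(f) mean(f$auc_roc, na.rm = TRUE), numeric(1))
  mpr <- vapply(folds, function(f) mean(f$auc_pr, na.rm = TRUE), numeric(1))
  list(folds = folds, fold_assignment = fold,
       aggregate = data.frame(
         metric = c("accuracy", "macro_auc_roc", "macro_auc_pr"),
         mean = c(mean(acc), mean(mroc), mean(mpr)),
         sd = c(stats::sd(acc), stats::sd(mroc), stats::sd(mpr))))
}
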