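#' Confusion counts of binary predictions
#'
#' Positives are druggable proteins (label 1): `tp` counts correctly
#' predicted druggable proteins, `tn` correctly predicted non-druggable
#' ones, `fn` druggable proteins missed and `fp` non-druggable proteins
#' called druggable.
#'
#' @param predicted,actual 0/1 vectors of equal length.
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual),
            all(predicted %in% c(0, 1)), all(actual %in% c(0, 1)))
  structure(list(tp = sum(predicted == 1 & actual == 1),
                 tn = sum(predicted == 0 & actual == 0),
                 fp = sum(predicted == 1 & actual == 0),
                 fn = sum(predicted == 0 & actual == 1)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and Matthews correlation
#'
#' \deqn{ACC = (tp+tn)/(tp+tn+fp+fn)}
#' \deqn{SEN = tp/(tp+fn)} \deqn{SPE = tn/(tn+fp)}
#' \deqn{MCC = (tp \cdot tn - fp \cdot fn) /
#'   \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}
#' MCC is defined as 0 when its denominator vanishes (the standard
#' convention for degenerate predictors). SEN/SPE are `NaN` when their
#' class is absent.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named numeric vector `c(ACC, SEN, SPE, MCC)`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    n <- tp + tn + fp + fn
    if (n == 0) stop("no evaluated samples")
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    c(ACC = (tp + tn) / n,
      SEN = tp / (tp + fn),
      SPE = tn / (tn + fp),
      MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
  })
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' receives a higher score than a random negative, with ties counted one
#' half. Equals the trapezoidal area under the ROC curve.
#'
#' @param scores numeric positive-class scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return data.frame of `threshold`, `fpr`, `tpr`, ordered from the
#'   all-positive to the all-negative operating point.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  out <- lapply(thr, function(t) {
    pred <- as.integer(scores > t)
    c(threshold = t, fpr = sum(pred == 1 & labels == 0) / n0,
      tpr = sum(pred == 1 & labels == 1) / n1)
  })
  as.data.frame(do.call(rbind, out))
}

#' A model factory for the cascade deep forest
#'
#' Adapts [fit_cascade()] to the factory interface used by
#' [stratified_kfold_cv()]: a function of `(X, y, seed)` returning an object
#' with a `predict_proba(newX)` closure.
#'
#' @param cfg a [cascade_config()]; its seed is replaced per fold.
#' @return A factory function.
#' @export
cascade_factory <- function(cfg = cascade_config()) {
  function(X, y, seed = cfg$seed) {
    cfg$seed <- as.integer(seed)
    model <- fit_cascade(X, y, cfg)
    list(model = model,
         predict_proba = function(newX) predict_proba(model, newX))
  }
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into k folds whose per-class sizes differ by at most one,
#' fits the model on k-1 folds and evaluates on the held-out fold. Any
#' standardization is fitted inside the training folds only and applied to
#' the held-out fold, so no information leaks across the split. Reports
#' per-fold confusion counts and metrics, their mean, the pooled-confusion
#' metrics, and AUC (per-fold mean and pooled over all out-of-fold scores).
#'
#' @param X numeric n x d feature matrix.
#' @param y 0/1 labels; each class needs at least k members.
#' @param k number of folds (>= 2), 10 by default.
#' @param model_factory function `(X_train, y_train, seed)` returning an
#'   object with a `predict_proba(newX)` closure (see [cascade_factory()]).
#' @param seed seed for the fold assignment and the per-fold model seeds.
#' @param standardize logical; z-score features inside each training fold.
#' @return An `evaluation_report` list: `folds` (assignment), `per_fold`
#'   (data.frame of fold metrics), `mean_metrics`, `pooled_counts`,
#'   `pooled_metrics`, `auc` (mean and pooled), `oof_scores`, `seed`, `k`.
#' @export
stratified_kfold_cv <- function(X, y, k = 10L, model_factory,
                                seed = 42L, standardize = TRUE) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(nrow(X) == length(y), k >= 2L)
  if (any(table(y) < k))
    stop("each class needs at least k = ", k, " members")
  folds <- stratified_folds(y, k, derive_seed(seed))
  oof_scores <- numeric(length(y))
  per_fold <- vector("list", k)
  fold_counts <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    if (standardize) {
      params <- fit_standardizer(Xtr)
      Xtr <- suppressWarnings(apply_standardizer(Xtr, params))
      Xte <- suppressWarnings(apply_standardizer(Xte, params))
    }
    fit <- model_factory(Xtr, y[tr], derive_seed(seed, fold = f))
    p <- fit$predict_proba(Xte)
    scores <- p[, ncol(p)]
    oof_scores[!tr] <- scores
    pred <- as.integer(scores > 0.5)
    cc <- confusion_counts(pred, y[!tr])
    fold_counts[[f]] <- cc
    per_fold[[f]] <- c(fold = f, classification_metrics(cc),
                       AUC = roc_auc(scores, y[!tr]))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  pooled <- structure(list(tp = sum(vapply(fold_counts, `[[`, 0, "tp")),
                           tn = sum(vapply(fold_counts, `[[`, 0, "tn")),
                           fp = sum(vapply(fold_counts, `[[`, 0, "fp")),
                           fn = sum(vapply(fold_counts, `[[`, 0, "fn"))),
                      class = "confusion_counts")
  structure(list(folds = folds, per_fold = per_fold,
                 mean_metrics = colMeans(per_fold[, c("ACC", "SEN", "SPE",
                                                      "MCC")]),
                 pooled_counts = pooled,
                 pooled_metrics = classification_metrics(pooled),
                 auc = c(mean_fold = mean(per_fold$AUC),
                         pooled = roc_auc(oof_scores, y)),
                 oof_scores = oof_scores, seed = seed, k = k),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV (seed %d)\n", x$k, x$seed))
  m <- x$mean_metrics
  cat(sprintf("  mean ACC %.4f  SEN %.4f  SPE %.4f  MCC %.4f  AUC %.4f\n",
              m["ACC"], m["SEN"], m["SPE"], m["MCC"], x$auc["mean_fold"]))
  with(x$pooled_counts,
       cat(sprintf("  pooled confusion: tp=%d tn=%d fp=%d fn=%d\n",
                   tp, tn, fp, fn)))
  invisible(x)
}
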