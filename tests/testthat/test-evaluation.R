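test_that("confusion metrics reproduce the closed-form values", {
  perfect <- structure(list(tp = 50, tn = 50, fp = 0, fn = 0),
                       class = "confusion_counts")
  expect_equal(unname(classification_metrics(perfect)), c(1, 1, 1, 1))
  c2 <- structure(list(tp = 40, tn = 35, fp = 15, fn = 10),
                  class = "confusion_counts")
  m <- classification_metrics(c2)
  expect_equal(unname(m["ACC"]), 0.75)
  expect_equal(unname(m["SEN"]), 0.8)
  expect_equal(unname(m["SPE"]), 0.7)
  expect_equal(unname(m["MCC"]),
               (40 * 35 - 15 * 10) / sqrt(55 * 50 * 50 * 45),
               tolerance = 1e-12)
  # degenerate predictor: zero denominator -> MCC = 0 by convention
  never_pos <- structure(list(tp = 0, tn = 20, fp = 0, fn = 10),
                         class = "confusion_counts")
  expect_equal(unname(classification_metrics(never_pos)["MCC"]), 0)
  expect_error(classification_metrics(
    structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
              class = "confusion_counts")), "no evaluated")
})

test_that("metrics agree with per-sample recounts on random draws", {
  set.seed(55)
  for (rep in 1:1000) {
    n <- sample(2:40, 1)
    actual <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    cc <- confusion_counts(pred, actual)
    # brute-force recount, sample by sample
    tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_len(n)) {
      if (pred[i] == 1 && actual[i] == 1) tp <- tp + 1L
      else if (pred[i] == 0 && actual[i] == 0) tn <- tn + 1L
      else if (pred[i] == 1) fp <- fp + 1L else fn <- fn + 1L
    }
    expect_identical(unlist(unclass(cc)), c(tp = tp, tn = tn, fp = fp, fn = fn))
    expect_equal(unname(classification_metrics(cc)["ACC"]), (tp + tn) / n)
  }
})

test_that("rank AUC handles separation, ties and the null case", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.9), c(1, 0)), 0)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "both classes")
  # null simulation: scores independent of labels
  set.seed(77)
  aucs <- sapply(1:10, function(s) {
    roc_auc(runif(2000), sample(0:1, 2000, replace = TRUE))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("rank AUC equals the trapezoidal ROC integral on tie-free scores", {
  set.seed(91)
  for (rep in 1:20) {
    n <- 60
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- sample(seq_len(1000), n) / 1000   # distinct scores
    pts <- roc_points(scores, labels)
    pts <- pts[order(pts$fpr, pts$tpr), ]
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(roc_auc(scores, labels), trap, tolerance = 1e-9)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- runif(300)
  labels <- as.integer(runif(300) < scores)    # informative scores
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-9)
})

test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c(0L, 1L), each = 50)
  X <- matrix(rnorm(100 * 5), 100)
  factory <- function(Xtr, ytr, seed) {
    # trivial centroid model, fast and deterministic
    mu1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
    mu0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
    list(predict_proba = function(newX) {
      d1 <- rowSums(sweep(newX, 2, mu1)^2)
      d0 <- rowSums(sweep(newX, 2, mu0)^2)
      p1 <- exp(-d1) / (exp(-d1) + exp(-d0))
      cbind(1 - p1, p1)
    })
  }
  rep10 <- stratified_kfold_cv(X, y, k = 10, factory, seed = 5,
                               standardize = FALSE)
  tab <- table(rep10$folds, y)
  expect_true(all(tab == 5))                       # 5 pos + 5 neg per fold
  expect_setequal(unique(rep10$folds), 1:10)
  expect_equal(sum(unlist(unclass(rep10$pooled_counts))), 100)
  expect_error(stratified_kfold_cv(X, y, k = 60, factory), "at least k")
  # bit-identical reruns under a fixed seed
  rep10b <- stratified_kfold_cv(X, y, k = 10, factory, seed = 5,
                                standardize = FALSE)
  expect_identical(rep10$per_fold, rep10b$per_fold)
})

test_that("cross-validated cascade separates blob data", {
  b <- synthetic_blobs(100, 10, separation = 2, seed = 31)
  cfg <- cascade_config(n_trees = 40L, max_layers = 2L, seed = 7L)
  rep5 <- stratified_kfold_cv(b$X, b$y, k = 5, cascade_factory(cfg),
                              seed = 19)
  expect_gte(unname(rep5$mean_metrics["ACC"]), 0.90)
  expect_gte(unname(rep5$auc["mean_fold"]), 0.95)
  expect_true(all(rep5$per_fold$MCC >= -1 & rep5$per_fold$MCC <= 1))
})
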