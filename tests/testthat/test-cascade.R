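small_cfg <- function(...) {
  args <- utils::modifyList(list(n_trees = 30L, internal_cv_folds = 3L,
                                 max_layers = 3L, seed = 11L), list(...))
  do.call(cascade_config, args)
}

test_that("layer fitting yields normalized, deterministic out-of-fold blocks", {
  b <- synthetic_blobs(50, 8, separation = 1.5, seed = 2)
  cfg <- small_cfg()
  l1 <- fit_layer(b$X, b$y, cfg, layer = 1L)
  expect_equal(dim(l1$oof), c(100L, 8L))           # 4 estimators x 2 classes
  for (e in 1:4) {
    expect_equal(rowSums(l1$oof[, (2 * e - 1):(2 * e)]), rep(1, 100),
                 tolerance = 1e-9)
  }
  l2 <- fit_layer(b$X, b$y, cfg, layer = 1L)
  expect_identical(l1$oof, l2$oof)
  expect_error(fit_layer(b$X, rep(1L, 100), cfg), "both classes")
  expect_error(cascade_config(internal_cv_folds = 1), "internal_cv_folds")
})

test_that("cascade augmentation arithmetic and stopping caps hold", {
  b <- synthetic_blobs(40, 10, separation = 1, seed = 8)
  cfg <- small_cfg(max_layers = 1L)
  m1 <- fit_cascade(b$X, b$y, cfg)
  expect_length(m1$layers, 1)
  m <- fit_cascade(b$X, b$y, small_cfg())
  # layer >= 2 consumed d + 2*n_estimators columns: verify via the stored
  # ranger fits' variable counts
  if (length(m$layers) >= 2) {
    rf2 <- m$layers[[2]][[2]]$model
    expect_equal(rf2$num.independent.variables, 10L + 8L)
  }
  rf1 <- m$layers[[1]][[2]]$model
  expect_equal(rf1$num.independent.variables, 10L)
  expect_equal(m$best_layer, which.max(m$layer_scores))
})

test_that("single-forest one-layer cascade equals a plain random forest", {
  b <- synthetic_blobs(60, 12, separation = 1, seed = 21)
  cfg <- cascade_config(estimators = "rf", n_trees = 50L, max_layers = 1L,
                        seed = 33L)
  m <- fit_cascade(b$X, b$y, cfg)
  # reference fit: same learner, same derived seed, outside the cascade
  Xn <- b$X; colnames(Xn) <- paste0("f", seq_len(ncol(Xn)))
  ref <- ranger::ranger(x = as.data.frame(Xn),
                        y = factor(b$y, levels = c(0, 1)),
                        num.trees = 50L, mtry = floor(sqrt(12)),
                        probability = TRUE, num.threads = 1,
                        seed = derive_seed(33L, 1L, 1L, 0L),
                        splitrule = "gini", num.random.splits = 1)
  p_ref <- predict(ref, as.data.frame(Xn), num.threads = 1)$predictions
  expect_equal(unname(predict_proba(m, b$X)[, "P1"]), unname(p_ref[, "1"]),
               tolerance = 1e-12)
  expect_equal(predict(m, b$X), as.integer(p_ref[, "1"] > 0.5))
})

test_that("probabilities are normalized, argmax-consistent, tie to negative", {
  b <- synthetic_blobs(40, 6, separation = 1.5, seed = 13)
  m <- fit_cascade(b$X, b$y, small_cfg())
  p <- predict_proba(m, b$X)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_equal(predict(m, b$X), as.integer(p[, "P1"] > 0.5))
  expect_error(predict_proba(m, b$X[, 1:3]), "expected 6")
  # documented tie rule on the decision function itself
  expect_equal(as.integer(c(0.5, 0.7, 0.3) > 0.5), c(0L, 1L, 0L))
})

test_that("cascade separates Gaussian blobs and reruns bit-identically", {
  b <- synthetic_blobs(200, 20, separation = 2, seed = 41)
  cfg <- cascade_config(n_trees = 60L, max_layers = 3L, seed = 17L)
  m <- fit_cascade(b$X, b$y, cfg)
  acc <- mean(predict(m, b$X) == b$y)
  expect_gte(acc, 0.95)
  expect_gte(max(m$layer_scores), 0.95)
  m2 <- fit_cascade(b$X, b$y, cfg)
  expect_identical(predict_proba(m, b$X), predict_proba(m2, b$X))
})

test_that("cascade does not underperform a same-budget single forest", {
  # total budget: 4 estimators x 60 trees in layer 1
  deltas <- sapply(1:5, function(s) {
    tr <- synthetic_blobs(100, 10, separation = 1.2, seed = 100 + s)
    te <- synthetic_blobs(100, 10, separation = 1.2, seed = 200 + s)
    m <- fit_cascade(tr$X, tr$y,
                     cascade_config(n_trees = 60L, max_layers = 2L,
                                    seed = s))
    Xn <- tr$X; colnames(Xn) <- paste0("f", seq_len(ncol(Xn)))
    Tn <- te$X; colnames(Tn) <- paste0("f", seq_len(ncol(Tn)))
    rf <- ranger::ranger(x = as.data.frame(Xn),
                         y = factor(tr$y, levels = c(0, 1)),
                         num.trees = 240L, probability = TRUE,
                         num.threads = 1, seed = s)
    acc_c <- mean(predict(m, te$X) == te$y)
    p_rf <- predict(rf, as.data.frame(Tn), num.threads = 1)$predictions
    acc_r <- mean(as.integer(p_rf[, "1"] > 0.5) == te$y)
    acc_c - acc_r
  })
  expect_true(all(deltas >= -0.02))
})

test_that("serialization round-trip reproduces probabilities bit-identically", {
  b <- synthetic_blobs(40, 6, separation = 1.5, seed = 3)
  m <- fit_cascade(b$X, b$y, small_cfg(max_layers = 2L))
  path <- tempfile(fileext = ".rds")
  save_cascade(m, path)
  m2 <- load_cascade(path)
  expect_identical(predict_proba(m, b$X), predict_proba(m2, b$X))
})
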