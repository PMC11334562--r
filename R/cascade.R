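#' Configuration of the cascade deep forest
#'
#' Each layer holds a heterogeneous group of tree ensembles — by default one
#' gradient-boosted tree ensemble, one random forest and two
#' extremely-randomized-tree forests (four learners). Forest learners sample
#' `floor(sqrt(d))` candidate features at every node split; the boosted
#' learner subsamples columns per node at rate `sqrt(d)/d`. Layers pass
#' their class-probability outputs forward, concatenated with the original
#' features, and the cascade grows until the layer validation score stops
#' improving.
#'
#' @param estimators character vector of per-layer learners, each one of
#'   `"xgboost"`, `"rf"`, `"extratrees"`.
#' @param n_trees trees per forest learner / boosting rounds for xgboost.
#' @param internal_cv_folds folds of the internal cross-fitting used to
#'   produce leakage-free augmented probabilities (>= 2).
#' @param max_layers hard cap on cascade depth.
#' @param patience layers without improvement of the best validation score
#'   before growth stops.
#' @param seed master seed; all per-layer / per-estimator / per-fold seeds
#'   derive from it via [derive_seed()].
#' @param xgb_params extra parameters merged into the xgboost parameter list.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(estimators = c("xgboost", "rf", "extratrees",
                                          "extratrees"),
                           n_trees = 100L, internal_cv_folds = 3L,
                           max_layers = 20L, patience = 1L, seed = 1L,
                           xgb_params = list()) {
  stopifnot(length(estimators) >= 1L,
            all(estimators %in% c("xgboost", "rf", "extratrees")),
            n_trees >= 1, max_layers >= 1, patience >= 1)
  if (internal_cv_folds < 2L)
    stop("internal_cv_folds must be >= 2 (out-of-fold estimates need held-out data)")
  structure(list(estimators = estimators, n_trees = as.integer(n_trees),
                 internal_cv_folds = as.integer(internal_cv_folds),
                 max_layers = as.integer(max_layers),
                 patience = as.integer(patience), seed = as.integer(seed),
                 xgb_params = xgb_params),
            class = "cascade_config")
}

# Fit one base learner; returns a closure predicting an n x 2 probability
# matrix with columns (P(class 0), P(class 1)).
fit_estimator <- function(type, X, y, cfg, seed) {
  d <- ncol(X)
  if (type == "xgboost") {
    params <- utils::modifyList(
      list(objective = "binary:logistic", nthread = 1, seed = seed,
           max_depth = 6, eta = 0.3,
           colsample_bynode = max(sqrt(d) / d, 1 / d)),
      cfg$xgb_params)
    booster <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = cfg$n_trees, verbose = 0)
    list(type = type, model = booster,
         predict_proba = function(newX) {
           p1 <- predict(booster, xgboost::xgb.DMatrix(newX, nthread = 1))
           cbind(1 - p1, p1)
         })
  } else {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      num.trees = cfg$n_trees, mtry = max(1L, floor(sqrt(d))),
      probability = TRUE, seed = seed, num.threads = 1,
      splitrule = if (type == "extratrees") "extratrees" else "gini",
      num.random.splits = 1)
    list(type = type, model = fit,
         predict_proba = function(newX) {
           p <- predict(fit, data = as.data.frame(newX),
                        num.threads = 1)$predictions
           p[, c("0", "1"), drop = FALSE]
         })
  }
}

# Stratified fold assignment: per-class sizes differ by at most 1.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Fit one cascade layer
#'
#' Trains every configured estimator on the (possibly augmented) feature
#' matrix and produces the class-probability block passed to the next
#' layer. The forwarded probabilities are out-of-fold: each sample's
#' probabilities come from estimators trained with that sample held out
#' (internal `internal_cv_folds`-fold cross-fitting), which prevents the
#' stacked layers from overfitting trivially. Full-data refits are kept for
#' inference.
#'
#' @param X numeric matrix (original features, plus the previous layer's
#'   probability block for layers >= 2).
#' @param y 0/1 label vector with both classes present.
#' @param cfg a [cascade_config()].
#' @param layer layer index (drives seed derivation).
#' @return List with `estimators` (full-data fits), `oof` (n x
#'   2*n_estimators out-of-fold probability matrix) and `score` (accuracy of
#'   the averaged out-of-fold probabilities).
#' @export
fit_layer <- function(X, y, cfg, layer = 1L) {
  if (length(unique(y)) < 2L) stop("need both classes to fit a layer")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  k <- cfg$internal_cv_folds
  folds <- stratified_folds(y, k, derive_seed(cfg$seed, layer))
  n_est <- length(cfg$estimators)
  oof <- matrix(NA_real_, n, 2L * n_est)
  full <- vector("list", n_est)
  for (e in seq_len(n_est)) {
    type <- cfg$estimators[e]
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_estimator(type, X[tr, , drop = FALSE], y[tr], cfg,
                           derive_seed(cfg$seed, layer, e, f))
      oof[!tr, (2 * e - 1):(2 * e)] <-
        fit$predict_proba(X[!tr, , drop = FALSE])
    }
    full[[e]] <- fit_estimator(type, X, y, cfg,
                               derive_seed(cfg$seed, layer, e, 0L))
  }
  p1 <- rowMeans(vapply(seq_len(n_est), function(e) oof[, 2 * e],
                        numeric(n)))
  score <- mean(as.integer(p1 > 0.5) == y)
  list(estimators = full, oof = oof, score = score)
}

#' Fit a cascade deep forest
#'
#' Layer 1 consumes the feature matrix; every later layer consumes the
#' original features concatenated with the previous layer's out-of-fold
#' class probabilities (the augmented attributes, adding
#' `2 * n_estimators` columns). Growth stops once the layer validation
#' score (accuracy of the averaged out-of-fold probabilities) has failed to
#' exceed the best score seen for `patience` consecutive layers, or at
#' `max_layers`. Inference uses layers up to the best-scoring one.
#'
#' @param X numeric n x d matrix.
#' @param y 0/1 labels (1 = druggable / positive class).
#' @param cfg a [cascade_config()].
#' @return A `cascade_model` with fields `layers`, `layer_scores`,
#'   `best_layer`, `config` and `d_input`.
#' @export
fit_cascade <- function(X, y, cfg = cascade_config()) {
  X <- as.matrix(X); y <- as.integer(y)
  if (nrow(X) < 2L * cfg$internal_cv_folds)
    stop("need at least 2 samples per internal fold")
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop("labels must contain both classes, coded 0/1")
  layers <- list(); scores <- numeric(0)
  best <- -Inf; stall <- 0L
  prev_oof <- NULL
  for (t in seq_len(cfg$max_layers)) {
    Xt <- if (t == 1L) X else cbind(X, prev_oof)
    layer <- fit_layer(Xt, y, cfg, layer = t)
    layers[[t]] <- layer$estimators
    scores[t] <- layer$score
    prev_oof <- layer$oof
    if (layer$score > best) {
      best <- layer$score; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  structure(list(layers = layers, layer_scores = scores,
                 best_layer = which.max(scores), config = cfg,
                 d_input = ncol(X)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %d layer(s), best layer %d (score %.4f), d=%d\n",
              length(x$layers), x$best_layer,
              x$layer_scores[x$best_layer], x$d_input))
  invisible(x)
}

#' Class probabilities from a fitted cascade
#'
#' Propagates the input through layers 1..best_layer, rebuilding each
#' layer's augmented block from the stored full-data estimators, then
#' averages the final layer's per-estimator probability vectors. Rows sum
#' to 1.
#'
#' @param model a `cascade_model`.
#' @param X numeric matrix with `d_input` columns.
#' @return n x 2 matrix with columns `P0`, `P1`.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d_input)
    stop("expected ", model$d_input, " features, got ", ncol(X))
  prev <- NULL
  for (t in seq_len(model$best_layer)) {
    Xt <- if (t == 1L) X else cbind(X, prev)
    colnames(Xt) <- paste0("f", seq_len(ncol(Xt)))
    probs <- lapply(model$layers[[t]], function(est) est$predict_proba(Xt))
    prev <- do.call(cbind, probs)
  }
  n_est <- length(model$layers[[model$best_layer]])
  P1 <- rowMeans(vapply(seq_len(n_est), function(e) prev[, 2 * e],
                        numeric(nrow(X))))
  out <- cbind(P0 = 1 - P1, P1 = P1)
  rownames(out) <- rownames(X)
  out
}

#' Predicted labels from a fitted cascade
#'
#' Argmax of [predict_proba()]; an exact 0.5/0.5 tie goes to the negative
#' class.
#'
#' @param object a `cascade_model`.
#' @param X feature matrix.
#' @param ... unused.
#' @return Integer 0/1 vector.
#' @export
predict.cascade_model <- function(object, X, ...) {
  p <- predict_proba(object, X)
  as.integer(p[, "P1"] > 0.5)
}

#' Serialize a cascade model to a file
#'
#' Boosted learners are converted to their raw byte representation so the
#' archive survives sessions; [load_cascade()] restores a model whose
#' predictions are bit-identical.
#'
#' @param model a `cascade_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_cascade <- function(model, path) {
  stripped <- model
  stripped$layers <- lapply(model$layers, function(group) {
    lapply(group, function(est) {
      if (est$type == "xgboost") {
        list(type = "xgboost", raw = xgboost::xgb.save.raw(est$model))
      } else {
        list(type = est$type, model = est$model)
      }
    })
  })
  saveRDS(stripped, path)
  invisible(path)
}

#' Restore a cascade model saved by [save_cascade()]
#'
#' @param path archive path.
#' @return A `cascade_model`.
#' @export
load_cascade <- function(path) {
  model <- readRDS(path)
  model$layers <- lapply(model$layers, function(group) {
    lapply(group, function(est) {
      if (est$type == "xgboost") {
        booster <- xgboost::xgb.load.raw(est$raw)
        list(type = "xgboost", model = booster,
             predict_proba = function(newX) {
               p1 <- predict(booster, xgboost::xgb.DMatrix(newX, nthread = 1))
               cbind(1 - p1, p1)
             })
      } else {
        fit <- est$model
        list(type = est$type, model = fit,
             predict_proba = function(newX) {
               p <- predict(fit, data = as.data.frame(newX),
                            num.threads = 1)$predictions
               p[, c("0", "1"), drop = FALSE]
             })
      }
    })
  })
  model
}

#' Gaussian two-blob dataset for classifier checks
#'
#' Two isotropic Gaussian classes whose means sit `separation` apart along
#' every coordinate — linearly separable for large separations. Used for
#' sanity bounds on the cascade.
#'
#' @param n_per_class samples per class.
#' @param n_features dimensionality.
#' @param separation distance between class means per coordinate.
#' @param sd within-class standard deviation.
#' @param seed integer seed.
#' @return List with matrix `X` and 0/1 vector `y`.
#' @export
synthetic_blobs <- function(n_per_class = 200L, n_features = 20L,
                            separation = 2, sd = 1, seed = 1L) {
  with_local_seed(seed, {
    X0 <- matrix(rnorm(n_per_class * n_features, 0, sd),
                 n_per_class, n_features)
    X1 <- matrix(rnorm(n_per_class * n_features, separation, sd),
                 n_per_class, n_features)
    X <- rbind(X0, X1)
    y <- rep(c(0L, 1L), each = n_per_class)
    ord <- sample(length(y))
    list(X = X[ord, , drop = FALSE], y = y[ord])
  })
}
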