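# Machine-learning baselines: a single-hidden-layer back-propagation
# network and a random-forest regressor, plus the four-rung nested
# covariate ladder y = f(T) .. f(T, Comp, Site, Clim) used to quantify what
# competition, site and climate each add.

# Reference selection outcome: the informative site and climate sets used
# as ladder defaults.
DEFAULT_SITE_SET <- c("PW", "HB", "TRHD", "PX", "DM")
DEFAULT_CLIM_SET <- c("DD18", "MAP", "Eref")

#' Hidden-layer sizing rule
#'
#' The usual rule of thumb for one hidden layer:
#' `floor(sqrt(n_in + n_out)) + m` with `m` an integer in 1..10. With 10
#' inputs, one output and `m = 3` this gives the 10:6:1 architecture.
#'
#' @param n_in,n_out input and output node counts (>= 1).
#' @param m additive constant, integer in `[1, 10]`.
#' @return integer node count.
#' @export
hidden_nodes <- function(n_in, n_out = 1, m = 3) {
  if (n_in < 1 || n_out < 1)
    stop_itgrow("n_in and n_out must be >= 1", "itgrow_validation_error")
  if (m < 1 || m > 10)
    stop_itgrow("m must be in [1, 10]", "itgrow_validation_error")
  as.integer(floor(sqrt(n_in + n_out)) + m)
}

#' Back-propagation network configuration
#'
#' Single hidden layer with logistic sigmoid units and a linear output.
#' Inputs and output are min–max scaled to `[0, 1]` with training-set
#' bounds; `target_loss` is a mean-squared-error threshold on that scale.
#' Training uses a batch quasi-Newton optimizer run in warm-restarted
#' chunks (so a loss trajectory is recorded); `learning_rate` is kept for
#' interface completeness but is not consumed by that optimizer.
#'
#' @param n_hidden hidden node count; `NULL` applies [hidden_nodes()] with
#'   `m = 3` to the feature count at training time.
#' @param learning_rate nominal learning rate (default 0.01).
#' @param target_loss stop once scaled training MSE falls below this
#'   (default 0.001).
#' @param max_iter iteration cap (default 1000).
#' @param seed seed for the weight initialization.
#' @return a `bp_config` list.
#' @export
bp_config <- function(n_hidden = NULL, learning_rate = 0.01,
                      target_loss = 0.001, max_iter = 1000, seed = 1) {
  if (!is.null(n_hidden) && n_hidden < 1)
    stop_itgrow("n_hidden must be >= 1", "itgrow_validation_error")
  if (learning_rate <= 0)
    stop_itgrow("learning_rate must be > 0", "itgrow_validation_error")
  structure(list(n_hidden = n_hidden, learning_rate = learning_rate,
                 target_loss = target_loss, max_iter = max_iter,
                 seed = seed),
            class = "bp_config")
}

#' Random-forest configuration
#'
#' @param ntree number of trees (>= 1). 500 stabilizes the error for these
#'   data sizes; grid tuning via [tune_rf()].
#' @param mtry variables tried per split; `NULL` applies the regression
#'   default `max(1, floor(p / 3))` at training time.
#' @param seed seed for the forest.
#' @return an `rf_config` list.
#' @export
rf_config <- function(ntree = 500, mtry = NULL, seed = 1) {
  if (ntree < 1) stop_itgrow("ntree must be >= 1", "itgrow_validation_error")
  structure(list(ntree = as.integer(ntree), mtry = mtry, seed = seed),
            class = "rf_config")
}

#' Feature set of one ladder rung
#'
#' Rung 1: age only. Rung 2: + competition (plot density `N`). Rung 3:
#' + site factors. Rung 4 (whole model): + climate factors.
#'
#' @param rung 1..4.
#' @param site,clim the site and climate variable sets (defaults: the
#'   reference selection outcome).
#' @return character vector of feature names.
#' @export
ladder_features <- function(rung, site = DEFAULT_SITE_SET,
                            clim = DEFAULT_CLIM_SET) {
  if (!rung %in% 1:4) stop_itgrow("rung must be 1..4",
                                  "itgrow_validation_error")
  feats <- "T"
  if (rung >= 2) feats <- c(feats, "N")
  if (rung >= 3) feats <- c(feats, site)
  if (rung >= 4) feats <- c(feats, clim)
  feats
}

rung_label <- function(rung) {
  c("T", "T + Comp", "T + Comp + Site", "T + Comp + Site + Clim")[rung]
}

minmax_fit <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

minmax_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$lo), 2, sc$span, "/")
}

#' Train the back-propagation network
#'
#' Fits a 3-layer network (logistic hidden, linear output) on the given
#' feature columns, training in chunks until the scaled training MSE
#' reaches `target_loss` or `max_iter` iterations; the per-chunk loss
#' trajectory is recorded. Deterministic given the config seed.
#'
#' @param train a `growth_dataset` (>= 50 rows) or flat data.frame with
#'   `response`.
#' @param features character vector of predictor columns.
#' @param cfg a [bp_config()].
#' @return a `bp_model` with a [predict()] method.
#' @export
train_bp <- function(train, features, cfg = bp_config()) {
  flat <- if (inherits(train, "growth_dataset")) as.data.frame(train)
  else as.data.frame(train)
  if (nrow(flat) < 50)
    stop_itgrow("train_bp needs >= 50 training rows",
                "itgrow_validation_error")
  X <- as.matrix(flat[, features, drop = FALSE])
  y <- flat$response
  sx <- minmax_fit(X)
  sy <- minmax_fit(matrix(y, ncol = 1))
  Xs <- minmax_apply(X, sx)
  ys <- (y - sy$lo) / sy$span
  size <- cfg$n_hidden %||% hidden_nodes(length(features), 1, 3)
  n_wts <- (ncol(Xs) + 1) * size + (size + 1)

  wts <- with_seed(cfg$seed, stats::runif(n_wts, -0.5, 0.5))
  chunk <- 50L
  done <- 0L
  loss <- numeric(0)
  net <- NULL
  while (done < cfg$max_iter) {
    it <- min(chunk, cfg$max_iter - done)
    net <- nnet::nnet(Xs, ys, size = size, Wts = wts, linout = TRUE,
                      decay = 0, maxit = it, trace = FALSE,
                      abstol = cfg$target_loss * length(ys), reltol = 1e-10)
    done <- done + it
    mse <- net$value / length(ys)
    if (!is.finite(mse))
      stop_itgrow(paste0("non-finite training loss at iteration ", done),
                  "itgrow_fit_error")
    loss <- c(loss, mse)
    if (mse <= cfg$target_loss) break
    if (length(loss) >= 2 &&
        abs(loss[length(loss) - 1] - mse) < 1e-12) break
    wts <- net$wts
  }
  structure(list(net = net, features = features, scale_x = sx,
                 scale_y = sy, loss_history = loss, iterations = done,
                 config = cfg),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat("<bp_model> ", length(x$features), ":", x$net$n[2], ":1 network, ",
      x$iterations, " iterations, final scaled MSE = ",
      signif(utils::tail(x$loss_history, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a trained network
#' @param object a `bp_model`.
#' @param newdata `growth_dataset` or data.frame with the feature columns.
#' @param ... unused.
#' @return numeric predictions on the response scale.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  flat <- if (inherits(newdata, "growth_dataset")) as.data.frame(newdata)
  else as.data.frame(newdata)
  Xs <- minmax_apply(as.matrix(flat[, object$features, drop = FALSE]),
                     object$scale_x)
  ys <- as.numeric(stats::predict(object$net, Xs))
  ys * object$scale_y$span + object$scale_y$lo
}

#' Train the random-forest regressor
#'
#' Bootstrap-resampled regression trees (`mtry` variables considered per
#' split, minimum node size 5); the forest prediction is the mean of the
#' tree outputs, hence bounded by the training response range.
#' Deterministic given the config seed.
#'
#' @param train a `growth_dataset` (>= 30 rows) or flat data.frame.
#' @param features predictor columns.
#' @param cfg an [rf_config()].
#' @return an `rf_model` with a [predict()] method.
#' @export
train_rf <- function(train, features, cfg = rf_config()) {
  flat <- if (inherits(train, "growth_dataset")) as.data.frame(train)
  else as.data.frame(train)
  if (nrow(flat) < 30)
    stop_itgrow("train_rf needs >= 30 training rows",
                "itgrow_validation_error")
  p <- length(features)
  mtry <- cfg$mtry %||% max(1, floor(p / 3))
  if (mtry > p)
    stop_itgrow("mtry exceeds the number of predictors",
                "itgrow_validation_error")
  X <- flat[, features, drop = FALSE]
  y <- flat$response
  rf <- with_seed(cfg$seed,
    randomForest::randomForest(x = X, y = y, ntree = cfg$ntree,
                               mtry = mtry, nodesize = 5))
  structure(list(forest = rf, features = features,
                 mtry = mtry, ntree = cfg$ntree,
                 y_range = range(y)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat("<rf_model> ntree = ", x$ntree, ", mtry = ", x$mtry,
      ", features: ", paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict from a trained forest
#' @param object an `rf_model`.
#' @param newdata `growth_dataset` or data.frame with the feature columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  flat <- if (inherits(newdata, "growth_dataset")) as.data.frame(newdata)
  else as.data.frame(newdata)
  as.numeric(stats::predict(object$forest,
                            flat[, object$features, drop = FALSE]))
}

#' Cross-validated random-forest grid tuning
#'
#' K-fold cross-validated RMSE over an `ntree x mtry` grid. For each fold
#' and `mtry` one forest of `max(ntree_grid)` trees is grown and the RMSE
#' of every smaller `ntree` is obtained exactly from cumulative means of
#' the per-tree holdout predictions. Ties resolve to the smaller `ntree`,
#' then smaller `mtry`.
#'
#' @param train a `growth_dataset` or flat data.frame.
#' @param features predictor columns.
#' @param ntree_grid forest sizes to score (default 1, 20, 40, ..., 500).
#' @param mtry_grid split-candidate counts (default 1..min(10, p)).
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment + forests).
#' @return list with `best` (an [rf_config()]) and `scores` (data.frame
#'   `ntree`, `mtry`, `rmse` with one row per grid point).
#' @export
tune_rf <- function(train, features,
                    ntree_grid = c(1, seq(20, 500, by = 20)),
                    mtry_grid = NULL, folds = 5, seed = 1) {
  flat <- if (inherits(train, "growth_dataset")) as.data.frame(train)
  else as.data.frame(train)
  n <- nrow(flat)
  if (!length(ntree_grid))
    stop_itgrow("ntree_grid is empty", "itgrow_validation_error")
  if (folds > n)
    stop_itgrow("more folds than rows", "itgrow_validation_error")
  p <- length(features)
  mtry_grid <- mtry_grid %||% seq_len(min(10, p))
  mtry_grid <- mtry_grid[mtry_grid >= 1 & mtry_grid <= p]
  if (!length(mtry_grid))
    stop_itgrow("mtry_grid has no value in [1, p]", "itgrow_validation_error")
  ntree_grid <- sort(unique(as.integer(ntree_grid)))
  max_trees <- max(ntree_grid)

  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  X <- flat[, features, drop = FALSE]
  y <- flat$response
  sse <- matrix(0, length(ntree_grid), length(mtry_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    for (j in seq_along(mtry_grid)) {
      rf <- with_seed(child_seed(seed, f * 100 + j),
        randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                   ntree = max_trees, mtry = mtry_grid[j],
                                   nodesize = 5))
      pr <- stats::predict(rf, X[!tr, , drop = FALSE], predict.all = TRUE)
      ind <- pr$individual                      # n_holdout x max_trees
      csum <- t(apply(ind, 1, cumsum))
      if (nrow(ind) == 1) csum <- matrix(cumsum(ind[1, ]), nrow = 1)
      for (i in seq_along(ntree_grid)) {
        k <- ntree_grid[i]
        pred_k <- csum[, k] / k
        sse[i, j] <- sse[i, j] + sum((y[!tr] - pred_k)^2)
      }
    }
  }
  rmse <- sqrt(sse / n)
  scores <- data.frame(
    ntree = rep(ntree_grid, times = length(mtry_grid)),
    mtry = rep(mtry_grid, each = length(ntree_grid)),
    rmse = as.vector(rmse))
  best <- scores[order(scores$rmse, scores$ntree, scores$mtry), ][1, ]
  list(best = rf_config(ntree = best$ntree, mtry = best$mtry, seed = seed),
       scores = scores)
}

#' Evaluate one method over the covariate ladder
#'
#' Fits the method on each of the four nested feature sets using one fixed
#' train/test split shared across rungs, and reports train and test R²,
#' MAE and RMSE per rung — the machine-readable analogue of the published
#' sub-model tables.
#'
#' @param ds a `growth_dataset` containing all ladder variables.
#' @param method `"RP"`, `"BP"` or `"RF"`.
#' @param seed seed of the shared 80/20 split (and fallback model seed).
#' @param fraction training fraction.
#' @param site,clim the site and climate sets for rungs 3–4.
#' @param bp,rf,control method configurations.
#' @return data.frame with one row per rung: `model`, `rung`, `variables`,
#'   `train_r2`, `train_mae`, `train_rmse`, `test_r2`, `test_mae`,
#'   `test_rmse`. The split seed is stored in attribute `"split_seed"`.
#' @export
run_ladder <- function(ds, method = c("RP", "BP", "RF"), seed = 1,
                       fraction = 0.8,
                       site = DEFAULT_SITE_SET, clim = DEFAULT_CLIM_SET,
                       bp = bp_config(seed = seed),
                       rf = rf_config(seed = seed),
                       control = rp_control(seed = seed)) {
  method <- match.arg(method)
  sp <- split_train_test(ds, fraction = fraction, seed = seed)
  train_flat <- as.data.frame(sp$train)
  test_flat <- as.data.frame(sp$test)
  rows <- vector("list", 4)
  for (rung in 1:4) {
    feats <- ladder_features(rung, site, clim)
    model <- switch(method,
      RP = if (rung == 1) fit_curve("Mitscherlich", sp$train,
                                    seed = control$seed)
           else fit_rp(sp$train, setdiff(feats, "T"), control),
      BP = train_bp(train_flat, feats, bp),
      RF = train_rf(train_flat, feats, rf))
    m_tr <- compute_metrics(train_flat$response, predict(model, train_flat))
    m_te <- compute_metrics(test_flat$response, predict(model, test_flat))
    rows[[rung]] <- data.frame(
      model = method, rung = rung, variables = rung_label(rung),
      train_r2 = m_tr$r2, train_mae = m_tr$mae, train_rmse = m_tr$rmse,
      test_r2 = m_te$r2, test_mae = m_te$mae, test_rmse = m_te$rmse)
  }
  out <- do.call(rbind, rows)
  attr(out, "split_seed") <- seed
  out
}
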