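# Fit statistics, residual diagnostics, relative-improvement arithmetic,
# cross-validated group importance, partial dependence, and the side-by-side
# model comparison.

#' Fit metrics: R², RMSE, MAE
#'
#' The default R² is \eqn{1 - \sum(y_i - \hat y_i)^2 / \sum(y_i - \bar y)^2}
#' (the share of response variance the model explains; never exceeds 1).
#' The explained-variance ratio
#' \eqn{\sum(\hat y_i - \bar y)^2 / \sum(y_i - \bar y)^2}, which can exceed
#' 1 for biased nonlinear predictors, is available via
#' `r2_method = "explained_variance"` for fidelity with sources that define
#' it that way. RMSE and MAE are the usual root-mean-square and mean
#' absolute prediction errors in response units.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param r2_method `"one_minus_rss"` (default) or `"explained_variance"`.
#' @return a `growth_metrics` list: `r2`, `rmse`, `mae`, `n`. With
#'   zero-variance observations `r2` is `NA` with a warning.
#' @export
compute_metrics <- function(observed, predicted,
                            r2_method = c("one_minus_rss",
                                          "explained_variance")) {
  r2_method <- match.arg(r2_method)
  n <- length(observed)
  if (n == 0 || length(predicted) != n)
    stop_itgrow("observed and predicted must have equal nonzero length",
                "itgrow_validation_error")
  err <- observed - predicted
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) {
    warning("zero variance in observed values: R² undefined",
            call. = FALSE)
    NA_real_
  } else if (r2_method == "one_minus_rss") {
    1 - sum(err^2) / sst
  } else {
    sum((predicted - mean(observed))^2) / sst
  }
  structure(list(r2 = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 n = n),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  cat(sprintf("R² = %.3f, RMSE = %.3f, MAE = %.3f (n = %d)\n",
              x$r2, x$rmse, x$mae, x$n))
  invisible(x)
}

#' Percent change of a metric relative to a reference
#'
#' `higher_better` (R²): `100 * (new - reference) / reference`;
#' `lower_better` (RMSE, MAE): `100 * (reference - new) / reference`.
#' Rounded half away from zero to one decimal, the convention used when
#' reporting "R² increased by x%".
#'
#' @param reference baseline metric value (nonzero).
#' @param new new metric value.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return percent change, one decimal.
#' @export
relative_change <- function(reference, new,
                            direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (reference == 0)
    stop_itgrow("reference metric must be nonzero", "itgrow_validation_error")
  pct <- if (direction == "higher_better")
    100 * (new - reference) / reference
  else
    100 * (reference - new) / reference
  round_half_away(pct, 1)
}

#' Residual summary with binned spread
#'
#' Residuals (observed − predicted), their range, and per-bin mean and SD
#' over equal-population bins of the predicted value, for numerical
#' heteroscedasticity inspection; `spread_ratio` is max bin SD / min bin
#' SD. Bins too small to hold a point are merged with neighbours by the
#' quantile construction.
#'
#' @param observed,predicted equal-length numeric vectors (e.g., the test
#'   responses and a model's predictions).
#' @param bins number of bins on the predicted axis.
#' @return a `residual_summary` list: `residuals`, `range`, `bins`
#'   (data.frame with `lower`, `upper`, `n`, `mean`, `sd`), `spread_ratio`.
#' @export
residual_summary <- function(observed, predicted, bins = 6) {
  if (length(observed) != length(predicted) || !length(observed))
    stop_itgrow("observed and predicted must have equal nonzero length",
                "itgrow_validation_error")
  res <- observed - predicted
  qs <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out =
                                                        bins + 1)))
  if (length(qs) < 2) qs <- c(min(predicted) - 1e-9, max(predicted) + 1e-9)
  grp <- cut(predicted, breaks = qs, include.lowest = TRUE)
  bin_stats <- do.call(rbind, lapply(levels(grp), function(g) {
    r <- res[grp == g]
    data.frame(bin = g, n = length(r), mean = mean(r),
               sd = if (length(r) > 1) stats::sd(r) else NA_real_)
  }))
  sds <- bin_stats$sd[is.finite(bin_stats$sd) & bin_stats$sd > 0]
  structure(list(residuals = res, range = range(res), bins = bin_stats,
                 spread_ratio = if (length(sds)) max(sds) / min(sds)
                 else NA_real_),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("residuals in [%.3f, %.3f], bin-SD spread ratio %.2f\n",
              x$range[1], x$range[2], x$spread_ratio))
  invisible(x)
}

#' Cross-validated variable-group importance
#'
#' K-fold cross-validation of the whole-model random forest; per fold the
#' impurity importances are computed on the training portion, averaged
#' across folds, summed within the groups age (T), competition (N), site
#' and climate, and normalized to 100%.
#'
#' @param ds a `growth_dataset`.
#' @param k folds.
#' @param seed integer seed.
#' @param site,clim the site and climate variable sets.
#' @param n_trees forest size per fold.
#' @return named numeric vector (percent) over `T`, `Comp`, `Site`, `Clim`,
#'   summing to 100.
#' @export
cv_group_importance <- function(ds, k = 10, seed = 1,
                                site = DEFAULT_SITE_SET,
                                clim = DEFAULT_CLIM_SET,
                                n_trees = 500) {
  flat <- as.data.frame(ds)
  feats <- c("T", "N", site, clim)
  X <- flat[, feats, drop = FALSE]
  y <- flat$response
  n <- nrow(flat)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  imp_sum <- stats::setNames(numeric(length(feats)), feats)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    rf <- with_seed(child_seed(seed, f),
      randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                 ntree = n_trees))
    imp_sum <- imp_sum + rf$importance[feats, "IncNodePurity"]
  }
  imp <- imp_sum / k
  groups <- c(T = imp[["T"]], Comp = imp[["N"]],
              Site = sum(imp[site]), Clim = sum(imp[clim]))
  100 * groups / sum(groups)
}

#' Partial dependence of a prediction on one variable
#'
#' For each grid value `v`, the mean model prediction over the dataset
#' with the variable set to `v` everywhere (all other columns untouched).
#' Grid values outside the observed variable range trigger a warning.
#'
#' @param model any fitted model with a `predict(model, newdata)` method
#'   over flat data.frames (`rp_fit`, `curve_fit`, `bp_model`, `rf_model`).
#' @param ds a `growth_dataset` (or flat data.frame) providing the
#'   background rows.
#' @param variable variable name.
#' @param grid numeric grid; default `n_grid` equally spaced values over
#'   the observed range.
#' @param n_grid grid size when `grid` is `NULL`.
#' @return data.frame with columns `value` and `yhat`.
#' @export
partial_dependence <- function(model, ds, variable, grid = NULL,
                               n_grid = 20) {
  flat <- if (inherits(ds, "growth_dataset")) as.data.frame(ds)
  else as.data.frame(ds)
  if (!variable %in% names(flat))
    stop_itgrow(paste0("variable ", variable, " not in data"),
                "itgrow_validation_error")
  obs_range <- range(flat[[variable]])
  grid <- grid %||% seq(obs_range[1], obs_range[2], length.out = n_grid)
  if (any(grid < obs_range[1] - 1e-9 | grid > obs_range[2] + 1e-9))
    warning("grid extends outside the observed variable range",
            call. = FALSE)
  yhat <- vapply(grid, function(v) {
    d <- flat
    d[[variable]] <- v
    mean(predict(model, d))
  }, numeric(1))
  data.frame(value = grid, yhat = yhat)
}

#' Side-by-side comparison of fitted models on one test set
#'
#' Takes the named test metrics of competing methods (computed on the same
#' split), reports them in one table with the pairwise relative changes,
#' and names the winner per metric (ties reported as such).
#'
#' @param metrics named list of `growth_metrics` (e.g.,
#'   `list(RP = ..., BP = ..., RF = ...)`), all with equal `n`.
#' @return list with `table` (method x metric data.frame),
#'   `relative_changes` (data.frame: reference, comparison, metric,
#'   change_pct) and `winner` (named character, `"tie"` where tied).
#' @export
compare_models <- function(metrics) {
  if (is.null(names(metrics)) || any(names(metrics) == ""))
    stop_itgrow("metrics list must be named by method",
                "itgrow_validation_error")
  ns <- vapply(metrics, function(m) m$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop_itgrow("metrics were computed on different splits (n differs)",
                "itgrow_validation_error")
  tab <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(method = nm, r2 = m$r2, mae = m$mae, rmse = m$rmse, n = m$n)
  }))
  dirs <- c(r2 = "higher_better", mae = "lower_better",
            rmse = "lower_better")
  rel <- list()
  for (a in names(metrics)) for (b in names(metrics)) {
    if (a == b) next
    for (mt in names(dirs)) {
      rel[[length(rel) + 1]] <- data.frame(
        reference = a, comparison = b, metric = mt,
        change_pct = relative_change(metrics[[a]][[mt]],
                                     metrics[[b]][[mt]], dirs[[mt]]))
    }
  }
  winner <- vapply(names(dirs), function(mt) {
    vals <- tab[[mt]]
    best <- if (dirs[[mt]] == "higher_better") max(vals) else min(vals)
    w <- tab$method[abs(vals - best) < 1e-12]
    if (length(w) > 1) "tie" else w
  }, character(1))
  list(table = tab, relative_changes = do.call(rbind, rel), winner = winner)
}

#' Published reference test metrics
#'
#' The reference test-set metric tables for Chinese fir growth models in
#' Fujian Province (sub-model ladders for the network and forest diameter
#' models, and the three height models), shipped as a JSON fixture. These
#' are inputs for comparative arithmetic (see [relative_change()]); the
#' underlying inventory data are not public.
#'
#' @return nested list: `dbh_bp` and `dbh_rf` (per-rung train/test R²,
#'   MAE, RMSE), `dbh_rp`, `h_rp`, `h_bp`, `h_rf`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_test_metrics.json",
                      package = "itgrow")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
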