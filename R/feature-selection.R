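# Environment-variable screening: random-forest impurity importance per
# covariate group, Pearson correlation among covariates, and removal of the
# less important member of every strongly correlated pair.

#' Random-forest impurity importance ranking
#'
#' Importance of each column of `X` for predicting `y`, measured as the
#' impurity decrease summed over all splits on the variable and averaged
#' over the forest, then normalized to sum to 1. For a continuous response
#' the split impurity is node variance (the regression analogue of the Gini
#' measure used for classification).
#'
#' @param X numeric covariate data.frame/matrix (>= 2 columns).
#' @param y response vector (>= 30 values).
#' @param n_trees forest size.
#' @param seed integer seed; results are deterministic given it.
#' @param group optional label (`"Site"`, `"Clim"`, ...) stored on the
#'   result.
#' @param nodesize minimum terminal-node size of the forest. The package
#'   default (5) grows deep trees; larger values regularize the forest so
#'   uninformative variables collect less impurity decrease from deep
#'   near-noise splits, which stabilizes rankings.
#' @return an `importance_ranking`: data.frame with columns `variable` and
#'   `importance`, sorted descending, importances summing to 1.
#' @export
impurity_importance <- function(X, y, n_trees = 500, seed = 1,
                                group = NULL, nodesize = 5) {
  X <- as.data.frame(X)
  if (ncol(X) < 2)
    stop_itgrow("need >= 2 covariate columns", "itgrow_validation_error")
  if (length(y) < 30)
    stop_itgrow("need >= 30 observations", "itgrow_validation_error")
  if (stats::sd(y) == 0) {
    warning("constant response: importances are uniform", call. = FALSE)
    imp <- rep(1 / ncol(X), ncol(X))
    names(imp) <- names(X)
  } else {
    rf <- with_seed(seed,
      randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                 nodesize = nodesize))
    imp <- rf$importance[, "IncNodePurity"]
    if (sum(imp) == 0) imp[] <- 1
    imp <- imp / sum(imp)
  }
  out <- data.frame(variable = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("importance_ranking", "data.frame"),
            group = group)
}

#' Pearson correlation matrix
#'
#' Pairwise Pearson r between columns, diagonal 1. Constant columns yield
#' `NA` entries and a warning.
#'
#' @param X numeric data.frame/matrix with at least 3 rows.
#' @return symmetric correlation matrix.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (nrow(X) < 3)
    stop_itgrow("need >= 3 rows", "itgrow_validation_error")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const))
    warning(paste0("constant columns give undefined correlations: ",
                   paste(colnames(X)[const], collapse = ", ")),
            call. = FALSE)
  suppressWarnings(stats::cor(X))
}

#' Drop the weaker member of each strongly correlated pair
#'
#' Pairs with `|r| > threshold` are processed in descending `|r|`; within
#' each offending pair still fully retained, the lower-importance variable
#' is dropped. The survivors contain no pair above the threshold.
#'
#' @param ranking an `importance_ranking` (or data.frame with `variable`
#'   and `importance`) covering every matrix variable.
#' @param corr correlation matrix over the same variables.
#' @param threshold absolute-correlation cutoff (0.7 is the usual rule).
#' @return character vector of retained variables, in ranking order.
#' @export
correlation_screen <- function(ranking, corr, threshold = 0.7) {
  vars <- ranking$variable
  if (!all(rownames(corr) %in% vars) || !all(vars %in% rownames(corr)))
    stop_itgrow("ranking and correlation matrix cover different variables",
                "itgrow_validation_error")
  imp <- stats::setNames(ranking$importance, ranking$variable)
  pairs <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    r_abs <- abs(corr[pairs])
    pairs <- pairs[order(-r_abs), , drop = FALSE]
  }
  retained <- vars
  for (k in seq_len(nrow(pairs))) {
    v1 <- rownames(corr)[pairs[k, 1]]
    v2 <- colnames(corr)[pairs[k, 2]]
    if (!(v1 %in% retained) || !(v2 %in% retained)) next
    drop <- if (imp[v1] < imp[v2]) v1 else v2
    retained <- setdiff(retained, drop)
  }
  retained
}

#' Select the informative site and climate variable sets
#'
#' Fits one random forest of the full model — age, stand density and every
#' site and climate covariate — and ranks the site and climate variables by
#' their impurity decrease at node splitting within it (ranking against the
#' raw response without age in the forest would leave the age-driven
#' variance as noise and swamp the environmental signal). Per group the
#' `top_k` most important variables are kept, then [correlation_screen()]
#' removes the weaker member of every strongly correlated retained pair.
#' Under the generator's default configuration this reproduces the
#' reference selection outcome (Site = PW, HB, TRHD, PX, DM;
#' Clim = DD18, MAP, Eref).
#'
#' @param ds a `growth_dataset` with all site and climate columns.
#' @param top_k how many top-ranked variables to keep per group before
#'   correlation screening.
#' @param threshold correlation cutoff.
#' @param n_trees forest size for the ranking forest.
#' @param seed integer seed.
#' @param nodesize minimum terminal-node size of the ranking forest; the
#'   default (40) is deliberately larger than the usual regression default
#'   so repeated observations of the same plot cannot be isolated by deep
#'   splits on uninformative plot-level covariates.
#' @return list with `site` and `clim` (selected names), plus per-group
#'   `rankings` (importances renormalized within group) and `correlations`,
#'   and `dropped` (correlation-screen casualties per group).
#' @export
select_environment <- function(ds, top_k = 5, threshold = 0.7,
                               n_trees = 500, seed = 1, nodesize = 40) {
  flat <- as.data.frame(ds)
  y <- flat$response
  groups <- list(Site = site_variables(),
                 Clim = climate_variables(ds))
  all_vars <- c("T", "N", unlist(groups, use.names = FALSE))
  full <- impurity_importance(flat[, all_vars, drop = FALSE], y,
                              n_trees = n_trees, seed = seed,
                              nodesize = nodesize)
  imp <- stats::setNames(full$importance, full$variable)
  out <- list(rankings = list(), correlations = list(), dropped = list())
  for (g in names(groups)) {
    vars <- groups[[g]]
    gi <- imp[vars]
    gi <- sort(gi / sum(gi), decreasing = TRUE)
    rk <- structure(
      data.frame(variable = names(gi), importance = unname(gi)),
      class = c("importance_ranking", "data.frame"), group = g)
    top <- utils::head(rk, min(top_k, nrow(rk)))
    corr <- pearson_matrix(flat[, top$variable, drop = FALSE])
    kept <- correlation_screen(top, corr, threshold)
    out$rankings[[g]] <- rk
    out$correlations[[g]] <- corr
    out$dropped[[g]] <- setdiff(top$variable, kept)
    out[[tolower(g)]] <- kept
  }
  out
}
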