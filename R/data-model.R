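# Domain containers and plot-level data handling for continuous forest
# inventory (CFI) records: one observation per (tree, survey), one plot
# record per sample plot carrying density, site and climate covariates.

# Coded site factors and their legal code sets (fixed-plot survey coding:
# landform, slope aspect, slope position, soil name).
SITE_CODE_SETS <- list(
  DM   = c(3L, 4L, 5L),       # middle mountains / low mountains / hills
  PX   = 1:8,                 # slope aspect, N..NW clockwise
  PW   = 1:6,                 # slope position, ridge..flat
  TRMC = c(12L, 13L)          # red soil / lateritic soil
)

# Continuous site factors.
SITE_CONTINUOUS <- c("HB", "PD", "TRHD")

#' Site and climate variable names
#'
#' `site_variables()` returns the seven plot-level site factors (continuous
#' elevation `HB`, slope gradient `PD`, soil thickness `TRHD`, then the coded
#' factors `DM`, `PX`, `PW`, `TRMC`). `climate_variables()` returns the
#' climate column names of a dataset or plot table (every plot column that is
#' not an identifier, density or site factor).
#'
#' @param x a `growth_dataset` or a plot `data.frame`.
#' @return character vector of variable names.
#' @export
site_variables <- function() c(SITE_CONTINUOUS, names(SITE_CODE_SETS))

#' @rdname site_variables
#' @export
climate_variables <- function(x) {
  plots <- if (inherits(x, "growth_dataset")) x$plots else x
  setdiff(names(plots), c("plot_id", "N", site_variables()))
}

# Climate keys that must always be present.
REQUIRED_CLIMATE <- c("DD18", "MAP", "Eref", "MAT", "MCMT")

#' Construct a growth dataset
#'
#' Bundles per-tree survey observations with their plot records into the
#' container used throughout the package. Observations carry tree age `T`
#' and a single response kind (stem diameter at breast height `DBH` in cm,
#' or total height `H` in m); plots carry stand density `N` (stems per
#' plot), site factors and annual climate variables.
#'
#' @param observations data.frame with columns `plot_id`, `tree_id`,
#'   `survey_year`, `T` and `response`.
#' @param plots data.frame with columns `plot_id`, `N`, the site factors
#'   (`HB`, `PD`, `TRHD`, `DM`, `PX`, `PW`, `TRMC`) and climate columns
#'   (at least `DD18`, `MAP`, `Eref`, `MAT`, `MCMT`).
#' @param response_kind `"DBH"` or `"H"`.
#' @param validate run the full invariant checks (code sets, positivity,
#'   uniqueness, referential integrity).
#' @return an object of class `growth_dataset`: a list with elements
#'   `observations`, `plots` and `response_kind`.
#' @export
growth_dataset <- function(observations, plots,
                           response_kind = c("DBH", "H"),
                           validate = TRUE) {
  response_kind <- match.arg(response_kind)
  observations <- as.data.frame(observations)
  plots <- as.data.frame(plots)
  ds <- structure(
    list(observations = observations, plots = plots,
         response_kind = response_kind),
    class = "growth_dataset"
  )
  if (validate) validate_growth_dataset(ds)
  ds
}

#' Validate a growth dataset
#'
#' Checks the structural invariants: mandatory columns, site codes inside
#' their enumerated sets, positive responses and ages, unique
#' (plot, tree, survey) keys, unique plot ids, required climate columns, and
#' that every observation resolves to a plot. Errors name the offending rows.
#'
#' @param ds a `growth_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_growth_dataset <- function(ds) {
  obs <- ds$observations
  plots <- ds$plots

  need_obs <- c("plot_id", "tree_id", "survey_year", "T", "response")
  miss <- setdiff(need_obs, names(obs))
  if (length(miss))
    stop_itgrow(paste0("observation columns missing: ",
                       paste(miss, collapse = ", ")), "itgrow_schema_error")
  need_plot <- c("plot_id", "N", site_variables(), REQUIRED_CLIMATE)
  miss <- setdiff(need_plot, names(plots))
  if (length(miss))
    stop_itgrow(paste0("plot columns missing: ",
                       paste(miss, collapse = ", ")), "itgrow_schema_error")

  if (nrow(obs)) {
    bad <- which(!is.finite(obs$response) | obs$response <= 0)
    if (length(bad))
      stop_itgrow(paste0("non-positive response in observation rows: ",
                         paste(utils::head(bad, 10), collapse = ", ")),
                  "itgrow_validation_error")
    bad <- which(!is.finite(obs$T) | obs$T < 1)
    if (length(bad))
      stop_itgrow(paste0("age T < 1 in observation rows: ",
                         paste(utils::head(bad, 10), collapse = ", ")),
                  "itgrow_validation_error")
    key <- paste(obs$plot_id, obs$tree_id, obs$survey_year, sep = "\r")
    if (anyDuplicated(key))
      stop_itgrow(paste0("duplicate (plot, tree, survey) keys in rows: ",
                         paste(utils::head(which(duplicated(key)), 10),
                               collapse = ", ")),
                  "itgrow_validation_error")
    orphan <- which(!obs$plot_id %in% plots$plot_id)
    if (length(orphan))
      stop_itgrow(paste0("observations reference unknown plots, rows: ",
                         paste(utils::head(orphan, 10), collapse = ", ")),
                  "itgrow_validation_error")
  }

  if (anyDuplicated(plots$plot_id))
    stop_itgrow("duplicate plot_id in plot table", "itgrow_validation_error")
  if (nrow(plots)) {
    if (any(!is.finite(plots$N) | plots$N <= 0))
      stop_itgrow("plot density N must be positive", "itgrow_validation_error")
    for (v in names(SITE_CODE_SETS)) {
      bad <- which(!plots[[v]] %in% SITE_CODE_SETS[[v]])
      if (length(bad))
        stop_itgrow(paste0(v, " code outside {",
                           paste(SITE_CODE_SETS[[v]], collapse = ","),
                           "} in plot rows: ",
                           paste(utils::head(bad, 10), collapse = ", ")),
                    "itgrow_validation_error")
    }
    if (any(plots$HB < 0))
      stop_itgrow("HB (elevation) must be >= 0", "itgrow_validation_error")
    if (any(plots$PD < 0 | plots$PD > 90))
      stop_itgrow("PD (slope gradient) must be in [0, 90] degrees",
                  "itgrow_validation_error")
    if (any(plots$TRHD <= 0))
      stop_itgrow("TRHD (soil thickness) must be > 0",
                  "itgrow_validation_error")
  }
  invisible(ds)
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat("<growth_dataset> ", nrow(x$observations), " ", x$response_kind,
      " observations on ", nrow(x$plots), " plots (",
      length(climate_variables(x)), " climate variables)\n", sep = "")
  invisible(x)
}

#' Number of observations in a dataset
#' @param ds a `growth_dataset`.
#' @return integer count of observations.
#' @export
n_observations <- function(ds) nrow(ds$observations)

#' Flatten a growth dataset to one modelling frame
#'
#' Joins each observation to its plot record, producing the flat data.frame
#' (one row per tree survey; columns `plot_id`, `tree_id`, `survey_year`,
#' `T`, `response`, `N`, site factors, climate) consumed by the model-fitting
#' functions.
#'
#' @param x a `growth_dataset`.
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame.
#' @export
as.data.frame.growth_dataset <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  idx <- match(x$observations$plot_id, x$plots$plot_id)
  out <- cbind(x$observations,
               x$plots[idx, setdiff(names(x$plots), "plot_id"),
                       drop = FALSE])
  rownames(out) <- NULL
  out
}

# Stable CSV column order.
csv_column_order <- function(ds) {
  c("plot_id", "tree_id", "survey_year", "T", ds$response_kind,
    "N", "HB", "PD", "TRHD", "DM", "PX", "PW", "TRMC",
    climate_variables(ds))
}

#' Read a growth dataset from CSV
#'
#' Reads the flat inventory CSV (one row per tree survey; UTF-8, comma
#' separated, header row) and validates it. The response column must be
#' named after the response kind (`DBH` or `H`); site codes are checked
#' against their enumerations and offending rows reported.
#'
#' @param path CSV file path.
#' @param response_kind `"DBH"` or `"H"`.
#' @return a `growth_dataset`.
#' @export
read_growth_data <- function(path, response_kind = c("DBH", "H")) {
  response_kind <- match.arg(response_kind)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("plot_id", "tree_id", "survey_year", "T", response_kind,
            "N", site_variables())
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_itgrow(paste0("mandatory columns missing from ", path, ": ",
                       paste(miss, collapse = ", ")), "itgrow_schema_error")

  obs <- data.frame(plot_id = raw$plot_id, tree_id = raw$tree_id,
                    survey_year = raw$survey_year, T = raw$T,
                    response = raw[[response_kind]])
  plot_cols <- c("plot_id", "N", site_variables(),
                 setdiff(names(raw), c(need, "tree_id", "survey_year", "T")))
  plot_cols <- setdiff(unique(plot_cols), response_kind)
  plots <- unique(raw[, plot_cols, drop = FALSE])
  if (anyDuplicated(plots$plot_id))
    stop_itgrow("plot covariates are not constant within plot_id",
                "itgrow_validation_error")
  rownames(plots) <- NULL
  growth_dataset(obs, plots, response_kind)
}

#' Write a growth dataset to CSV
#'
#' Inverse of [read_growth_data()]: writes the flat schema with a stable
#' column order, so a write/read round trip reproduces the dataset.
#'
#' @param ds a `growth_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_data <- function(ds, path) {
  validate_growth_dataset(ds)
  flat <- as.data.frame(ds)
  names(flat)[names(flat) == "response"] <- ds$response_kind
  flat <- flat[, csv_column_order(ds), drop = FALSE]
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Grouped 3-sigma (Pauta) outlier filter
#'
#' Removes, plot by plot and in a single pass, observations whose response
#' deviates from the plot mean by more than `k` sample standard deviations,
#' both statistics computed once on the original (pre-removal) plot values.
#' Plots with fewer than 3 observations pass through unfiltered (their
#' sample SD is unstable), as do zero-variance plots.
#'
#' @param ds a `growth_dataset`.
#' @param k SD multiple; the 3-sigma rule is the default.
#' @return list with `kept` (a `growth_dataset`) and `removed` (data.frame
#'   of removed observation rows). Kept and removed partition the input.
#' @export
pauta_filter <- function(ds, k = 3) {
  obs <- ds$observations
  if (!nrow(obs))
    stop_itgrow("pauta_filter needs at least one observation",
                "itgrow_validation_error")
  drop <- logical(nrow(obs))
  for (pid in unique(obs$plot_id)) {
    i <- which(obs$plot_id == pid)
    if (length(i) < 3) next
    y <- obs$response[i]
    m <- mean(y)
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) next
    drop[i] <- abs(y - m) > k * s
  }
  kept <- growth_dataset(obs[!drop, , drop = FALSE], ds$plots,
                         ds$response_kind, validate = FALSE)
  rownames(kept$observations) <- NULL
  removed <- obs[drop, , drop = FALSE]
  rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Random train/test split
#'
#' Random partition by observation (the default) or by whole plot. The train
#' size is `round(fraction * n)`; the same seed always yields the same
#' membership.
#'
#' @param ds a `growth_dataset`.
#' @param fraction training proportion, in (0, 1).
#' @param seed integer seed controlling the permutation.
#' @param by_plot if `TRUE`, whole plots are assigned to one side
#'   (fraction then applies to plot counts).
#' @return list with `train` and `test` datasets; disjoint and exhaustive.
#' @export
split_train_test <- function(ds, fraction = 0.8, seed = 1, by_plot = FALSE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_itgrow("fraction must be in (0, 1)", "itgrow_validation_error")
  obs <- ds$observations
  if (nrow(obs) < 2)
    stop_itgrow("need at least 2 observations to split",
                "itgrow_validation_error")
  if (by_plot) {
    pids <- unique(obs$plot_id)
    n_tr <- round(fraction * length(pids))
    tr_pid <- with_seed(seed, sample(pids, n_tr))
    in_train <- obs$plot_id %in% tr_pid
  } else {
    n <- nrow(obs)
    n_tr <- round(fraction * n)
    idx <- with_seed(seed, sample.int(n, n_tr))
    in_train <- logical(n)
    in_train[idx] <- TRUE
  }
  mk <- function(keep) {
    d <- growth_dataset(obs[keep, , drop = FALSE], ds$plots,
                        ds$response_kind, validate = FALSE)
    rownames(d$observations) <- NULL
    d
  }
  list(train = mk(in_train), test = mk(!in_train))
}
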