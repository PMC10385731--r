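# Covariate-parameterized ("re-parameterized") Mitscherlich growth model:
# the curve's asymptote and rate are linear combinations of competition,
# site and climate covariates, estimated jointly by nonlinear least squares.
# Also holds the multicollinearity (VIF) and AIC stepwise screening used to
# choose which covariates enter.

#' Re-parameterized growth-model coefficients
#'
#' The coefficient set of the covariate-parameterized Mitscherlich model
#' \deqn{y = \omega_0 (1 - e^{-\omega_1 T}),\quad
#'       \omega_0 = \alpha_0 + \sum_j \alpha_j x_j,\quad
#'       \omega_1 = \beta_0 + \sum_j \beta_j x_j,}
#' where the \eqn{x_j} are the named covariates. `alpha` carries response
#' units (cm for DBH, m for H) per covariate unit; `beta` carries per-year
#' rate per covariate unit. Coded site factors enter as their numeric codes
#' (one coefficient per coded factor).
#'
#' @param variables ordered character vector of covariate names (the usual
#'   set is `N, PW, HB, TRHD, DM, DD18, Eref`).
#' @param alpha numeric vector of length `length(variables) + 1`: intercept
#'   then one coefficient per variable, for the asymptote.
#' @param beta same shape, for the rate.
#' @param response_kind `"DBH"` or `"H"`.
#' @return an object of class `rp_coefficients`.
#' @export
rp_coefficients <- function(variables, alpha, beta,
                            response_kind = c("DBH", "H")) {
  response_kind <- match.arg(response_kind)
  p <- length(variables)
  if (length(alpha) != p + 1 || length(beta) != p + 1)
    stop_itgrow("alpha and beta must each have length(variables) + 1 entries",
                "itgrow_validation_error")
  nm <- c("(Intercept)", variables)
  structure(list(variables = as.character(variables),
                 alpha = stats::setNames(as.numeric(alpha), nm),
                 beta = stats::setNames(as.numeric(beta), nm),
                 response_kind = response_kind),
            class = "rp_coefficients")
}

#' @export
print.rp_coefficients <- function(x, ...) {
  cat("<rp_coefficients> ", x$response_kind, " model, covariates: ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  print(rbind(alpha = x$alpha, beta = x$beta))
  invisible(x)
}

#' Published reference coefficient sets
#'
#' Coefficient estimates reported for Chinese fir (*Cunninghamia lanceolata*)
#' continuous-inventory plots in Fujian Province, shipped as JSON fixtures:
#' one set for stem diameter (DBH, cm) and one for total height (H, m), both
#' over the covariates `N, PW, HB, TRHD, DM, DD18, Eref`. The DM rate
#' coefficient is stored as 0.000 exactly as printed in the source table.
#' Pass one of these sets as the `coefficients` of a [generator_config()]
#' to run parameter-recovery studies against the published estimates.
#'
#' @param response_kind `"DBH"` or `"H"`.
#' @return an `rp_coefficients` object.
#' @export
rp_reference_coefficients <- function(response_kind = c("DBH", "H")) {
  response_kind <- match.arg(response_kind)
  file <- if (response_kind == "DBH") "rp_dbh_reference.json" else
    "rp_h_reference.json"
  path <- system.file("extdata", file, package = "itgrow")
  read_rp_coefficients(path)
}

#' Read/write coefficient sets as JSON
#'
#' Coefficients are exchanged as JSON keyed by variable name, so files are
#' self-describing and order-stable.
#'
#' @param path JSON file path.
#' @param coeffs an `rp_coefficients` object.
#' @return `read_rp_coefficients` returns an `rp_coefficients`;
#'   `write_rp_coefficients` returns `path` invisibly.
#' @export
read_rp_coefficients <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rp_coefficients(j$variables,
                  alpha = as.numeric(j$alpha), beta = as.numeric(j$beta),
                  response_kind = j$response_kind)
}

#' @rdname read_rp_coefficients
#' @export
write_rp_coefficients <- function(coeffs, path) {
  jsonlite::write_json(
    list(response_kind = coeffs$response_kind,
         variables = coeffs$variables,
         alpha = as.numeric(coeffs$alpha),
         beta = as.numeric(coeffs$beta)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Build the covariate matrix (rows x variables, in coefficient order) from
# a named vector, data.frame or matrix.
covariate_matrix <- function(coeffs, covariates) {
  vars <- coeffs$variables
  if (is.null(dim(covariates))) {
    if (is.null(names(covariates)))
      stop_itgrow("covariates must be named", "itgrow_validation_error")
    covariates <- as.data.frame(as.list(covariates))
  }
  covariates <- as.data.frame(covariates)
  miss <- setdiff(vars, names(covariates))
  if (length(miss))
    stop_itgrow(paste0("covariates missing: ", paste(miss, collapse = ", ")),
                "itgrow_validation_error")
  X <- as.matrix(covariates[, vars, drop = FALSE])
  if (anyNA(X))
    stop_itgrow("covariates contain missing values", "itgrow_validation_error")
  X
}

#' Evaluate the asymptote/rate pair
#'
#' Computes \eqn{\omega_0 = \alpha_0 + \sum \alpha_j x_j} and
#' \eqn{\omega_1 = \beta_0 + \sum \beta_j x_j} for one or many covariate
#' rows. Non-positive values are returned as-is with `valid = FALSE`; a
#' biologically meaningful Mitscherlich curve needs both positive.
#'
#' @param coeffs an `rp_coefficients`.
#' @param covariates named numeric vector, data.frame or matrix providing
#'   every coefficient covariate by name.
#' @return list with numeric vectors `omega0` (response units), `omega1`
#'   (per year) and logical `valid`.
#' @export
omega_pair <- function(coeffs, covariates) {
  X <- covariate_matrix(coeffs, covariates)
  Z <- cbind(1, X)
  w0 <- drop(Z %*% coeffs$alpha)
  w1 <- drop(Z %*% coeffs$beta)
  list(omega0 = unname(w0), omega1 = unname(w1),
       valid = unname(w0 > 0 & w1 > 0))
}

#' Predict growth from covariates and age
#'
#' Evaluates \eqn{\omega_0 (1 - e^{-\omega_1 T})}; exactly 0 at `T = 0` and
#' asymptoting to \eqn{\omega_0}. Rows with non-positive \eqn{\omega_0} or
#' \eqn{\omega_1} are still evaluated but flagged through the `"valid"`
#' attribute.
#'
#' @param coeffs an `rp_coefficients`.
#' @param covariates as in [omega_pair()]; one row, or one row per age.
#' @param T age(s) in years, `>= 0`.
#' @return numeric predictions with a logical `"valid"` attribute.
#' @export
rp_predict <- function(coeffs, covariates, T) {
  if (any(T < 0))
    stop_itgrow("ages T must be >= 0", "itgrow_validation_error")
  w <- omega_pair(coeffs, covariates)
  out <- w$omega0 * (1 - exp(-w$omega1 * T))
  attr(out, "valid") <- w$valid & rep(TRUE, length(out))
  out
}

#' Variance inflation factors
#'
#' VIF of each column of `X`: \eqn{1 / (1 - R^2_j)} with \eqn{R^2_j} from
#' the least-squares regression (with intercept) of column *j* on all other
#' columns. Perfectly collinear columns get `Inf`.
#'
#' @param X numeric matrix or data.frame of candidate covariates, at least
#'   two columns and more rows than columns.
#' @return named numeric vector of VIFs.
#' @export
vif_table <- function(X) {
  X <- as.matrix(as.data.frame(X))
  p <- ncol(X)
  if (p < 2) stop_itgrow("vif_table needs >= 2 columns",
                         "itgrow_validation_error")
  if (nrow(X) <= p) stop_itgrow("vif_table needs more rows than columns",
                                "itgrow_validation_error")
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(X))
}

#' Iterative VIF screening
#'
#' Repeatedly drops the highest-VIF column (ties resolved by dropping the
#' later-listed one) until every remaining VIF is below the threshold, then
#' returns the survivors in their original order.
#'
#' @param X numeric matrix or data.frame.
#' @param threshold VIF cutoff; 5 is the usual no-collinearity rule.
#' @return character vector of retained column names.
#' @export
vif_screen <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  keep <- names(X)
  while (length(keep) >= 2) {
    v <- vif_table(X[, keep, drop = FALSE])
    if (max(v) < threshold) break
    worst <- max(which(v >= max(v) - 1e-12))   # later-listed among ties
    keep <- keep[-worst]
  }
  keep
}

# Shared internals ----------------------------------------------------------

# Residuals and analytic Jacobian of the standardized-scale model for
# minpack.lm::nls.lm. theta = c(a0..ap, b0..bp) on the standardized scale.
rp_residual_fn <- function(theta, Z, T, y) {
  p1 <- ncol(Z)
  w0 <- drop(Z %*% theta[seq_len(p1)])
  w1 <- drop(Z %*% theta[p1 + seq_len(p1)])
  y - w0 * (1 - exp(-w1 * T))
}

rp_jacobian_fn <- function(theta, Z, T, y) {
  p1 <- ncol(Z)
  w0 <- drop(Z %*% theta[seq_len(p1)])
  w1 <- drop(Z %*% theta[p1 + seq_len(p1)])
  e <- exp(-w1 * T)
  # d res / d theta = -d pred / d theta
  cbind(-Z * (1 - e), -Z * (w0 * T * e))
}

#' Fitting control for the re-parameterized model
#'
#' @param max_iter Levenberg–Marquardt iteration cap per start.
#' @param tol relative tolerance on the sum of squares (and step size).
#' @param n_restarts jittered restarts tried when the first start does not
#'   converge or to escape poor local minima.
#' @param seed seed for the restart jitter.
#' @return list of control settings.
#' @export
rp_control <- function(max_iter = 1000, tol = 1e-12, n_restarts = 5,
                       seed = 1) {
  list(max_iter = max_iter, tol = tol, n_restarts = n_restarts, seed = seed)
}

#' Fit the covariate-parameterized Mitscherlich model
#'
#' Estimates the full coefficient set (`alpha`, `beta`) by nonlinear least
#' squares (Levenberg–Marquardt with analytic Jacobian). Covariates are
#' standardized internally for optimization and the coefficients are
#' back-transformed to the raw covariate scale for reporting. The start is
#' taken from the age-only Mitscherlich fit (asymptote -> alpha intercept,
#' rate -> beta intercept, covariate coefficients 0), with seeded jittered
#' restarts; non-convergence is flagged, carrying the best solution so far.
#'
#' With `variables = character(0)` the fit reduces to the age-only
#' Mitscherlich curve.
#'
#' @param train a `growth_dataset`.
#' @param variables character vector of covariate names to parameterize
#'   both the asymptote and the rate (one shared set, as in the model's
#'   definition).
#' @param control see [rp_control()].
#' @return an object of class `rp_fit`: list with `coefficients`
#'   (raw-scale `rp_coefficients`), `converged`, `sse`, `metrics`
#'   (training-set [compute_metrics()] result), `variables`, `n`.
#' @export
fit_rp <- function(train, variables, control = rp_control()) {
  flat <- as.data.frame(train)
  n <- nrow(flat)
  p <- length(variables)
  if (n < 2 * (p + 1) + 2)
    stop_itgrow("too few observations for the requested covariate set",
                "itgrow_validation_error")
  miss <- setdiff(variables, names(flat))
  if (length(miss))
    stop_itgrow(paste0("unknown covariates: ", paste(miss, collapse = ", ")),
                "itgrow_validation_error")
  y <- flat$response
  T <- flat$T

  # standardize covariates (constant columns kept with scale 1)
  if (p > 0) {
    X <- as.matrix(flat[, variables, drop = FALSE])
    mu <- colMeans(X)
    sigma <- apply(X, 2, stats::sd)
    sigma[!is.finite(sigma) | sigma == 0] <- 1
    Zs <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  } else {
    mu <- sigma <- numeric(0)
    Zs <- matrix(0, n, 0)
  }
  Z <- cbind(1, Zs)

  base <- fit_curve("Mitscherlich", train, n_restarts = control$n_restarts,
                    seed = control$seed)
  start <- c(base$curve$parameters[["a"]], rep(0, p),
             base$curve$parameters[["b"]], rep(0, p))

  run_lm <- function(theta0) {
    minpack.lm::nls.lm(
      par = theta0, fn = rp_residual_fn, jac = rp_jacobian_fn,
      Z = Z, T = T, y = y,
      control = minpack.lm::nls.lm.control(
        maxiter = min(control$max_iter, 1024),
        ftol = control$tol, ptol = control$tol, gtol = 0))
  }

  best <- run_lm(start)
  best_sse <- best$deviance
  ok <- best$info %in% 1:4
  if (!ok || !is.finite(best_sse)) {
    for (r in seq_len(control$n_restarts)) {
      theta0 <- with_seed(child_seed(control$seed, r),
                          start * stats::runif(length(start), 0.7, 1.3) +
                            stats::rnorm(length(start), 0, 1e-3))
      cand <- try(run_lm(theta0), silent = TRUE)
      if (inherits(cand, "try-error")) next
      if (is.finite(cand$deviance) && cand$deviance < best_sse) {
        best <- cand
        best_sse <- cand$deviance
        ok <- cand$info %in% 1:4
      }
    }
  }

  theta <- best$par
  p1 <- p + 1
  a_std <- theta[seq_len(p1)]
  b_std <- theta[p1 + seq_len(p1)]
  # back-transform: x_j enters as (x_j - mu_j)/sigma_j
  if (p > 0) {
    alpha <- c(a_std[1] - sum(a_std[-1] * mu / sigma), a_std[-1] / sigma)
    beta <- c(b_std[1] - sum(b_std[-1] * mu / sigma), b_std[-1] / sigma)
  } else {
    alpha <- a_std
    beta <- b_std
  }
  coeffs <- rp_coefficients(variables, alpha, beta, train$response_kind)
  pred <- y - rp_residual_fn(theta, Z, T, y)

  structure(list(coefficients = coeffs,
                 converged = ok,
                 sse = best_sse,
                 metrics = compute_metrics(y, pred),
                 variables = variables,
                 n = n),
            class = "rp_fit")
}

#' @export
print.rp_fit <- function(x, ...) {
  cat("<rp_fit> n = ", x$n, ", SSE = ", signif(x$sse, 6),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Predict from a fitted re-parameterized model
#'
#' @param object an `rp_fit`.
#' @param newdata a `growth_dataset` or flat data.frame with an age column
#'   `T` and the model's covariates.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.rp_fit <- function(object, newdata, ...) {
  flat <- if (inherits(newdata, "growth_dataset")) as.data.frame(newdata)
  else as.data.frame(newdata)
  as.numeric(rp_predict(object$coefficients, flat, flat$T))
}

#' AIC of an RP fit
#'
#' `n * log(SSE / n) + 2k` with `k` the number of free alpha/beta
#' coefficients (`2 * (|variables| + 1)`).
#' @param fit an `rp_fit`.
#' @return numeric AIC value.
#' @export
rp_aic <- function(fit) {
  k <- 2 * (length(fit$variables) + 1)
  fit$n * log(fit$sse / fit$n) + 2 * k
}

#' Both-direction AIC stepwise covariate selection
#'
#' Stepwise search over covariates entering the asymptote and rate
#' symmetrically (a variable is added or dropped for both linear predictors
#' at once, since the model uses one shared covariate set). Starting from
#' the empty set, at each step the single addition or removal that most
#' lowers AIC (`n log(SSE/n) + 2k`) is taken; the search stops when no move
#' improves. Each candidate model is a full nonlinear least-squares fit.
#'
#' @param train a `growth_dataset`.
#' @param candidates character vector of candidate covariate names (must be
#'   columns of the flattened dataset).
#' @param control see [rp_control()].
#' @param trace print the accepted moves.
#' @return character vector of selected covariates (possibly empty), in
#'   candidate order.
#' @export
stepwise_aic <- function(train, candidates, control = rp_control(),
                         trace = FALSE) {
  if (!length(candidates)) return(character(0))
  cache <- new.env(parent = emptyenv())
  aic_of <- function(vars) {
    key <- paste0("m|", paste(sort(vars), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(rp_aic(fit_rp(train, vars, control)),
                    error = function(e) Inf)
    cache[[key]] <- val
    val
  }
  current <- character(0)
  current_aic <- aic_of(current)
  repeat {
    moves <- list()
    for (v in setdiff(candidates, current))
      moves[[length(moves) + 1]] <- union(current, v)
    for (v in current)
      moves[[length(moves) + 1]] <- setdiff(current, v)
    if (!length(moves)) break
    scores <- vapply(moves, aic_of, numeric(1))
    if (min(scores) < current_aic - 1e-8) {
      best <- which.min(scores)
      current <- moves[[best]]
      current_aic <- scores[best]
      if (trace)
        message("step -> {", paste(current, collapse = ", "), "} AIC = ",
                signif(current_aic, 7))
    } else break
  }
  candidates[candidates %in% current]
}
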