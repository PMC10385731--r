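# Age-only candidate growth equations (Gompertz, Logistic, Mitscherlich,
# Richards), their least-squares fitting, and selection of the best base
# family before covariate parameterization.

CURVE_FAMILIES <- c("Gompertz", "Logistic", "Mitscherlich", "Richards")
CURVE_NPAR <- c(Gompertz = 3L, Logistic = 3L, Mitscherlich = 2L,
                Richards = 3L)

#' Construct a growth curve
#'
#' The four bounded-growth families used as base models:
#' \describe{
#'   \item{Gompertz}{\eqn{y = a e^{-b e^{-c t}}}}
#'   \item{Logistic}{\eqn{y = a / (1 + b e^{-c t})}}
#'   \item{Mitscherlich}{\eqn{y = a (1 - e^{-b t})} (two parameters)}
#'   \item{Richards}{\eqn{y = a (1 - e^{-c t})^b}}
#' }
#' `a` is the asymptote (response units) and must be positive.
#'
#' @param family one of `"Gompertz"`, `"Logistic"`, `"Mitscherlich"`,
#'   `"Richards"`.
#' @param a,b,c parameters; `c` is unused by Mitscherlich.
#' @return an object of class `growth_curve`.
#' @export
growth_curve <- function(family, a, b, c = NA_real_) {
  family <- match.arg(family, CURVE_FAMILIES)
  if (!is.na(a) && a <= 0)
    stop_itgrow("asymptote a must be positive", "itgrow_validation_error")
  if (family != "Mitscherlich" && is.na(c))
    stop_itgrow(paste0(family, " needs parameter c"),
                "itgrow_validation_error")
  structure(list(family = family,
                 parameters = c(a = as.numeric(a), b = as.numeric(b),
                                c = as.numeric(c))),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  p <- x$parameters
  cat("<growth_curve> ", x$family, ": a = ", signif(p["a"], 6),
      ", b = ", signif(p["b"], 6),
      if (x$family != "Mitscherlich") paste0(", c = ", signif(p["c"], 6)),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a growth curve at given ages
#'
#' Exact closed-form evaluation of the family equation.
#'
#' @param curve a `growth_curve`.
#' @param t ages in years, `>= 0`.
#' @return numeric vector of responses.
#' @export
curve_value <- function(curve, t) {
  if (any(t < 0)) stop_itgrow("t must be >= 0", "itgrow_validation_error")
  p <- curve$parameters
  switch(curve$family,
    Gompertz = p["a"] * exp(-p["b"] * exp(-p["c"] * t)),
    Logistic = p["a"] / (1 + p["b"] * exp(-p["c"] * t)),
    Mitscherlich = p["a"] * (1 - exp(-p["b"] * t)),
    Richards = p["a"] * (1 - exp(-p["c"] * t))^p["b"],
    stop_itgrow("unknown curve family", "itgrow_validation_error")
  ) |> unname()
}

# Log-linearized starting values for each family; a0 slightly above the
# observed maximum so the transforms are defined.
curve_start <- function(family, t, y) {
  a0 <- 1.05 * max(y)
  frac <- pmin(pmax(y / a0, 1e-6), 1 - 1e-6)
  st <- switch(family,
    Mitscherlich = {
      b0 <- unname(stats::coef(stats::lm(I(-log(1 - frac)) ~ 0 + t)))
      c(a = a0, b = max(b0, 1e-4))
    },
    Logistic = {
      f <- stats::lm(log(1 / frac - 1) ~ t)
      c(a = a0, b = exp(unname(stats::coef(f)[1])),
        c = max(-unname(stats::coef(f)[2]), 1e-4))
    },
    Gompertz = {
      f <- stats::lm(log(-log(frac)) ~ t)
      c(a = a0, b = exp(unname(stats::coef(f)[1])),
        c = max(-unname(stats::coef(f)[2]), 1e-4))
    },
    Richards = {
      b0 <- unname(stats::coef(stats::lm(I(-log(1 - frac)) ~ 0 + t)))
      c(a = a0, b = 1, c = max(b0, 1e-4))
    })
  st
}

curve_residual_fn <- function(family) {
  function(par, t, y) {
    cv <- switch(family,
      Gompertz = par[1] * exp(-par[2] * exp(-par[3] * t)),
      Logistic = par[1] / (1 + par[2] * exp(-par[3] * t)),
      Mitscherlich = par[1] * (1 - exp(-par[2] * t)),
      Richards = par[1] * (1 - exp(-par[3] * t))^par[2])
    y - cv
  }
}

#' Least-squares fit of one base growth family
#'
#' Minimizes the sum of squared residuals of the response on age by
#' Levenberg–Marquardt, starting from a log-linearization (asymptote 5%
#' above the observed maximum) with up to `n_restarts` seeded jittered
#' restarts. Non-convergence is flagged — not silently dropped — and the
#' best solution so far is returned; constant-response data yield a
#' degenerate flagged fit.
#'
#' @param family curve family name.
#' @param train a `growth_dataset` (or flat data.frame with `T` and
#'   `response`).
#' @param n_restarts jittered restarts before declaring non-convergence.
#' @param seed seed for the restart jitter.
#' @return an object of class `curve_fit`: list with `curve`
#'   (`growth_curve`), `converged`, `degenerate`, `sse`, `metrics`
#'   (training [compute_metrics()]), `n`.
#' @export
fit_curve <- function(family, train, n_restarts = 5, seed = 1) {
  family <- match.arg(family, CURVE_FAMILIES)
  flat <- if (inherits(train, "growth_dataset")) as.data.frame(train)
  else as.data.frame(train)
  t <- flat$T
  y <- flat$response
  npar <- CURVE_NPAR[[family]]
  if (length(y) < npar + 1)
    stop_itgrow("fewer observations than parameters + 1",
                "itgrow_validation_error")
  if (any(y <= 0))
    stop_itgrow("responses must be positive", "itgrow_validation_error")

  if (stats::sd(y) == 0) {
    # flat data: asymptote = the constant, rate degenerate
    curve <- growth_curve(family, a = y[1], b = 1e3,
                          c = if (family == "Mitscherlich") NA_real_ else 1e3)
    return(structure(list(curve = curve, converged = FALSE,
                          degenerate = TRUE, sse = 0,
                          metrics = compute_metrics(y, rep(y[1], length(y))),
                          n = length(y)),
                     class = "curve_fit"))
  }

  start <- curve_start(family, t, y)
  resid_fn <- curve_residual_fn(family)
  run <- function(par0) {
    minpack.lm::nls.lm(par = par0, fn = resid_fn, t = t, y = y,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, ftol = 1e-12, ptol = 1e-12))
  }
  best <- try(run(start), silent = TRUE)
  failed <- inherits(best, "try-error")
  best_sse <- if (failed) Inf else best$deviance
  ok <- !failed && best$info %in% 1:4
  for (r in seq_len(n_restarts)) {
    if (ok && r > 1) break
    par0 <- with_seed(child_seed(seed, r),
                      start * stats::runif(length(start), 0.5, 1.5))
    cand <- try(run(par0), silent = TRUE)
    if (inherits(cand, "try-error")) next
    if (is.finite(cand$deviance) && cand$deviance < best_sse) {
      best <- cand
      best_sse <- cand$deviance
      ok <- cand$info %in% 1:4
      failed <- FALSE
    }
  }
  if (failed)
    stop_itgrow(paste0(family, " fit failed from every start"),
                "itgrow_fit_error")

  par <- best$par
  par[1] <- max(par[1], 1e-8)   # keep the asymptote positive
  curve <- growth_curve(family, a = par[1], b = par[2],
                        c = if (npar == 3) par[3] else NA_real_)
  pred <- curve_value(curve, t)
  structure(list(curve = curve, converged = ok, degenerate = FALSE,
                 sse = best_sse, metrics = compute_metrics(y, pred),
                 n = length(y)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  print(x$curve)
  cat("  n = ", x$n, ", SSE = ", signif(x$sse, 6),
      if (!x$converged) " (NOT converged)",
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted base curve
#' @param object a `curve_fit`.
#' @param newdata `growth_dataset` or data.frame with column `T`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.curve_fit <- function(object, newdata, ...) {
  flat <- if (inherits(newdata, "growth_dataset")) as.data.frame(newdata)
  else as.data.frame(newdata)
  curve_value(object$curve, flat$T)
}

#' Fit and rank the candidate base families
#'
#' Fits each family on the training set and ranks the convergent ones by
#' test-set R² (descending), breaking ties by test RMSE (ascending) and
#' then by fewer parameters. Training metrics are reported alongside;
#' non-convergent families are listed separately rather than ranked.
#'
#' @param train,test `growth_dataset`s.
#' @param families candidate family names.
#' @param n_restarts,seed passed to [fit_curve()].
#' @return list with `ranking` (data.frame: family, n_parameters, train and
#'   test R²/RMSE/MAE), `fits` (named list of `curve_fit`s) and
#'   `not_converged` (character).
#' @export
select_base_model <- function(train, test, families = CURVE_FAMILIES,
                              n_restarts = 5, seed = 1) {
  fits <- list()
  rows <- list()
  bad <- character(0)
  test_flat <- as.data.frame(test)
  for (fam in families) {
    fit <- tryCatch(fit_curve(fam, train, n_restarts, seed),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      bad <- c(bad, fam)
      if (!is.null(fit)) fits[[fam]] <- fit
      next
    }
    fits[[fam]] <- fit
    m_test <- compute_metrics(test_flat$response, predict(fit, test_flat))
    rows[[fam]] <- data.frame(
      family = fam, n_parameters = CURVE_NPAR[[fam]],
      train_r2 = fit$metrics$r2, train_rmse = fit$metrics$rmse,
      train_mae = fit$metrics$mae,
      test_r2 = m_test$r2, test_rmse = m_test$rmse, test_mae = m_test$mae)
  }
  if (!length(rows))
    stop_itgrow("no base family converged", "itgrow_fit_error")
  ranking <- do.call(rbind, rows)
  ord <- order(-round(ranking$test_r2, 12), round(ranking$test_rmse, 12),
               ranking$n_parameters)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, fits = fits, not_converged = bad)
}
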