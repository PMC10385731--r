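test_that("rp_coefficients validates shapes", {
  expect_error(rp_coefficients(c("N", "PW"), alpha = c(1, 2), beta = 1:3),
               class = "itgrow_validation_error")
  cf <- rp_coefficients("N", alpha = c(10, 0.1), beta = c(0.05, 0))
  expect_named(cf$alpha, c("(Intercept)", "N"))
})

test_that("reference coefficient sets load with the published values", {
  dbh <- rp_reference_coefficients("DBH")
  expect_equal(dbh$variables,
               c("N", "PW", "HB", "TRHD", "DM", "DD18", "Eref"))
  expect_equal(unname(dbh$alpha[["(Intercept)"]]), -20.041)
  expect_equal(unname(dbh$alpha[["TRHD"]]), 0.155)
  expect_equal(unname(dbh$beta[["(Intercept)"]]), 0.039)
  expect_equal(unname(dbh$beta[["DM"]]), 0)
  h <- rp_reference_coefficients("H")
  expect_equal(unname(h$alpha[["(Intercept)"]]), -2.301)
  expect_equal(unname(h$beta[["(Intercept)"]]), 0.063)
})

test_that("omega_pair and rp_predict reproduce the hand-checked oracle", {
  dbh <- rp_reference_coefficients("DBH")
  x <- oracle_covariates()
  w <- omega_pair(dbh, x)
  expect_equal(w$omega0, 16.59, tolerance = 1e-6)
  expect_equal(w$omega1, 0.04099896, tolerance = 1e-7)
  expect_true(w$valid)
  pred <- rp_predict(dbh, x, 23)
  expect_equal(as.numeric(pred), 10.12874, tolerance = 1e-5)
  expect_equal(round(as.numeric(pred), 2), 10.13)
  expect_true(attr(pred, "valid"))
})

test_that("rp_predict is 0 at age 0 and flags invalid parameter rows", {
  dbh <- rp_reference_coefficients("DBH")
  x <- oracle_covariates()
  expect_equal(as.numeric(rp_predict(dbh, x, 0)), 0)
  expect_error(rp_predict(dbh, x, -2), class = "itgrow_validation_error")

  bad <- rp_coefficients("N", alpha = c(-5, 0), beta = c(0.05, 0))
  p <- rp_predict(bad, c(N = 100), 10)
  expect_false(attr(p, "valid"))
})

test_that("vif_table matches car::vif", {
  X <- withr::with_seed(1, {
    x1 <- rnorm(200)
    x2 <- 0.8 * x1 + 0.6 * rnorm(200)
    x3 <- rnorm(200)
    data.frame(x1 = x1, x2 = x2, x3 = x3)
  })
  y <- withr::with_seed(2, rnorm(200))
  ours <- vif_table(X)
  theirs <- car::vif(stats::lm(y ~ x1 + x2 + x3, data = cbind(X, y = y)))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})

test_that("vif_table flags perfect collinearity and input problems", {
  X <- data.frame(a = 1:10, b = (1:10) * 2, c = rnorm(10))
  v <- vif_table(X)
  expect_true(is.infinite(v[["a"]]))
  expect_true(is.infinite(v[["b"]]))
  expect_error(vif_table(X[, 1, drop = FALSE]),
               class = "itgrow_validation_error")
  expect_error(vif_table(X[1:3, ]), class = "itgrow_validation_error")
})

test_that("vif_screen drops until all VIFs clear the threshold", {
  X <- withr::with_seed(3, {
    x1 <- rnorm(300)
    x2 <- x1 + rnorm(300, 0, 0.05)   # near-duplicate of x1
    x3 <- rnorm(300)
    x4 <- x3 + rnorm(300, 0, 0.05)   # near-duplicate of x3
    data.frame(x1, x2, x3, x4)
  })
  kept <- vif_screen(X, threshold = 5)
  expect_true(all(vif_table(X[, kept]) < 5))
  # exactly one member of each near-duplicate pair survives
  expect_equal(sum(c("x1", "x2") %in% kept), 1)
  expect_equal(sum(c("x3", "x4") %in% kept), 1)
  expect_length(kept, 2)

  # exact VIF ties (perfect collinearity) drop the later-listed column
  tied <- withr::with_seed(5,
    data.frame(a = rnorm(30), c = rnorm(30)))
  tied$b <- 2 * tied$a
  expect_equal(vif_screen(tied[, c("a", "b", "c")]), c("a", "c"))

  ortho <- withr::with_seed(4, data.frame(a = rnorm(50), b = rnorm(50)))
  expect_equal(vif_screen(ortho), c("a", "b"))
})

test_that("fit_rp recovers the generating coefficients without noise", {
  ref <- rp_reference_coefficients("DBH")
  cfg <- generator_config("DBH", n_plots = 100, trees_per_plot = 3,
                          coefficients = ref, noise_sd = 0)
  ds <- suppressWarnings(simulate_inventory(cfg, seed = 21))
  fit <- fit_rp(ds, ref$variables, rp_control(seed = 21))
  expect_true(fit$converged)
  est <- c(fit$coefficients$alpha, fit$coefficients$beta)
  tru <- c(ref$alpha, ref$beta)
  sel <- abs(tru) > 1e-5
  expect_lt(max(abs(est[sel] - tru[sel]) / abs(tru[sel])), 1e-3)
  expect_lt(fit$sse, 1e-8 * n_observations(ds))
})

test_that("fit_rp with no covariates reduces to the age-only curve", {
  ds <- small_sim()
  fit0 <- fit_rp(ds, character(0), rp_control(seed = 2))
  base <- fit_curve("Mitscherlich", ds, seed = 2)
  expect_equal(unname(fit0$coefficients$alpha[["(Intercept)"]]),
               unname(base$curve$parameters[["a"]]), tolerance = 1e-5)
  expect_equal(unname(fit0$coefficients$beta[["(Intercept)"]]),
               unname(base$curve$parameters[["b"]]), tolerance = 1e-5)
})

test_that("fit_rp validates inputs and predict matches rp_predict", {
  ds <- small_sim()
  expect_error(fit_rp(ds, c("N", "NOPE")), class = "itgrow_validation_error")
  tiny <- tiny_dataset()
  expect_error(fit_rp(tiny, c("N", "HB", "DD18")),
               class = "itgrow_validation_error")

  fit <- fit_rp(ds, c("N", "DD18"), rp_control(seed = 4))
  flat <- as.data.frame(ds)[1:10, ]
  expect_equal(predict(fit, flat),
               as.numeric(rp_predict(fit$coefficients, flat, flat$T)))
})

test_that("coefficient JSON round trip is exact", {
  ref <- rp_reference_coefficients("H")
  path <- withr::local_tempfile(fileext = ".json")
  write_rp_coefficients(ref, path)
  back <- read_rp_coefficients(path)
  expect_equal(back$alpha, ref$alpha)
  expect_equal(back$beta, ref$beta)
  expect_equal(back$variables, ref$variables)
  expect_equal(back$response_kind, "H")
})

test_that("rp_aic applies n log(SSE/n) + 2k", {
  ds <- small_sim()
  fit <- fit_rp(ds, c("N", "DD18"), rp_control(seed = 4))
  k <- 2 * (2 + 1)
  expect_equal(rp_aic(fit), fit$n * log(fit$sse / fit$n) + 2 * k)
})

test_that("stepwise_aic keeps informative covariates and minimizes AIC", {
  cfg <- generator_config("DBH", n_plots = 80, trees_per_plot = 2,
                          n_surveys = 3)
  ds <- suppressWarnings(simulate_inventory(cfg, seed = 13))
  ctl <- rp_control(seed = 13)
  sel <- stepwise_aic(ds, c("Eref", "PD"), ctl)
  expect_true("Eref" %in% sel)
  # with two candidates the greedy search should reach the global optimum:
  # compare against the exhaustive scan of all four subsets
  subsets <- list(character(0), "Eref", "PD", c("Eref", "PD"))
  aics <- vapply(subsets, function(v) rp_aic(fit_rp(ds, v, ctl)), numeric(1))
  expect_equal(rp_aic(fit_rp(ds, sel, ctl)), min(aics))
  expect_equal(stepwise_aic(ds, character(0)), character(0))
})
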