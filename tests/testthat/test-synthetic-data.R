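test_that("generator_config has response-specific defaults and validates", {
  cfg <- generator_config("DBH")
  expect_equal(cfg$n_plots, 600L)
  expect_equal(cfg$trees_per_plot, 3L)
  expect_equal(cfg$n_surveys, 4L)
  expect_equal(cfg$noise_sd, 2)
  cfg_h <- generator_config("H")
  expect_equal(cfg_h$n_plots, 36L)
  expect_equal(cfg_h$n_surveys, 3L)
  expect_equal(cfg_h$noise_sd, 1)

  expect_error(generator_config("DBH", ranges = list(DD18 = c(10, 5))),
               class = "itgrow_validation_error")
  expect_error(generator_config("DBH", noise_sd = -1),
               class = "itgrow_validation_error")
  bad <- diag(17)
  expect_error(generator_config("DBH", climate_correlation = bad * 2),
               class = "itgrow_validation_error")
})

test_that("default climate correlation is a valid correlation matrix", {
  cfg <- generator_config("DBH")
  C <- cfg$climate_correlation
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, ncol(C)))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_gt(C["MAT", "Eref"], 0.7)
  expect_gt(C["MCMT", "DD18"], 0.7)
})

test_that("generate_plots respects ranges, code sets and the seed", {
  cfg <- generator_config("DBH")
  plots <- generate_plots(cfg, n_plots = 200, seed = 4)
  expect_equal(nrow(plots), 200)
  for (nm in c("N", "HB", "PD", "TRHD", "DD18", "MAP", "Eref")) {
    expect_gte(min(plots[[nm]]), cfg$ranges[[nm]][1])
    expect_lte(max(plots[[nm]]), cfg$ranges[[nm]][2])
  }
  expect_true(all(plots$DM %in% c(3, 4, 5)))
  expect_true(all(plots$PX %in% 1:8))
  expect_true(all(plots$PW %in% 1:6))
  expect_true(all(plots$TRMC %in% c(12, 13)))

  again <- generate_plots(cfg, n_plots = 200, seed = 4)
  expect_identical(plots, again)
  other <- generate_plots(cfg, n_plots = 200, seed = 5)
  expect_false(identical(plots, other))
})

test_that("sampled climate carries the configured correlation", {
  cfg <- generator_config("DBH")
  plots <- generate_plots(cfg, n_plots = 2000, seed = 8)
  expect_gt(stats::cor(plots$MAT, plots$Eref), 0.7)
  expect_gt(stats::cor(plots$MCMT, plots$DD18), 0.7)
  # an independent pair stays near zero
  expect_lt(abs(stats::cor(plots$MSP, plots$DD18)), 0.1)
})

test_that("simulate_inventory produces a valid, deterministic dataset", {
  cfg <- generator_config("DBH", n_plots = 30, trees_per_plot = 2,
                          n_surveys = 3)
  ds <- simulate_inventory(cfg, seed = 3)
  expect_s3_class(ds, "growth_dataset")
  expect_equal(n_observations(ds), 30 * 2 * 3)
  expect_silent(validate_growth_dataset(ds))

  flat <- as.data.frame(ds)
  expect_true(all(flat$T >= cfg$age_range[1] & flat$T <= cfg$age_range[2]))
  ages <- tapply(flat$T, flat$tree_id, function(a) diff(sort(a)))
  expect_true(all(unlist(ages) == cfg$survey_interval))
  expect_true(all(flat$response >= cfg$response_floor))

  expect_identical(simulate_inventory(cfg, seed = 3)$observations,
                   ds$observations)
  expect_false(identical(simulate_inventory(cfg, seed = 4)$observations,
                         ds$observations))
})

test_that("noiseless generation matches the model law exactly", {
  ref <- rp_reference_coefficients("DBH")
  cfg <- generator_config("DBH", n_plots = 20, trees_per_plot = 2,
                          n_surveys = 2, coefficients = ref, noise_sd = 0)
  ds <- simulate_inventory(cfg, seed = 2)
  flat <- as.data.frame(ds)
  mu <- as.numeric(rp_predict(ref, flat, flat$T))
  expect_equal(flat$response, pmax(mu, cfg$response_floor), tolerance = 1e-12)

  # cross-check one row by hand arithmetic
  r <- flat[5, ]
  x <- c(N = r$N, PW = r$PW, HB = r$HB, TRHD = r$TRHD, DM = r$DM,
         DD18 = r$DD18, Eref = r$Eref)
  w0 <- ref$alpha[1] + sum(ref$alpha[-1] * x)
  w1 <- ref$beta[1] + sum(ref$beta[-1] * x)
  expect_equal(r$response, unname(w0 * (1 - exp(-w1 * r$T))),
               tolerance = 1e-10)
})

test_that("mean diameter lands at a realistic level near age 23", {
  ds <- default_sim(42)
  flat <- as.data.frame(ds)
  sub <- flat$T >= 21 & flat$T <= 25
  expect_gt(sum(sub), 100)
  m <- mean(flat$response[sub])
  expect_gt(m, 0.6 * 15.6)
  expect_lt(m, 1.4 * 15.6)
})

test_that("generator_config_from_file reads YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("response_kind: DBH", "n_plots: 12", "trees_per_plot: 2",
               "n_surveys: 2", "noise_sd: 0.5",
               "ranges:", "  DD18: [800, 1200]"), y)
  cfg <- generator_config_from_file(y)
  expect_equal(cfg$n_plots, 12)
  expect_equal(cfg$noise_sd, 0.5)
  expect_equal(cfg$ranges$DD18, c(800, 1200))
  expect_equal(cfg$ranges$MAP, c(1400, 2000))   # untouched default

  j <- withr::local_tempfile(fileext = ".json")
  ref <- rp_reference_coefficients("H")
  jsonlite::write_json(list(response_kind = "H", n_plots = 5,
                            coefficients = list(
                              response_kind = "H",
                              variables = ref$variables,
                              alpha = as.numeric(ref$alpha),
                              beta = as.numeric(ref$beta))),
                       j, auto_unbox = TRUE, digits = NA)
  cfg2 <- generator_config_from_file(j)
  expect_equal(cfg2$n_plots, 5)
  expect_equal(cfg2$coefficients$alpha, ref$alpha)
})

test_that("inject_outliers corrupts the requested share and is recoverable", {
  cfg <- generator_config("DBH", n_plots = 30, trees_per_plot = 10,
                          n_surveys = 4)
  ds <- suppressWarnings(simulate_inventory(cfg, seed = 6))
  n <- n_observations(ds)

  none <- inject_outliers(ds, rate = 0, seed = 1)
  expect_equal(nrow(none$injected), 0)
  expect_identical(none$dataset$observations, ds$observations)

  out <- inject_outliers(ds, rate = 0.02, magnitude = 6, seed = 1)
  expect_equal(nrow(out$injected), round(0.02 * n))
  expect_error(inject_outliers(ds, rate = 0.02, magnitude = 2),
               class = "itgrow_validation_error")
  expect_error(inject_outliers(ds, rate = 1.2),
               class = "itgrow_validation_error")

  fl <- pauta_filter(out$dataset)
  rem_key <- paste(fl$removed$plot_id, fl$removed$tree_id,
                   fl$removed$survey_year)
  inj_key <- paste(out$injected$plot_id, out$injected$tree_id,
                   out$injected$survey_year)
  recall <- mean(inj_key %in% rem_key)
  expect_gte(recall, 0.8)
  false_pos <- sum(!rem_key %in% inj_key)
  expect_lte(false_pos, 0.02 * n)
})

test_that("invalid generating parameters trigger redraw with warning", {
  # an absurd negative asymptote intercept makes most draws invalid
  ref <- rp_reference_coefficients("DBH")
  bad <- rp_coefficients(ref$variables,
                         alpha = c(-1e6, ref$alpha[-1]),
                         beta = ref$beta, response_kind = "DBH")
  cfg <- generator_config("DBH", n_plots = 5, trees_per_plot = 1,
                          n_surveys = 1, coefficients = bad)
  expect_error(suppressWarnings(simulate_inventory(cfg, seed = 1)),
               class = "itgrow_fit_error")
})
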