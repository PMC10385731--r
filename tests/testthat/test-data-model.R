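test_that("growth_dataset builds and prints", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "growth_dataset")
  expect_equal(n_observations(ds), 6)
  expect_output(print(ds), "6 DBH observations on 3 plots")
})

test_that("validation catches missing columns with the schema class", {
  plots <- tiny_plots()
  obs <- tiny_dataset()$observations
  expect_error(growth_dataset(obs[, -4], plots, "DBH"),
               class = "itgrow_schema_error")
  expect_error(growth_dataset(obs, plots[, setdiff(names(plots), "DD18")],
                              "DBH"),
               class = "itgrow_schema_error")
})

test_that("validation names offending rows and codes", {
  plots <- tiny_plots()
  obs <- tiny_dataset()$observations

  bad <- obs; bad$response[2] <- -1
  err <- expect_error(growth_dataset(bad, plots, "DBH"),
                      class = "itgrow_validation_error")
  expect_match(conditionMessage(err), "rows: 2")

  bad <- obs; bad$T[3] <- 0
  expect_error(growth_dataset(bad, plots, "DBH"),
               class = "itgrow_validation_error")

  bad <- obs; bad$survey_year[2] <- bad$survey_year[1]
  bad$tree_id[2] <- bad$tree_id[1]; bad$plot_id[2] <- bad$plot_id[1]
  expect_error(growth_dataset(bad, plots, "DBH"), "duplicate",
               class = "itgrow_validation_error")

  bad <- obs; bad$plot_id[1] <- "P99"
  expect_error(growth_dataset(bad, plots, "DBH"), "unknown plots",
               class = "itgrow_validation_error")

  badp <- plots; badp$DM[1] <- 7L
  err <- expect_error(growth_dataset(obs, badp, "DBH"),
                      class = "itgrow_validation_error")
  expect_match(conditionMessage(err), "DM code outside \\{3,4,5\\}")

  badp <- plots; badp$plot_id[2] <- badp$plot_id[1]
  expect_error(validate_growth_dataset(
    structure(list(observations = obs[0, ], plots = badp,
                   response_kind = "DBH"), class = "growth_dataset")),
    "duplicate plot_id", class = "itgrow_validation_error")
})

test_that("site and climate variable helpers agree with the schema", {
  expect_equal(site_variables(),
               c("HB", "PD", "TRHD", "DM", "PX", "PW", "TRMC"))
  ds <- tiny_dataset()
  expect_setequal(climate_variables(ds),
                  c("DD18", "MAP", "Eref", "MAT", "MCMT"))
})

test_that("as.data.frame joins each observation to its plot record", {
  ds <- tiny_dataset(n_plots = 4, reps = 2)
  flat <- as.data.frame(ds)
  expect_equal(nrow(flat), 8)
  i <- which(flat$plot_id == "P03")[1]
  p <- ds$plots[ds$plots$plot_id == "P03", ]
  expect_equal(flat$HB[i], p$HB)
  expect_equal(flat$DD18[i], p$DD18)
  expect_equal(flat$N[i], p$N)
})

test_that("CSV write/read round trip preserves the dataset", {
  ds <- tiny_dataset(n_plots = 4, reps = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_data(ds, path)
  back <- read_growth_data(path, "DBH")
  expect_equal(back$response_kind, "DBH")
  expect_equal(back$observations$response, ds$observations$response)
  expect_equal(back$observations$T, ds$observations$T)
  o1 <- ds$plots[order(ds$plots$plot_id), ]
  o2 <- back$plots[order(back$plots$plot_id), names(o1)]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("read_growth_data rejects broken files", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_data(ds, path)
  raw <- utils::read.csv(path, check.names = FALSE)

  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw[, setdiff(names(raw), "PW")], p2, row.names = FALSE)
  expect_error(read_growth_data(p2, "DBH"), "PW",
               class = "itgrow_schema_error")

  raw$HB[1] <- raw$HB[1] + 1   # plot covariate no longer constant in plot
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, p3, row.names = FALSE)
  expect_error(read_growth_data(p3, "DBH"), "not constant",
               class = "itgrow_validation_error")
})

test_that("pauta_filter removes 3-sigma outliers plot by plot", {
  plots <- tiny_plots(2)
  y1 <- c(10, 11, 9, 10.5, 9.5, 10, 11, 9, 10, 10.2, 9.8, 10.1,
          9.9, 10.3, 9.7, 10.4, 9.6, 10.2, 9.8, 10, 60)   # 21 values
  obs <- data.frame(
    plot_id = rep("P01", 21),
    tree_id = sprintf("P01-T%03d", 1:21),
    survey_year = 2000L, T = 10, response = y1)
  ds <- growth_dataset(obs, plots, "DBH")
  out <- pauta_filter(ds)
  expect_equal(nrow(out$removed), 1)
  expect_equal(out$removed$response, 60)
  expect_equal(n_observations(out$kept) + nrow(out$removed),
               n_observations(ds))
})

test_that("pauta_filter is single pass and exempts tiny plots", {
  plots <- tiny_plots(2)
  # P01: one extreme point inflates the SD so a moderate point survives
  # the single pass (it would fall outside 3 SD of the cleaned plot).
  y <- c(rep(10, 30), 13, 100)
  obs1 <- data.frame(plot_id = "P01", tree_id = sprintf("A%03d", 1:32),
                     survey_year = 2000L, T = 10, response = y)
  # P02: two observations only -> exempt even though far apart
  obs2 <- data.frame(plot_id = "P02", tree_id = c("B001", "B002"),
                     survey_year = 2000L, T = 10, response = c(1, 50))
  ds <- growth_dataset(rbind(obs1, obs2), plots, "DBH")
  out <- pauta_filter(ds)
  expect_equal(out$removed$response, 100)
  expect_true(all(c(1, 50, 13) %in% out$kept$observations$response))

  # cleaned statistics would have flagged 13 too: confirms one pass only
  expect_gt(abs(13 - mean(rep(10, 30))) / stats::sd(c(rep(10, 30), 13)), 3)
})

test_that("pauta_filter keeps zero-variance plots intact", {
  plots <- tiny_plots(1)
  obs <- data.frame(plot_id = "P01", tree_id = sprintf("T%02d", 1:5),
                    survey_year = 2000L, T = 10, response = rep(7, 5))
  out <- pauta_filter(growth_dataset(obs, plots, "DBH"))
  expect_equal(n_observations(out$kept), 5)
  expect_equal(nrow(out$removed), 0)
})

test_that("split_train_test partitions deterministically", {
  ds <- small_sim()
  n <- n_observations(ds)
  sp <- split_train_test(ds, fraction = 0.8, seed = 11)
  expect_equal(n_observations(sp$train), round(0.8 * n))
  expect_equal(n_observations(sp$train) + n_observations(sp$test), n)

  key <- function(d) paste(d$observations$plot_id, d$observations$tree_id,
                           d$observations$survey_year)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)

  sp2 <- split_train_test(ds, fraction = 0.8, seed = 11)
  expect_identical(sp$train$observations, sp2$train$observations)
  sp3 <- split_train_test(ds, fraction = 0.8, seed = 12)
  expect_false(identical(sp$train$observations, sp3$train$observations))
})

test_that("split_train_test by plot keeps plots intact", {
  ds <- small_sim()
  sp <- split_train_test(ds, fraction = 0.8, seed = 3, by_plot = TRUE)
  expect_length(intersect(unique(sp$train$observations$plot_id),
                          unique(sp$test$observations$plot_id)), 0)
  expect_equal(length(unique(sp$train$observations$plot_id)),
               round(0.8 * nrow(ds$plots)))
})

test_that("split_train_test validates the fraction", {
  ds <- tiny_dataset()
  expect_error(split_train_test(ds, fraction = 0),
               class = "itgrow_validation_error")
  expect_error(split_train_test(ds, fraction = 1),
               class = "itgrow_validation_error")
})
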