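# Shared builders for the test suite. Small hand-built fixtures for the
# data-model tests; seeded simulated datasets (cached per session) for the
# model-fitting tests.

# A minimal valid plot table with n plots.
tiny_plots <- function(n = 3) {
  data.frame(
    plot_id = sprintf("P%02d", seq_len(n)),
    N = 100 + seq_len(n),
    HB = 400 + 10 * seq_len(n),
    PD = 10 + seq_len(n),
    TRHD = 90 + seq_len(n),
    DM = rep_len(c(3L, 4L, 5L), n),
    PX = rep_len(1:8, n),
    PW = rep_len(1:6, n),
    TRMC = rep_len(c(12L, 13L), n),
    DD18 = 1500 + 5 * seq_len(n),
    MAP = 1700 + 5 * seq_len(n),
    Eref = 900 + 2 * seq_len(n),
    MAT = 19 + 0.1 * seq_len(n),
    MCMT = 9 + 0.1 * seq_len(n)
  )
}

# A minimal valid dataset: `reps` surveys for one tree per plot.
tiny_dataset <- function(n_plots = 3, reps = 2, response_kind = "DBH") {
  plots <- tiny_plots(n_plots)
  obs <- expand.grid(plot_id = plots$plot_id, s = seq_len(reps),
                     stringsAsFactors = FALSE)
  obs <- data.frame(
    plot_id = obs$plot_id,
    tree_id = paste0(obs$plot_id, "-T001"),
    survey_year = 2000L + 5L * (obs$s - 1L),
    T = 10 + 5 * (obs$s - 1),
    response = 8 + 2 * (obs$s - 1) + seq_len(nrow(obs)) * 0.1
  )
  growth_dataset(obs, plots, response_kind)
}

# Session-level cache so expensive simulations are shared across test files.
.itgrow_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.itgrow_test_cache[[key]]))
    .itgrow_test_cache[[key]] <- force(expr)
  .itgrow_test_cache[[key]]
}

# Small simulated DBH dataset for fitting tests (360 observations).
small_sim <- function() {
  cached("small_sim", suppressWarnings(simulate_inventory(
    generator_config("DBH", n_plots = 60, trees_per_plot = 2, n_surveys = 3),
    seed = 7)))
}

# Full-default simulated DBH dataset (shared by selection/ladder tests).
default_sim <- function(seed = 42) {
  cached(paste0("default_sim_", seed), suppressWarnings(
    simulate_inventory(generator_config("DBH"), seed = seed)))
}

# The pinned single-stand covariate row used by the hand-checked oracles.
oracle_covariates <- function() {
  c(N = 121, PW = 3, HB = 423, TRHD = 98, DM = 4, DD18 = 1500, Eref = 900)
}
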