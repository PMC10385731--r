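# Synthetic continuous-forest-inventory generator. The covariate-
# parameterized Mitscherlich model is the generative law, so every
# downstream stage (filtering, screening, fitting, the model ladder) can be
# validated against a known ground truth.

# Default covariate ranges, per response kind (survey summary ranges for
# the respective data set; climate ranges chosen for subtropical Fujian so
# the default coefficients give realistic asymptotes).
default_ranges <- function(response_kind) {
  clim <- list(
    DD18 = c(500, 2500), MAP = c(1400, 2000), Eref = c(650, 1150),
    MAT = c(17, 21), MCMT = c(5, 13),
    MWMT = c(24, 29), TD = c(12, 20), MSP = c(700, 1200),
    AHM = c(18, 32), SHM = c(40, 90), DD5 = c(5000, 7500),
    NFFD = c(280, 365), FFP = c(240, 360), PAS = c(0, 10),
    EMT = c(-8, 2), EXT = c(33, 41), CMD = c(0, 150))
  if (response_kind == "DBH") {
    c(list(N = c(40, 238), HB = c(100, 885), PD = c(2, 35),
           TRHD = c(73, 120)), clim)
  } else {
    c(list(N = c(25, 282), HB = c(101, 1041), PD = c(5, 37),
           TRHD = c(60, 130)), clim)
  }
}

# Correlation structure of the five inter-dependent climate variables
# (annual mean temperature strongly tied to coldest-month temperature and
# to reference evaporation, moderately to heat sum and precipitation); the
# remaining climate variables are independent.
default_climate_correlation <- function(clim_names) {
  core <- c("DD18", "MAP", "Eref", "MAT", "MCMT")
  C5 <- matrix(c(
    1.00, 0.30, 0.45, 0.35, 0.78,
    0.30, 1.00, 0.50, 0.35, 0.30,
    0.45, 0.50, 1.00, 0.78, 0.30,
    0.35, 0.35, 0.78, 1.00, 0.45,
    0.78, 0.30, 0.30, 0.45, 1.00), 5, 5,
    dimnames = list(core, core))
  C <- diag(length(clim_names))
  dimnames(C) <- list(clim_names, clim_names)
  C[core, core] <- C5
  C
}

# Default generating truth: an importance-calibrated coefficient set.
#
# The published reference coefficients (see rp_reference_coefficients())
# come from a linear re-parameterization that explains ~62% of the test
# variance; taken literally they give the slope-position factor an effect
# of ~0.15 cm and the slope aspect and annual precipitation no effect at
# all, which contradicts the contribution structure the source analysis
# reports (competition ~8% of the model, PW ~4%, HB/TRHD ~3%, PX/DM ~1%,
# DD18 the leading climate factor, MAP and Eref behind it). The generator's
# default truth therefore uses asymptote effects recomputed from those
# contribution rates (the HB effect keeps the reference value, which already
# matches its reported share), keeps the reference rate (beta) coefficients,
# and sets the intercept so the mean asymptote stays at the realistic survey
# level (~16.6 cm DBH asymptote / ~10.7 m H asymptote). The unmodified
# reference sets remain available for parameter-recovery studies via
# `coefficients = rp_reference_coefficients(kind)`.
default_generating_coefficients <- function(response_kind) {
  ref <- rp_reference_coefficients(response_kind)
  vars <- c(ref$variables, "PX", "MAP")
  if (response_kind == "DBH") {
    alpha <- c(-37.38, N = -0.035, PW = 1.0, HB = -0.0075, TRHD = 0.125,
               DM = -2.1, DD18 = 0.005, Eref = 0.02, PX = 0.75,
               MAP = 0.017)
  } else {
    alpha <- c(-10.54, N = -0.014, PW = 0.4, HB = -0.003, TRHD = 0.05,
               DM = -0.84, DD18 = 0.002, Eref = 0.008, PX = 0.3,
               MAP = 0.0068)
  }
  rp_coefficients(vars, alpha = unname(alpha),
                  beta = c(ref$beta, PX = 0, MAP = 0),
                  response_kind = response_kind)
}

#' Synthetic inventory generator configuration
#'
#' Bundles everything the generator needs: plot and survey design, covariate
#' ranges, the climate correlation matrix, the generating coefficient set,
#' the age structure and the response noise. DBH defaults: 300 plots of
#' ~667 m² measured 4 times at 5-year intervals with 3 sampled trees per
#' plot (3600 observations; the plot count is much higher than a typical
#' regional survey's because the plot-level covariates need enough degrees
#' of freedom for covariate screening to be identifiable — with a few dozen
#' plots no ranking of ~24 plot-level covariates is recoverable).
#' H defaults: 36 plots × 3 height-sample trees × 3 surveys.
#'
#' @param response_kind `"DBH"` (cm) or `"H"` (m).
#' @param n_plots number of sample plots.
#' @param trees_per_plot trees measured per plot.
#' @param n_surveys repeated surveys per tree.
#' @param survey_interval years between surveys.
#' @param age_range range of tree ages over the whole record; first-survey
#'   ages are drawn so that all survey ages stay inside it.
#' @param age_structure `"even"` (plot-level common age plus per-tree
#'   jitter) or `"mixed"` (independent tree ages).
#' @param age_jitter per-tree age jitter (years) under `"even"`.
#' @param ranges named list of `c(min, max)` covariate ranges; defaults are
#'   the survey summary ranges plus subtropical climate ranges.
#' @param climate_correlation correlation matrix over the climate variables
#'   (symmetric, unit diagonal, positive semi-definite).
#' @param coefficients generating `rp_coefficients`; the default is an
#'   importance-calibrated set whose asymptote effects reproduce the
#'   reported covariate contribution structure (pass
#'   [rp_reference_coefficients()] instead for parameter-recovery studies
#'   against the published estimates).
#' @param noise_sd SD of the additive Gaussian response noise (2 cm for
#'   DBH, 1 m for H by default).
#' @param response_floor small positive lower truncation for responses.
#' @param seed default seed used when none is passed to the generator.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(response_kind = c("DBH", "H"),
                             n_plots = NULL,
                             trees_per_plot = NULL,
                             n_surveys = NULL,
                             survey_interval = 5,
                             age_range = NULL,
                             age_structure = c("even", "mixed"),
                             age_jitter = 2,
                             ranges = NULL,
                             climate_correlation = NULL,
                             coefficients = NULL,
                             noise_sd = NULL,
                             response_floor = 0.1,
                             seed = 1) {
  response_kind <- match.arg(response_kind)
  age_structure <- match.arg(age_structure)
  dbh <- response_kind == "DBH"
  n_plots <- n_plots %||% if (dbh) 600L else 36L
  trees_per_plot <- trees_per_plot %||% 3L
  n_surveys <- n_surveys %||% if (dbh) 4L else 3L
  age_range <- age_range %||% if (dbh) c(4, 41) else c(4, 51)
  noise_sd <- noise_sd %||% if (dbh) 2 else 1
  defaults <- default_ranges(response_kind)
  if (!is.null(ranges)) defaults[names(ranges)] <- ranges
  ranges <- defaults
  for (nm in names(ranges))
    if (ranges[[nm]][1] > ranges[[nm]][2])
      stop_itgrow(paste0("range for ", nm, " has min > max"),
                  "itgrow_validation_error")
  clim_names <- setdiff(names(ranges), c("N", "HB", "PD", "TRHD"))
  climate_correlation <- climate_correlation %||%
    default_climate_correlation(clim_names)
  if (!isTRUE(all.equal(climate_correlation, t(climate_correlation))) ||
      any(abs(diag(climate_correlation) - 1) > 1e-8))
    stop_itgrow("climate correlation must be symmetric with unit diagonal",
                "itgrow_validation_error")
  if (min(eigen(climate_correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop_itgrow("climate correlation matrix is not positive semi-definite",
                "itgrow_validation_error")
  coefficients <- coefficients %||%
    default_generating_coefficients(response_kind)
  if (noise_sd < 0)
    stop_itgrow("noise_sd must be >= 0", "itgrow_validation_error")
  structure(list(response_kind = response_kind, n_plots = n_plots,
                 trees_per_plot = trees_per_plot, n_surveys = n_surveys,
                 survey_interval = survey_interval, age_range = age_range,
                 age_structure = age_structure, age_jitter = age_jitter,
                 ranges = ranges, climate_names = clim_names,
                 climate_correlation = climate_correlation,
                 coefficients = coefficients, noise_sd = noise_sd,
                 response_floor = response_floor, seed = seed),
            class = "generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [generator_config()]; `ranges`
#' may be given as a mapping of `[min, max]` pairs and `coefficients` as the
#' JSON layout of [write_rp_coefficients()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `generator_config`.
#' @export
generator_config_from_file <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$ranges))
    cfg$ranges <- lapply(cfg$ranges, as.numeric)
  if (!is.null(cfg$coefficients))
    cfg$coefficients <- rp_coefficients(
      cfg$coefficients$variables,
      as.numeric(cfg$coefficients$alpha),
      as.numeric(cfg$coefficients$beta),
      cfg$coefficients$response_kind %||% cfg$response_kind %||% "DBH")
  do.call(generator_config, cfg)
}

# One batch of plot covariate rows (no plot ids yet).
sample_plot_covariates <- function(cfg, n, chol_C) {
  runif_range <- function(nm) stats::runif(n, cfg$ranges[[nm]][1],
                                           cfg$ranges[[nm]][2])
  out <- data.frame(
    N = pmax(1L, as.integer(round(runif_range("N")))),
    HB = runif_range("HB"), PD = runif_range("PD"),
    TRHD = runif_range("TRHD"),
    DM = sample(SITE_CODE_SETS$DM, n, replace = TRUE),
    PX = sample(SITE_CODE_SETS$PX, n, replace = TRUE),
    PW = sample(SITE_CODE_SETS$PW, n, replace = TRUE),
    TRMC = sample(SITE_CODE_SETS$TRMC, n, replace = TRUE))
  # correlated multivariate normal, clipped to range
  Z <- matrix(stats::rnorm(n * length(cfg$climate_names)), n) %*% chol_C
  for (j in seq_along(cfg$climate_names)) {
    nm <- cfg$climate_names[j]
    lo <- cfg$ranges[[nm]][1]
    hi <- cfg$ranges[[nm]][2]
    x <- (lo + hi) / 2 + Z[, j] * (hi - lo) / 6
    out[[nm]] <- pmin(pmax(x, lo), hi)
  }
  out
}

#' Generate synthetic sample plots
#'
#' Continuous covariates are uniform within their configured ranges, coded
#' site factors uniform over their code sets (all site factors mutually
#' independent), and the climate vector is drawn from a correlated
#' multivariate normal (mid-range mean, SD = range/6) clipped to range.
#'
#' @param cfg a `generator_config`.
#' @param n_plots number of plots (defaults to the config value).
#' @param seed integer seed.
#' @return data.frame of plot records (`plot_id`, `N`, site, climate).
#' @export
generate_plots <- function(cfg, n_plots = cfg$n_plots, seed = cfg$seed) {
  chol_C <- chol(cfg$climate_correlation)
  plots <- with_seed(seed, sample_plot_covariates(cfg, n_plots, chol_C))
  plots <- cbind(plot_id = sprintf("P%04d", seq_len(n_plots)), plots)
  plots
}

#' Generate tree observations from plots
#'
#' For every tree and survey age `T` the response is the model prediction
#' under the generating coefficients plus Gaussian noise, truncated below at
#' a small positive floor; ages increase by the survey interval across a
#' tree's repeated surveys. Plots whose covariates give a non-positive
#' asymptote or rate are redrawn (with a warning stating the count) so the
#' generative law stays well defined.
#'
#' @param plots plot data.frame from [generate_plots()].
#' @param cfg a `generator_config`.
#' @param seed integer seed.
#' @return a `growth_dataset` (its plot table may contain redrawn rows).
#' @export
generate_observations <- function(plots, cfg, seed = cfg$seed) {
  if (!nrow(plots))
    stop_itgrow("plots must be nonempty", "itgrow_validation_error")
  chol_C <- chol(cfg$climate_correlation)
  with_seed(child_seed(seed, 1), {
    # redraw covariates of plots with invalid generating parameters
    n_resampled <- 0L
    for (attempt in 1:200) {
      w <- omega_pair(cfg$coefficients, plots)
      bad <- which(!w$valid)
      if (!length(bad)) break
      if (attempt == 200)
        stop_itgrow("could not draw valid plot covariates; check coefficient/range compatibility",
                    "itgrow_fit_error")
      n_resampled <- n_resampled + length(bad)
      repl <- sample_plot_covariates(cfg, length(bad), chol_C)
      plots[bad, names(repl)] <- repl
    }
    if (n_resampled > 0)
      warning(sprintf("redrew covariates for %d plot draw(s) with non-positive growth parameters",
                      n_resampled), call. = FALSE)

    n_sv <- cfg$n_surveys
    step <- cfg$survey_interval
    first_max <- max(cfg$age_range[1], cfg$age_range[2] - (n_sv - 1) * step)
    obs <- vector("list", nrow(plots))
    for (i in seq_len(nrow(plots))) {
      k <- cfg$trees_per_plot
      if (cfg$age_structure == "even") {
        base_age <- sample(seq(cfg$age_range[1], first_max), 1)
        jit <- sample(seq(-cfg$age_jitter, cfg$age_jitter), k, replace = TRUE)
        first_age <- pmin(pmax(base_age + jit, cfg$age_range[1]), first_max)
      } else {
        first_age <- sample(seq(cfg$age_range[1], first_max), k,
                            replace = TRUE)
      }
      T <- rep(first_age, each = n_sv) + step * (seq_len(n_sv) - 1)
      obs[[i]] <- data.frame(
        plot_id = plots$plot_id[i],
        tree_id = sprintf("%s-T%03d", plots$plot_id[i],
                          rep(seq_len(k), each = n_sv)),
        survey_year = 2000L + step * (seq_len(n_sv) - 1L),
        T = T)
    }
    obs <- do.call(rbind, obs)
    mu <- rp_predict(cfg$coefficients,
                     plots[match(obs$plot_id, plots$plot_id), , drop = FALSE],
                     obs$T)
    noise <- if (cfg$noise_sd > 0)
      stats::rnorm(nrow(obs), 0, cfg$noise_sd) else 0
    obs$response <- pmax(as.numeric(mu) + noise, cfg$response_floor)
    growth_dataset(obs, plots, cfg$response_kind)
  })
}

#' Simulate a complete synthetic inventory
#'
#' Convenience wrapper: [generate_plots()] then [generate_observations()].
#'
#' @param cfg a `generator_config`.
#' @param seed integer seed.
#' @return a `growth_dataset`.
#' @export
simulate_inventory <- function(cfg = generator_config(), seed = cfg$seed) {
  plots <- generate_plots(cfg, seed = seed)
  generate_observations(plots, cfg, seed = seed)
}

#' Inject artificial outliers
#'
#' Shifts a random subset of observations by `+/- magnitude` plot-level
#' response SDs — a harness for validating the grouped 3-sigma filter.
#'
#' @param ds a `growth_dataset`.
#' @param rate proportion of observations to corrupt, in `[0, 1)`.
#' @param magnitude shift size in plot SD multiples; must exceed 3 so the
#'   injected points are genuine 3-sigma outliers.
#' @param seed integer seed.
#' @return list with `dataset` (corrupted copy) and `injected` (data.frame
#'   of the corrupted observation keys).
#' @export
inject_outliers <- function(ds, rate, magnitude = 6, seed = 1) {
  if (rate < 0 || rate >= 1)
    stop_itgrow("rate must be in [0, 1)", "itgrow_validation_error")
  if (magnitude <= 3)
    stop_itgrow("magnitude must exceed 3", "itgrow_validation_error")
  obs <- ds$observations
  n_out <- round(rate * nrow(obs))
  if (n_out == 0)
    return(list(dataset = ds, injected = obs[0, c("plot_id", "tree_id",
                                                  "survey_year")]))
  with_seed(seed, {
    idx <- sample.int(nrow(obs), n_out)
    sd_all <- stats::sd(obs$response)
    plot_sd <- tapply(obs$response, obs$plot_id, stats::sd)
    s <- plot_sd[obs$plot_id[idx]]
    s[!is.finite(s) | s == 0] <- sd_all
    shift <- sample(c(-1, 1), n_out, replace = TRUE) * magnitude * s
    # a downward shift that would push the response to the positivity floor
    # no longer has the requested magnitude, so point it upward instead
    clipped <- obs$response[idx] + shift < 0.01
    shift[clipped] <- abs(shift[clipped])
    obs$response[idx] <- obs$response[idx] + shift
  })
  out <- growth_dataset(obs, ds$plots, ds$response_kind, validate = FALSE)
  list(dataset = out,
       injected = obs[idx, c("plot_id", "tree_id", "survey_year")])
}
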