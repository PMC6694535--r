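# Policy experiments: the base-case and the four published intervention
# scenarios, scenario comparison, and Monte-Carlo parameter sensitivity.

#' Define a policy scenario
#'
#' A scenario is the base configuration plus timed parameter overrides: each
#' override takes effect in its stated year as a step change and is held
#' constant thereafter.
#'
#' @param name scenario label.
#' @param overrides `NULL` (base-case) or a data.frame with columns `path`
#'   (config path), `value` (numeric), `year` (effective year).
#' @param horizon simulation years `c(start, end)`.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = NULL, horizon = c(2010, 2040)) {
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides),
              all(c("path", "value", "year") %in% names(overrides)))
    if (any(overrides$year < horizon[1] | overrides$year > horizon[2])) {
      stop("override effective year outside the horizon", call. = FALSE)
    }
  }
  structure(list(name = name, overrides = overrides,
                 horizon = as.integer(horizon)), class = "scenario_spec")
}

#' Packaged policy scenarios
#'
#' The reference experiments: `base` (no change); `diabetes` (management
#' uptake 5% -> 15% in 2020); `hypertension` (uptake 3.5% -> 13.5% in 2020);
#' `smoking` (cessation 16.2% -> 25% in 2020); `combined` (all three
#' concurrently).
#'
#' @param which one of `"base"`, `"diabetes"`, `"hypertension"`, `"smoking"`,
#'   `"combined"`.
#' @param year effective year of the step change (default 2020).
#' @param horizon simulation years.
#' @return a `scenario_spec`.
#' @export
preset_scenario <- function(which = c("base", "diabetes", "hypertension",
                                      "smoking", "combined"),
                            year = 2020, horizon = c(2010, 2040)) {
  which <- match.arg(which)
  ov <- list(
    diabetes = data.frame(path = "diabetes.uptake_rate", value = 0.15, year = year),
    hypertension = data.frame(path = "hypertension.uptake_rate", value = 0.135, year = year),
    smoking = data.frame(path = "smoking.cessation_rate", value = 0.25, year = year)
  )
  overrides <- switch(which,
    base = NULL,
    combined = do.call(rbind, ov),
    ov[[which]]
  )
  scenario_spec(which, overrides, horizon)
}

#' Run a policy scenario
#'
#' @param spec a `scenario_spec`.
#' @param inputs a `demography_inputs`.
#' @param state the initial `model_state`.
#' @param config a `cvdsim_config` (calibrated or explicitly supplied).
#' @return a `cvdsim_result` (deterministic).
#' @export
run_scenario <- function(spec, inputs, state, config) {
  config$horizon$start <- spec$horizon[1]
  config$horizon$end <- spec$horizon[2]
  run_model(inputs, state, config, overrides = spec$overrides,
            scenario = spec$name)
}

#' Compare a scenario with the base-case
#'
#' Percent reduction relative to base at a stated year,
#' `100 * (base - scenario) / base`, per outcome. Zero base outcomes yield
#' `NA` with a warning.
#'
#' @param result,base `cvdsim_result`s with matching horizons.
#' @param year comparison year (default: last common year).
#' @param outcomes outcome columns to compare.
#' @return named numeric vector of percent reductions.
#' @export
compare_scenarios <- function(result, base, year = NULL,
                              outcomes = c("events", "cvd_deaths", "post_cvd",
                                           "age_adjusted_incidence")) {
  if (!identical(base$year, result$year)) {
    stop("results have different horizons", call. = FALSE)
  }
  if (is.null(year)) year <- max(base$year)
  i <- match(year, base$year)
  if (is.na(i)) stop("year not in the simulated horizon", call. = FALSE)
  out <- stats::setNames(numeric(length(outcomes)), outcomes)
  for (oc in outcomes) {
    b <- base[[oc]][i]; s <- result[[oc]][i]
    if (is.na(b) || b == 0) {
      warning("base outcome ", oc, " is zero at ", year, "; reduction undefined", call. = FALSE)
      out[oc] <- NA_real_
    } else {
      out[oc] <- 100 * (b - s) / b
    }
  }
  out
}

#' Percent change of an outcome within a scenario
#'
#' `100 * (value(to) - value(from)) / value(from)`, the "% change" column of
#' the outcome table.
#'
#' @param result a `cvdsim_result`.
#' @param outcome outcome column name.
#' @param from,to years (defaults: first and last simulated year).
#' @return percent change.
#' @export
pct_change <- function(result, outcome, from = NULL, to = NULL) {
  if (is.null(from)) from <- min(result$year)
  if (is.null(to)) to <- max(result$year)
  v0 <- result[[outcome]][match(from, result$year)]
  v1 <- result[[outcome]][match(to, result$year)]
  if (is.na(v0) || v0 == 0) {
    warning("baseline value is zero; percent change undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * (v1 - v0) / v0
}

#' Define a sensitivity experiment
#'
#' @param varied_params config paths of the parameters to vary (defaults: the
#'   three calibrated incidence/initiation rates).
#' @param range multiplicative half-width; each draw multiplies the baseline
#'   by `runif(1 - range, 1 + range)` (default 0.5, i.e. +/-50%).
#' @param n_runs number of Monte-Carlo runs (default 500).
#' @param ci_level credible-interval level (default 0.95, reported as the
#'   empirical 2.5th/97.5th percentiles).
#' @param seed RNG seed.
#' @param mode `"joint"` (default): all parameters drawn independently each
#'   run; `"one_at_a_time"`: each run perturbs a single parameter in turn;
#'   `"pairwise"`: each run perturbs one parameter pair.
#' @return an object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(varied_params = c("diabetes.incidence_rate",
                                               "hypertension.incidence_rate",
                                               "smoking.initiation_rate"),
                             range = 0.5, n_runs = 500, ci_level = 0.95,
                             seed = 1L,
                             mode = c("joint", "one_at_a_time", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1, range >= 0, ci_level > 0, ci_level < 1)
  if (n_runs < 40) {
    warning("fewer than 40 runs: ", 100 * ci_level,
            "% percentile interval will be unstable", call. = FALSE)
  }
  structure(list(varied_params = varied_params, range = range,
                 n_runs = as.integer(n_runs), ci_level = ci_level,
                 seed = as.integer(seed), mode = mode),
            class = "sensitivity_spec")
}

#' Monte-Carlo parameter sensitivity of a scenario
#'
#' Draws each varied parameter independently and uniformly from
#' `[(1 - range), (1 + range)]` times its baseline, runs the scenario
#' `n_runs` times, and reports the per-year mean and empirical percentile
#' interval of each outcome. Fully reproducible from `spec$seed`.
#'
#' @param spec a `sensitivity_spec`.
#' @param scenario a `scenario_spec`.
#' @param inputs,state,config the simulation world.
#' @param outcomes outcome columns to summarize.
#' @return a data.frame `(year, outcome, mean, lower, upper)` with attributes
#'   `draws` (the run x parameter draw matrix) and `spec`.
#' @export
run_sensitivity <- function(spec, scenario, inputs, state, config,
                            outcomes = c("events", "cvd_deaths", "post_cvd",
                                         "age_adjusted_incidence")) {
  base_vals <- vapply(spec$varied_params, function(p) config_get(config, p),
                      numeric(1))
  k <- length(spec$varied_params)
  set.seed(spec$seed)
  mult <- matrix(stats::runif(spec$n_runs * k, 1 - spec$range, 1 + spec$range),
                 nrow = spec$n_runs,
                 dimnames = list(NULL, spec$varied_params))
  if (spec$mode == "one_at_a_time") {
    keep <- matrix(0, spec$n_runs, k)
    keep[cbind(seq_len(spec$n_runs), (seq_len(spec$n_runs) - 1L) %% k + 1L)] <- 1
    mult <- 1 + (mult - 1) * keep
  } else if (spec$mode == "pairwise") {
    pairs <- utils::combn(k, 2)
    keep <- matrix(0, spec$n_runs, k)
    for (i in seq_len(spec$n_runs)) {
      keep[i, pairs[, (i - 1L) %% ncol(pairs) + 1L]] <- 1
    }
    mult <- 1 + (mult - 1) * keep
  }
  years <- scenario$horizon[1]:scenario$horizon[2]
  arr <- array(NA_real_, dim = c(spec$n_runs, length(years), length(outcomes)),
               dimnames = list(NULL, years, outcomes))
  for (r in seq_len(spec$n_runs)) {
    cfg <- config
    for (j in seq_len(k)) {
      cfg <- config_set(cfg, spec$varied_params[j], base_vals[j] * mult[r, j])
    }
    sim <- run_scenario(scenario, inputs, state, cfg)
    for (oc in outcomes) arr[r, , oc] <- sim[[oc]]
  }
  a <- (1 - spec$ci_level) / 2
  rows <- expand.grid(year = years, outcome = outcomes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$mean <- NA_real_; rows$lower <- NA_real_; rows$upper <- NA_real_
  for (i in seq_len(nrow(rows))) {
    v <- arr[, as.character(rows$year[i]), rows$outcome[i]]
    rows$mean[i] <- mean(v)
    q <- stats::quantile(v, c(a, 1 - a), names = FALSE, type = 7)
    rows$lower[i] <- q[1]; rows$upper[i] <- q[2]
  }
  structure(rows, draws = mult, spec = spec, scenario = scenario$name)
}
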