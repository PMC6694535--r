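# Synthetic stand-ins for the national statistical and disease-registry
# inputs: a parametric age pyramid, Gompertz life tables, constant fertility,
# and prevalence/event series produced by running the model under known
# ground-truth parameters.

#' Specification of a synthetic input world
#'
#' The defaults describe a Singapore-like adult population of about 3.19
#' million (chosen so that the packaged 2010 smoker count equals a 13 percent
#' prevalence), with Gompertz adult mortality, replacement-level-or-below
#' constant fertility, and zero net migration.
#'
#' @param population_scale multiplier on all person counts (default 1).
#' @param total_population adults 18+ at scale 1.
#' @param pyramid_center,pyramid_spread,pyramid_floor parameters of the age
#'   profile `w(a) = floor + (1 - floor) * exp(-((a - center)/spread)^2 / 2)`.
#' @param gompertz_a,gompertz_b named female/male Gompertz parameters of
#'   `m(age) = a * exp(b * age)` (error if any value exceeds 1).
#' @param fertility births per fecund woman per year, constant.
#' @param migration net migrants per year, a constant grid value (default 0).
#' @param horizon simulation years, `c(start, end)`.
#' @param true_params ground-truth `cvdsim_config` used when generating
#'   observation series.
#' @param noise_sd multiplicative lognormal observation noise (sdlog).
#' @param seed RNG seed for the observation noise.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(population_scale = 1,
                           total_population = 3190685,
                           pyramid_center = 42, pyramid_spread = 18,
                           pyramid_floor = 0.35,
                           gompertz_a = c(female = 5e-05, male = 8e-05),
                           gompertz_b = c(female = 0.085, male = 0.085),
                           fertility = 0.033,
                           migration = 0,
                           horizon = c(2010, 2040),
                           true_params = default_config(),
                           noise_sd = 0,
                           seed = 1L) {
  stopifnot(population_scale > 0, total_population > 0, noise_sd >= 0)
  structure(list(
    population_scale = population_scale, total_population = total_population,
    pyramid_center = pyramid_center, pyramid_spread = pyramid_spread,
    pyramid_floor = pyramid_floor,
    gompertz_a = gompertz_a[CVDSIM_SEXES], gompertz_b = gompertz_b[CVDSIM_SEXES],
    fertility = fertility, migration = migration,
    horizon = as.integer(horizon), true_params = true_params,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Gompertz adult mortality
#'
#' `m(age) = a * exp(b * age)`, errors when the uncapped value exceeds 1.
#'
#' @param age ages in years.
#' @param a,b Gompertz level and slope.
#' @return annual death fractions.
#' @export
gompertz_mortality <- function(age, a, b) {
  m <- a * exp(b * age)
  if (any(m > 1)) stop("Gompertz mortality exceeds 1 in the modelled age range", call. = FALSE)
  m
}

#' Generate synthetic demographic inputs
#'
#' @param spec a `synthetic_spec`.
#' @return a [demography_inputs()]: parametric age pyramid, constant-in-time
#'   Gompertz mortality, constant fertility, constant migration, replacement
#'   age-18 entry. Deterministic given the spec.
#' @export
make_demography <- function(spec) {
  years <- spec$horizon[1]:spec$horizon[2]
  w <- spec$pyramid_floor +
    (1 - spec$pyramid_floor) * exp(-((CVDSIM_AGES - spec$pyramid_center) / spec$pyramid_spread)^2 / 2)
  pop_sex <- spec$total_population * spec$population_scale / 2
  pyramid <- cbind(female = w / sum(w) * pop_sex, male = w / sum(w) * pop_sex)
  mort <- cbind(
    female = gompertz_mortality(CVDSIM_AGES, spec$gompertz_a[["female"]], spec$gompertz_b[["female"]]),
    male = gompertz_mortality(CVDSIM_AGES, spec$gompertz_a[["male"]], spec$gompertz_b[["male"]])
  )
  demography_inputs(
    initial_population = as_cohort_grid(pyramid),
    years = years,
    fertility_rate = spec$fertility,
    mortality_rate = mort,
    net_migration = spec$migration * spec$population_scale
  )
}

# Initial prevalence profile: logistic in age, scaled so the
# population-weighted aggregate count hits `target`; errors if any cell would
# exceed `cap`.
logistic_prevalence <- function(pop, target, midpoint, steepness, cap = 0.95) {
  shape <- stats::plogis(steepness * (CVDSIM_AGES - midpoint))
  shape <- matrix(rep(shape, 2L), ncol = 2L)
  c0 <- target / sum(unclass(pop) * shape)
  prev <- c0 * shape
  if (any(prev > cap)) stop("initial prevalence shape exceeds cap; flatten the shape", call. = FALSE)
  prev
}

#' Build the packaged population fixture
#'
#' A synthetic population whose 2010 aggregates match the model's published
#' initialization anchors (at scale 1): 369,133 diabetics, 659,958
#' hypertensives, 414,789 current smokers, 112,606 CVD survivors, and 33,292
#' CVD events distributed over risk groups by the packaged expert table.
#' Managed shares start at 44 percent (diabetes) and 43 percent
#' (hypertension). All counts scale linearly with `scale`. Per-group
#' intercepts are re-calibrated to this population unless `calibrate = FALSE`.
#'
#' @param scale population scale multiplier (default 1).
#' @param config base configuration (default packaged).
#' @param calibrate re-calibrate `cvd.beta0` to the fixture population and the
#'   packaged event distribution (default `TRUE`).
#' @param horizon simulation years `c(start, end)`.
#' @return a list with elements `inputs` (`demography_inputs`), `state`
#'   (`model_state`), `config` (`cvdsim_config`, with calibrated intercepts)
#'   and `targets` (`calibration_targets` holding the 2010 anchors).
#' @export
make_singapore_like_fixture <- function(scale = 1, config = default_config(),
                                        calibrate = TRUE,
                                        horizon = c(2010, 2040)) {
  anchors <- c(diabetes = 369133, hypertension = 659958, smoking = 414789,
               post_cvd = 112606, events = 33292)
  spec <- synthetic_spec(population_scale = scale, horizon = horizon,
                         true_params = config)
  inputs <- make_demography(spec)
  pop <- inputs$initial_population
  tgt <- anchors * scale

  # established-condition profiles rise with age; pre-condition and smoking
  # profiles are age-flat (keeps per-cell state sums below 1)
  prev_dia <- logistic_prevalence(pop, tgt[["diabetes"]], 50, 0.07)
  prev_hyp <- logistic_prevalence(pop, tgt[["hypertension"]], 52, 0.08)
  flat <- function(target) target / grid_total(pop)
  prev_pre_dia <- flat(0.14 * grid_total(pop))
  prev_pre_hyp <- flat(0.30 * grid_total(pop))
  prev_smo <- flat(tgt[["smoking"]])
  prev_former <- flat(0.10 * grid_total(pop))
  prev_pc <- logistic_prevalence(pop, tgt[["post_cvd"]], 70, 0.09)

  p <- unclass(pop)
  mk_two_stage <- function(prev_dis, prev_pre, managed0) {
    two_stage_stocks(
      healthy = p * (1 - prev_dis - prev_pre),
      pre_unmanaged = p * prev_pre * (1 - managed0),
      pre_managed = p * prev_pre * managed0,
      disease_unmanaged = p * prev_dis * (1 - managed0),
      disease_managed = p * prev_dis * managed0
    )
  }
  state <- model_state(
    population = pop,
    diabetes = mk_two_stage(prev_dia, prev_pre_dia, 0.44),
    hypertension = mk_two_stage(prev_hyp, prev_pre_hyp, 0.43),
    smoking = smoking_stocks(
      never = p * (1 - prev_smo - prev_former),
      current = p * prev_smo,
      former = p * prev_former
    ),
    post_cvd = p * prev_pc
  )

  dist <- default_event_distribution()
  targets <- calibration_targets(
    prevalence = matrix(
      c(tgt[["diabetes"]], tgt[["hypertension"]], tgt[["smoking"]]) / grid_total(pop),
      nrow = 1, dimnames = list("2010", c("diabetes", "hypertension", "smoking"))
    ),
    total_events = c("2010" = unname(tgt[["events"]])),
    event_distribution = dist
  )

  if (calibrate) {
    prev <- factor_prevalence(state, config)
    shares <- partition_risk_groups(prev$d, prev$h, prev$s,
                                    mode = config$modes$partition_mode)
    at_risk <- pmax(p - unclass(state$post_cvd), 0)
    pop_by_group <- sweep_groups(shares, at_risk)
    beta0 <- calibrate_beta0(targets, pop_by_group, default_engine_params(config))
    config <- config_set(config, "cvd.beta0", beta0)
  }
  config$horizon$start <- as.integer(horizon[1])
  config$horizon$end <- as.integer(horizon[2])

  list(inputs = inputs, state = state, config = validate_config(config),
       targets = targets)
}

#' Generate observation series with known ground truth
#'
#' Runs the full model under `spec$true_params` on the synthetic demography,
#' extracts the aggregate prevalence series (diabetes, hypertension, current
#' smoking) and the annual total-event series, applies multiplicative
#' lognormal noise of sdlog `spec$noise_sd` (seeded), and attaches an event
#' distribution computed from the simulated group-level events.
#'
#' @param spec a `synthetic_spec`.
#' @param fixture optionally a pre-built fixture (from
#'   [make_singapore_like_fixture()]) so the generating world is shared with
#'   the caller; by default one is built at `spec$population_scale` with
#'   `spec$true_params`.
#' @return a [calibration_targets()].
#' @export
make_observations <- function(spec, fixture = NULL) {
  if (is.null(fixture)) {
    fixture <- make_singapore_like_fixture(
      scale = spec$population_scale, config = spec$true_params,
      horizon = spec$horizon
    )
  }
  sim <- run_model(fixture$inputs, fixture$state, fixture$config,
                   scenario = "truth")
  prev <- cbind(diabetes = sim$prev_diabetes,
                hypertension = sim$prev_hypertension,
                smoking = sim$prev_smoking)
  rownames(prev) <- sim$year
  events <- stats::setNames(sim$events, sim$year)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    prev <- prev * exp(stats::rnorm(length(prev), 0, spec$noise_sd))
    events <- events * exp(stats::rnorm(length(events), 0, spec$noise_sd))
  }
  ebg <- colSums(attr(sim, "events_by_group"))
  dist <- event_distribution(ebg / sum(ebg))
  calibration_targets(prevalence = prev, total_events = events,
                      event_distribution = dist)
}
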