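# Orchestration of one simulated year and of full trajectories: demography,
# the three risk-factor sub-models and the CVD engine, with a single
# demographic ledger population guaranteeing conservation.

#' Full model state
#'
#' @param population the ledger `cohort_grid` (total persons 18+).
#' @param diabetes,hypertension `two_stage_stocks` partitioning the population.
#' @param smoking a `smoking_stocks` partitioning the population.
#' @param post_cvd a `cohort_grid` of CVD survivors (a subset of
#'   `population`, overlapping the risk-factor stocks).
#' @return an object of class `model_state`.
#' @export
model_state <- function(population, diabetes, hypertension, smoking, post_cvd) {
  structure(list(
    population = as_grid_arg(population),
    diabetes = diabetes,
    hypertension = hypertension,
    smoking = smoking,
    post_cvd = as_grid_arg(post_cvd)
  ), class = "model_state")
}

# Per-factor treated-risk multipliers under the configured mode.
risk_multipliers <- function(config) {
  cv <- config$cvd
  rr <- c(d = cv$rr_treated_diabetes, h = cv$rr_treated_hypertension,
          s = cv$rr_treated_smoking)
  if (isTRUE(config$modes$eq10_literal)) 1 - rr else rr
}

# Cell-wise coverage (treated share) of each factor. Coverage of smoking is
# the former-smoker share of ever-smokers in "ever" mode, 0 in "current" mode.
factor_coverage <- function(state, config) {
  cov_of <- function(num, den) {
    c <- num / den
    c[den <= 0] <- 0
    c
  }
  dia <- state$diabetes; hyp <- state$hypertension; smo <- state$smoking
  cov_d <- cov_of(unclass(dia$disease_managed),
                  unclass(dia$disease_managed) + unclass(dia$disease_unmanaged))
  cov_h <- cov_of(unclass(hyp$disease_managed),
                  unclass(hyp$disease_managed) + unclass(hyp$disease_unmanaged))
  if (config$modes$smoking_definition == "ever") {
    cov_s <- cov_of(unclass(smo$former), unclass(smo$current) + unclass(smo$former))
  } else {
    cov_s <- matrix(0, 83L, 2L)
  }
  list(d = cov_d, h = cov_h, s = cov_s)
}

# Marginal risk-factor prevalences (cell grids) feeding the partition.
factor_prevalence <- function(state, config) {
  prev_d <- prevalence(state$diabetes, "disease")$cell
  prev_h <- prevalence(state$hypertension, "disease")$cell
  smoke_state <- if (config$modes$smoking_definition == "ever") "ever" else "current"
  prev_s <- prevalence(state$smoking, smoke_state)$cell
  lapply(list(d = prev_d, h = prev_h, s = prev_s), function(p) {
    p[is.na(p)] <- 0
    pmin(pmax(p, 0), 1)
  })
}

#' Advance the full model one year
#'
#' Runs the CVD engine on the start-of-year state (events, event deaths,
#' post-CVD update), then deaths/transitions in the sub-models, then net
#' migration, then ageing with age-18 entry; finally the sub-model stocks are
#' rescaled to the ledger population (if `modes$renormalize`).
#'
#' @param state a `model_state` at the start of `year`.
#' @param inputs a `demography_inputs`.
#' @param config a `cvdsim_config`.
#' @param year simulation year.
#' @param standard_pop grid for age standardization (default: current at-risk
#'   population, making the year's rate crude).
#' @return a list with `state` (next year) and `outputs` (a one-row list of
#'   annual indicators and conservation flows).
#' @export
step_model <- function(state, inputs, config, year, standard_pop = NULL) {
  m <- year_slice(inputs$mortality_rate, inputs$years, year)
  if (isTRUE(config$modes$hazard)) m <- 1 - exp(-m)
  mig <- year_slice(inputs$net_migration, inputs$years, year)
  engine <- default_engine_params(config)

  pop <- unclass(state$population)
  pc <- pmin(unclass(state$post_cvd), pop)
  at_risk <- pop - pc

  ## --- CVD engine on the start-of-year population ---
  prev <- factor_prevalence(state, config)
  shares <- partition_risk_groups(prev$d, prev$h, prev$s,
                                  mode = config$modes$partition_mode)
  pop_by_group <- sweep_groups(shares, at_risk)
  p <- cvd_probability_grid(engine)
  cov <- factor_coverage(state, config)
  mult <- risk_multipliers(config)
  gmult <- group_risk_multiplier(cov$d, cov$h, cov$s, mult[["d"]], mult[["h"]], mult[["s"]])
  ap <- p * gmult
  events_by_group <- compute_events(pop_by_group, ap)
  events <- apply(events_by_group, c(2, 3), sum)
  dimnames(events) <- list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)

  cvd <- update_post_cvd(cvd_state(pc), events, engine, m)
  event_deaths_grid <- events * engine$event_death_rate

  std <- if (is.null(standard_pop)) at_risk else rate_grid(standard_pop)
  aai <- age_adjusted_incidence(events, at_risk, std)

  ## --- demographic ledger ---
  deaths_at_risk <- at_risk * m
  pc_deaths_total <- cvd$annual_post_cvd_deaths
  # post-CVD deaths grid, recovered from the stock identity
  # new_pc = pc - pc_deaths + survivors
  pc_deaths_grid <- pc - unclass(cvd$post_cvd) + events * (1 - engine$event_death_rate)
  pop2 <- pop - deaths_at_risk - pc_deaths_grid - event_deaths_grid + mig
  if (any(pop2 < -1e-9)) stop("population driven negative; check migration inputs", call. = FALSE)
  pop2[pop2 < 0] <- 0
  entrants <- entrants_for_year(inputs, year, as_cohort_grid(pop))
  pop_next <- age_shift(as_cohort_grid(pop2), entrants)
  pc_next <- age_shift(cvd$post_cvd, c(0, 0))

  ## --- risk-factor sub-models: deaths + transitions, migration, ageing ---
  on_neg <- config$modes$on_negative
  dia <- step_two_stage(state$diabetes, two_stage_params_from_config(config$diabetes),
                        m, on_negative = on_neg)
  hyp <- step_two_stage(state$hypertension, two_stage_params_from_config(config$hypertension),
                        m, on_negative = on_neg)
  smo <- step_smoking(state$smoking, smoking_params_from_config(config$smoking),
                      m, on_negative = on_neg)
  dia <- submodel_migrate_age(dia, mig, entrants, "healthy")
  hyp <- submodel_migrate_age(hyp, mig, entrants, "healthy")
  smo <- submodel_migrate_age(smo, mig, entrants, "never")
  if (isTRUE(config$modes$renormalize)) {
    dia <- renormalize_stocks(dia, pop_next, "healthy")
    hyp <- renormalize_stocks(hyp, pop_next, "healthy")
    smo <- renormalize_stocks(smo, pop_next, "never")
  }

  state_next <- model_state(pop_next, dia, hyp, smo, pc_next)

  outputs <- list(
    year = year,
    population = sum(pop),
    at_risk = sum(at_risk),
    events = cvd$annual_events,
    cvd_deaths = cvd$annual_event_deaths,
    post_cvd_deaths = cvd$annual_post_cvd_deaths,
    post_cvd = sum(pc),
    age_adjusted_incidence = aai,
    prev_diabetes = prevalence(state$diabetes, "disease")$aggregate,
    prev_hypertension = prevalence(state$hypertension, "disease")$aggregate,
    prev_smoking = prevalence(state$smoking, "current")$aggregate,
    managed_share_diabetes = managed_share(state$diabetes)$aggregate,
    managed_share_hypertension = managed_share(state$hypertension)$aggregate,
    former_smoker_share = {
      sm <- state$smoking
      ever <- grid_total(sm$current) + grid_total(sm$former)
      if (ever > 0) grid_total(sm$former) / ever else NA_real_
    },
    # conservation ledger flows
    flow_entrants = sum(entrants),
    flow_migration = sum(mig),
    flow_deaths = sum(deaths_at_risk) + pc_deaths_total + sum(event_deaths_grid),
    events_by_group = apply(events_by_group, 1, sum)
  )
  list(state = state_next, outputs = outputs)
}

sweep_groups <- function(shares, grid) {
  out <- shares
  for (g in 1:8) out[g, , ] <- shares[g, , ] * grid
  out
}

# Allocate net migration across a sub-model's stocks proportionally to their
# cell shares (empty cells: all to the entry stock), then age every stock,
# with 18-year-old entrants joining the entry stock.
submodel_migrate_age <- function(stocks, mig, entrants, entry_stock) {
  tot <- unclass(stocks_total(stocks))
  deaths <- attr(stocks, "deaths")
  nms <- names(stocks)
  out <- stocks
  for (nm in nms) {
    share <- unclass(stocks[[nm]]) / tot
    share[tot <= 0] <- if (nm == entry_stock) 1 else 0
    g <- unclass(stocks[[nm]]) + mig * share
    if (any(g < -1e-9)) {
      stop("net out-migration drove a sub-model stock negative", call. = FALSE)
    }
    g[g < 0] <- 0
    out[[nm]] <- age_shift(as_cohort_grid(g),
                           if (nm == entry_stock) entrants else c(0, 0))
  }
  attr(out, "deaths") <- deaths
  out
}

# Rescale every stock cell-wise so the sub-model total matches the ledger.
renormalize_stocks <- function(stocks, target, entry_stock) {
  tot <- unclass(stocks_total(stocks))
  tgt <- unclass(target)
  f <- tgt / tot
  f[tot <= 0] <- 0
  out <- stocks
  for (nm in names(stocks)) out[[nm]] <- as_cohort_grid(unclass(stocks[[nm]]) * f)
  # cells with ledger population but an empty sub-model: seed the entry stock
  empty <- tot <= 0 & tgt > 0
  if (any(empty)) {
    g <- unclass(out[[entry_stock]])
    g[empty] <- tgt[empty]
    out[[entry_stock]] <- as_cohort_grid(g)
  }
  out
}

#' Run a full trajectory
#'
#' Simulates from the configured start year to the horizon end, optionally
#' applying timed parameter overrides (step changes held constant once
#' effective).
#'
#' @param inputs a `demography_inputs` covering the horizon.
#' @param state the initial `model_state` (start-of-horizon).
#' @param config a `cvdsim_config`.
#' @param overrides optional data.frame with columns `path`, `value`, `year`.
#' @param scenario name stored in the result metadata.
#' @return a `cvdsim_result`: a data.frame of annual indicators with
#'   attributes `events_by_group` (year x group matrix), `scenario`, `config`
#'   and `final_state`.
#' @export
run_model <- function(inputs, state, config, overrides = NULL, scenario = "base") {
  config <- validate_config(config)
  years <- config$horizon$start:config$horizon$end
  if (!all(years %in% inputs$years)) {
    stop("demographic inputs do not cover the simulation horizon", call. = FALSE)
  }
  if (!is.null(overrides) && nrow(overrides)) {
    for (p in overrides$path) config_get(config, p)   # fail fast on unknown paths
    if (any(overrides$year < years[1] | overrides$year > years[length(years)])) {
      stop("override effective year outside the horizon", call. = FALSE)
    }
  }
  standard_pop <- pmax(unclass(state$population) - unclass(state$post_cvd), 0)
  rows <- vector("list", length(years))
  ebg <- matrix(NA_real_, length(years), 8L, dimnames = list(years, risk_groups()))
  cfg_y <- config
  for (i in seq_along(years)) {
    yr <- years[i]
    if (!is.null(overrides) && nrow(overrides)) {
      due <- overrides[overrides$year <= yr, , drop = FALSE]
      cfg_y <- config
      for (k in seq_len(nrow(due))) {
        cfg_y <- config_set(cfg_y, due$path[k], due$value[k])
      }
    }
    stp <- step_model(state, inputs, cfg_y, yr, standard_pop = standard_pop)
    state <- stp$state
    ebg[i, ] <- stp$outputs$events_by_group
    rows[[i]] <- as.data.frame(stp$outputs[setdiff(names(stp$outputs), "events_by_group")])
  }
  out <- do.call(rbind, rows)
  structure(out,
    events_by_group = ebg,
    scenario = scenario,
    config = config,
    overrides = overrides,
    final_state = state,
    class = c("cvdsim_result", "data.frame")
  )
}

#' @export
print.cvdsim_result <- function(x, ...) {
  cat("<cvdsim_result> scenario:", attr(x, "scenario"),
      " years:", x$year[1], "-", x$year[nrow(x)], "\n")
  print.data.frame(utils::head(as.data.frame(x)[, c(
    "year", "events", "cvd_deaths", "post_cvd", "age_adjusted_incidence",
    "prev_diabetes", "prev_hypertension", "prev_smoking")], 12), digits = 4)
  if (nrow(x) > 12) cat("... (", nrow(x) - 12, " more years)\n", sep = "")
  invisible(x)
}
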