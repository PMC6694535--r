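# CVD event engine: eight comorbidity risk groups over {diabetes,
# hypertension, smoking}, Framingham-style logistic event probabilities with
# group-specific intercepts, treatment adjustment, and the post-CVD stock.

#' Risk-group labels
#'
#' The eight comorbidity combinations of diabetes (D), hypertension (H) and
#' smoking (S): `none, D, H, S, DH, DS, HS, DHS`.
#'
#' @return character vector of length 8.
#' @export
risk_groups <- function() c("none", "D", "H", "S", "DH", "DS", "HS", "DHS")

# 8 x 3 logical membership matrix: which factors each group contains.
group_membership <- function() {
  g <- risk_groups()
  m <- cbind(
    diabetes = grepl("D", g),
    hypertension = grepl("H", g),
    smoking = grepl("S", g)
  )
  rownames(m) <- g
  m
}

#' Partition the population into risk groups
#'
#' Converts the three marginal risk-factor prevalences of each age/sex cell
#' into shares of the eight comorbidity groups. The default `"independence"`
#' mode multiplies marginals (share(DHS) = pd*ph*ps, share(none) =
#' (1-pd)(1-ph)(1-ps), ...). The `"even_split"` mode seeds each factor's
#' population evenly across its four containing groups and reconciles to the
#' marginals by iterative proportional fitting.
#'
#' @param prev_d,prev_h,prev_s marginal prevalences in \[0, 1\]: scalars or
#'   grids. `NA` cells (empty cohorts) are treated as prevalence 0.
#' @param mode `"independence"` (default) or `"even_split"`.
#' @return a 3-d array `share[group, age, sex]` whose group-sums are 1 in
#'   every cell.
#' @export
partition_risk_groups <- function(prev_d, prev_h, prev_s,
                                  mode = c("independence", "even_split")) {
  mode <- match.arg(mode)
  pd <- rate_grid(prev_d); ph <- rate_grid(prev_h); ps <- rate_grid(prev_s)
  pd[is.na(pd)] <- 0; ph[is.na(ph)] <- 0; ps[is.na(ps)] <- 0
  for (p in list(pd, ph, ps)) {
    if (any(p < 0 | p > 1)) stop("prevalence outside [0, 1]", call. = FALSE)
  }
  mem <- group_membership()
  out <- array(NA_real_, dim = c(8L, 83L, 2L),
               dimnames = list(group = risk_groups(), age = CVDSIM_AGES, sex = CVDSIM_SEXES))
  if (mode == "independence") {
    for (g in 1:8) {
      out[g, , ] <- (if (mem[g, 1]) pd else 1 - pd) *
        (if (mem[g, 2]) ph else 1 - ph) *
        (if (mem[g, 3]) ps else 1 - ps)
    }
    return(out)
  }
  # even_split: per cell, IPF on the 2x2x2 table from an even-split seed
  for (i in 1:83) for (j in 1:2) {
    out[, i, j] <- even_split_cell(pd[i, j], ph[i, j], ps[i, j], mem)
  }
  out
}

even_split_cell <- function(pd, ph, ps, mem, iter = 200L, tol = 1e-12) {
  # seed: each factor's mass spread evenly over its four containing groups
  s <- rep(1e-9, 8)
  s <- s + mem[, 1] * pd / 4 + mem[, 2] * ph / 4 + mem[, 3] * ps / 4
  s[1] <- s[1] + max(1 - pd - ph - ps, 0)   # residual mass to 'none'
  s <- s / sum(s)
  marg <- c(pd, ph, ps)
  for (k in seq_len(iter)) {
    prev <- s
    for (f in 1:3) {
      inm <- sum(s[mem[, f]])
      if (marg[f] > 0 && inm > 0) s[mem[, f]] <- s[mem[, f]] * marg[f] / inm
      if (marg[f] == 0) s[mem[, f]] <- 0
      outm <- sum(s[!mem[, f]])
      if (outm > 0) s[!mem[, f]] <- s[!mem[, f]] * (1 - marg[f]) / outm
    }
    s <- s / sum(s)
    if (max(abs(s - prev)) < tol) break
  }
  s
}

#' Framingham-style risk-engine parameters
#'
#' Logistic coefficients and treatment effects of the CVD event engine.
#'
#' @param beta0 named length-8 vector of intercepts, one per risk group
#'   (names as [risk_groups()]).
#' @param beta_age,beta_diabetes,beta_hypertension,beta_smoking named
#'   female/male coefficient pairs.
#' @param rr_treated_diabetes,rr_treated_hypertension,rr_treated_smoking
#'   relative risks of a CVD event under management (cessation for smoking),
#'   each in (0, 1\].
#' @param event_death_rate fraction of CVD events that are fatal, in \[0, 1\].
#' @param rr_death_post_cvd relative mortality risk of CVD survivors (> 0).
#' @param treatment_mortality_effect fractional mortality reduction conferred
#'   by risk-factor treatment, in \[0, 1\].
#' @param fraction_post_cvd_treated fraction of the post-CVD population whose
#'   risk factors are treated, in \[0, 1\].
#' @return an object of class `risk_engine_params`.
#' @export
risk_engine_params <- function(beta0, beta_age, beta_diabetes, beta_hypertension,
                               beta_smoking,
                               rr_treated_diabetes, rr_treated_hypertension,
                               rr_treated_smoking,
                               event_death_rate, rr_death_post_cvd,
                               treatment_mortality_effect,
                               fraction_post_cvd_treated) {
  beta0 <- beta0[risk_groups()]
  if (anyNA(beta0)) stop("beta0 must be named after all eight risk groups", call. = FALSE)
  for (b in list(beta_age, beta_diabetes, beta_hypertension, beta_smoking)) {
    if (anyNA(b[CVDSIM_SEXES])) stop("sex coefficients must be named female/male", call. = FALSE)
  }
  for (rr in c(rr_treated_diabetes, rr_treated_hypertension, rr_treated_smoking)) {
    if (rr <= 0 || rr > 1) stop("treatment relative risks must lie in (0, 1]", call. = FALSE)
  }
  if (event_death_rate < 0 || event_death_rate > 1) {
    stop("event_death_rate must lie in [0, 1]", call. = FALSE)
  }
  if (rr_death_post_cvd <= 0) stop("rr_death_post_cvd must be > 0", call. = FALSE)
  structure(list(
    beta0 = beta0,
    beta_age = beta_age[CVDSIM_SEXES],
    beta_diabetes = beta_diabetes[CVDSIM_SEXES],
    beta_hypertension = beta_hypertension[CVDSIM_SEXES],
    beta_smoking = beta_smoking[CVDSIM_SEXES],
    rr_treated_diabetes = rr_treated_diabetes,
    rr_treated_hypertension = rr_treated_hypertension,
    rr_treated_smoking = rr_treated_smoking,
    event_death_rate = event_death_rate,
    rr_death_post_cvd = rr_death_post_cvd,
    treatment_mortality_effect = treatment_mortality_effect,
    fraction_post_cvd_treated = fraction_post_cvd_treated
  ), class = "risk_engine_params")
}

# Linear predictor excluding the intercept, for one group: array over cells.
group_linear_predictor <- function(group, params) {
  mem <- group_membership()[group, ]
  age <- matrix(CVDSIM_AGES, 83L, 2L)
  bage <- matrix(rep(as.numeric(params$beta_age), each = 83L), ncol = 2L)
  lin <- bage * age
  if (mem["diabetes"]) lin <- lin + matrix(rep(as.numeric(params$beta_diabetes), each = 83L), ncol = 2L)
  if (mem["hypertension"]) lin <- lin + matrix(rep(as.numeric(params$beta_hypertension), each = 83L), ncol = 2L)
  if (mem["smoking"]) lin <- lin + matrix(rep(as.numeric(params$beta_smoking), each = 83L), ncol = 2L)
  dimnames(lin) <- list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)
  lin
}

#' Annual CVD event probability for a risk group
#'
#' The logistic model
#' `p = 1 / (1 + exp(-(beta0[g] + beta_age*age + beta_D*1[D in g] +
#' beta_H*1[H in g] + beta_S*1[S in g])))` with sex-specific slope
#' coefficients and a calibrated per-group intercept.
#'
#' @param group one of [risk_groups()].
#' @param age age(s) in years, within 18..100.
#' @param sex `"female"` or `"male"` (recycled against `age`).
#' @param params a `risk_engine_params`.
#' @return event probability per year, strictly in (0, 1).
#' @examples
#' # a 60-year-old diabetic man under the packaged default coefficients
#' cvd_probability("D", 60, "male", default_engine_params())
#' @export
cvd_probability <- function(group, age, sex, params) {
  group <- match.arg(group, risk_groups())
  stopifnot(all(age >= 18), all(age <= 100))
  sex <- match.arg(sex, CVDSIM_SEXES, several.ok = TRUE)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  mem <- group_membership()[group, ]
  lin <- params$beta0[[group]] + as.numeric(params$beta_age[sex]) * age +
    mem[["diabetes"]] * as.numeric(params$beta_diabetes[sex]) +
    mem[["hypertension"]] * as.numeric(params$beta_hypertension[sex]) +
    mem[["smoking"]] * as.numeric(params$beta_smoking[sex])
  stats::plogis(lin)
}

# Probability array p[group, age, sex] for the whole grid.
cvd_probability_grid <- function(params) {
  out <- array(NA_real_, dim = c(8L, 83L, 2L),
               dimnames = list(group = risk_groups(), age = CVDSIM_AGES, sex = CVDSIM_SEXES))
  for (g in risk_groups()) {
    out[g, , ] <- stats::plogis(params$beta0[[g]] + group_linear_predictor(g, params))
  }
  out
}

#' Treatment-adjusted event probability
#'
#' The treated fraction of a group experiences risk multiplied by `rr`:
#' `AP = p*(1 - coverage) + p*coverage*rr`. Inside the simulator the
#' multiplier passed here is derived from the configured relative risks
#' according to the engine mode (see the methods vignette); this function's
#' contract is always "treated risk = rr * p".
#'
#' @param p untreated event probability, in \[0, 1\].
#' @param coverage treated fraction of the group, in \[0, 1\].
#' @param rr risk multiplier for the treated fraction, in (0, 1\].
#' @return adjusted probability; `AP <= p` whenever `rr <= 1`.
#' @examples
#' adjusted_probability(0.1, 1, 0.8)   # 0.08: 20% reduction at full coverage
#' @export
adjusted_probability <- function(p, coverage, rr) {
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]", call. = FALSE)
  if (any(coverage < 0 | coverage > 1)) stop("coverage outside [0, 1]", call. = FALSE)
  if (any(rr <= 0 | rr > 1)) stop("rr outside (0, 1]", call. = FALSE)
  p * (1 - coverage) + p * coverage * rr
}

# Per-group risk multiplier arrays from per-factor coverage grids and
# per-factor treated-risk multipliers (already mode-resolved by the caller).
# Management status is assumed independent across factors.
group_risk_multiplier <- function(cov_d, cov_h, cov_s, mult_d, mult_h, mult_s) {
  mem <- group_membership()
  fac <- list(list(rate_grid(cov_d), mult_d),
              list(rate_grid(cov_h), mult_h),
              list(rate_grid(cov_s), mult_s))
  out <- array(1, dim = c(8L, 83L, 2L),
               dimnames = list(group = risk_groups(), age = CVDSIM_AGES, sex = CVDSIM_SEXES))
  for (g in 1:8) {
    m <- matrix(1, 83L, 2L)
    for (f in 1:3) {
      if (mem[g, f]) {
        cov <- fac[[f]][[1]]
        m <- m * (1 - cov + cov * fac[[f]][[2]])
      }
    }
    out[g, , ] <- m
  }
  out
}

#' Annual CVD events from group populations and probabilities
#'
#' @param pop_by_group persons: array `[group, age, sex]` (or conformable).
#' @param adjusted_p adjusted event probabilities of the same shape.
#' @return array of events per year with the input shape; sum for totals.
#' @export
compute_events <- function(pop_by_group, adjusted_p) {
  stopifnot(identical(dim(pop_by_group), dim(adjusted_p)))
  pop_by_group * adjusted_p
}

#' Post-CVD (survivor) state
#'
#' @param post_cvd a `cohort_grid` of CVD survivors living with disability.
#' @param annual_events,annual_event_deaths,annual_post_cvd_deaths flow totals
#'   of the most recent year (persons/yr).
#' @return an object of class `cvd_state`.
#' @export
cvd_state <- function(post_cvd, annual_events = 0, annual_event_deaths = 0,
                      annual_post_cvd_deaths = 0) {
  structure(list(
    post_cvd = as_grid_arg(post_cvd),
    annual_events = annual_events,
    annual_event_deaths = annual_event_deaths,
    annual_post_cvd_deaths = annual_post_cvd_deaths
  ), class = "cvd_state")
}

#' Update the post-CVD stock for one year
#'
#' Event deaths are `events * event_death_rate`; survivors flow into the
#' post-CVD stock; the post-CVD population dies at
#' `mortality * rr_death_post_cvd * (1 - treatment_mortality_effect *
#' fraction_post_cvd_treated)` (capped at 1).
#'
#' @param state a `cvd_state`.
#' @param events grid (or scalar) of CVD events this year, by age/sex.
#' @param params a `risk_engine_params`.
#' @param mortality background annual death fraction: scalar, pair or grid.
#' @return the updated `cvd_state` (annual flow fields refreshed).
#' @export
update_post_cvd <- function(state, events, params, mortality) {
  ev <- rate_grid(events)
  m <- rate_grid(mortality)
  event_deaths <- ev * params$event_death_rate
  survivors <- ev - event_deaths
  pc_mort <- pmin(m * params$rr_death_post_cvd *
    (1 - params$treatment_mortality_effect * params$fraction_post_cvd_treated), 1)
  pc_deaths <- unclass(state$post_cvd) * pc_mort
  cvd_state(
    post_cvd = unclass(state$post_cvd) - pc_deaths + survivors,
    annual_events = sum(ev),
    annual_event_deaths = sum(event_deaths),
    annual_post_cvd_deaths = sum(pc_deaths)
  )
}

#' Directly age-standardized incidence rate
#'
#' `sum over cells of rate(age, sex) * w(age, sex)` with weights from a
#' standard population. Cells with zero population are excluded with a warning
#' when they carry standard weight.
#'
#' @param events grid of events per year.
#' @param pop grid of the population at risk.
#' @param standard_pop grid giving the standardization weights.
#' @return the age/sex-standardized incidence (a fraction per year).
#' @export
age_adjusted_incidence <- function(events, pop, standard_pop) {
  ev <- rate_grid(events); p <- rate_grid(pop); s <- rate_grid(standard_pop)
  if (sum(s) <= 0) stop("standard population total must be > 0", call. = FALSE)
  ok <- p > 0
  if (any(!ok & s > 0)) {
    warning("empty population cells excluded from age standardization", call. = FALSE)
  }
  w <- s * ok
  w <- w / sum(w)
  rate <- ifelse(ok, ev / ifelse(ok, p, 1), 0)
  sum(rate * w)
}
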