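# Risk-factor sub-models: a generic two-stage disease model (pre-condition and
# established condition, each split managed/unmanaged) used for diabetes and
# hypertension, and a three-state smoking model (never/current/former).
# All flows are explicit-Euler with annual steps: every outflow is computed
# from the start-of-stage stock, deaths are applied before transitions.

#' Stocks of a two-stage disease sub-model
#'
#' Five compartments per age/sex cell: healthy, pre-condition
#' (unmanaged/managed) and established disease (unmanaged/managed). The five
#' stocks partition the sub-model's total population.
#'
#' @param healthy,pre_unmanaged,pre_managed,disease_unmanaged,disease_managed
#'   `cohort_grid`s (scalars are expanded).
#' @return an object of class `two_stage_stocks`.
#' @export
two_stage_stocks <- function(healthy, pre_unmanaged = 0, pre_managed = 0,
                             disease_unmanaged = 0, disease_managed = 0) {
  out <- list(
    healthy = as_grid_arg(healthy),
    pre_unmanaged = as_grid_arg(pre_unmanaged),
    pre_managed = as_grid_arg(pre_managed),
    disease_unmanaged = as_grid_arg(disease_unmanaged),
    disease_managed = as_grid_arg(disease_managed)
  )
  structure(out, class = "two_stage_stocks")
}

as_grid_arg <- function(x) {
  if (inherits(x, "cohort_grid")) x else if (is.matrix(x)) as_cohort_grid(x) else cohort_grid(x)
}

#' @export
print.two_stage_stocks <- function(x, ...) {
  tot <- vapply(x, grid_total, numeric(1))
  cat("<two_stage_stocks> totals:\n")
  print(round(tot, 2))
  invisible(x)
}

#' Total population of a stocks object
#'
#' @param stocks a `two_stage_stocks` or `smoking_stocks`.
#' @return a `cohort_grid` of per-cell totals.
#' @export
stocks_total <- function(stocks) {
  as_cohort_grid(Reduce(`+`, lapply(stocks, unclass)))
}

#' Parameters of the two-stage disease sub-model
#'
#' Managed progression can be given either as an explicit rate
#' (`progression_rate_managed`, the diabetes pathway) or as a multiplier on the
#' unmanaged rate (`progression_effect_managed`, the hypertension pathway).
#'
#' @param incidence_rate healthy -> pre-condition, per year.
#' @param regression_rate pre-condition -> healthy, per year.
#' @param progression_rate_unmanaged pre -> disease for the unmanaged stock;
#'   scalar or named female/male pair.
#' @param progression_rate_managed pre -> disease for the managed stock
#'   (explicit rate pathway), or `NULL`.
#' @param progression_effect_managed multiplier in \[0, 1\] applied to the
#'   unmanaged progression rate for the managed stock, or `NULL`. Exactly one
#'   of the two managed-progression arguments must be supplied.
#' @param uptake_rate unmanaged -> managed, per year.
#' @param treatment_mortality_effect fractional mortality reduction for managed
#'   stocks (mortality is multiplied by `1 - effect`).
#' @param uptake_stages which stocks the uptake flow applies to: `"both"`
#'   (default), `"pre"` or `"disease"`.
#' @param regression_scope whether pre-condition regression applies to `"both"`
#'   managed and unmanaged pre stocks (default) or `"managed"` only.
#' @param dropout_rate managed -> unmanaged reversion, per year (default 0; no
#'   such flow in the core model).
#' @return an object of class `two_stage_params`.
#' @export
two_stage_params <- function(incidence_rate, regression_rate,
                             progression_rate_unmanaged,
                             progression_rate_managed = NULL,
                             progression_effect_managed = NULL,
                             uptake_rate,
                             treatment_mortality_effect = 0,
                             uptake_stages = c("both", "pre", "disease"),
                             regression_scope = c("both", "managed"),
                             dropout_rate = 0) {
  uptake_stages <- match.arg(uptake_stages)
  regression_scope <- match.arg(regression_scope)
  if (is.null(progression_rate_managed) == is.null(progression_effect_managed)) {
    stop("supply exactly one of progression_rate_managed / progression_effect_managed",
         call. = FALSE)
  }
  rates <- c(incidence_rate, regression_rate, progression_rate_unmanaged,
             progression_rate_managed, uptake_rate, dropout_rate)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (!is.null(progression_effect_managed) &&
      (progression_effect_managed < 0 || progression_effect_managed > 1)) {
    stop("progression_effect_managed must lie in [0, 1]", call. = FALSE)
  }
  if (treatment_mortality_effect < 0 || treatment_mortality_effect > 1) {
    stop("treatment_mortality_effect must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    incidence_rate = incidence_rate,
    regression_rate = regression_rate,
    progression_rate_unmanaged = progression_rate_unmanaged,
    progression_rate_managed = progression_rate_managed,
    progression_effect_managed = progression_effect_managed,
    uptake_rate = uptake_rate,
    treatment_mortality_effect = treatment_mortality_effect,
    uptake_stages = uptake_stages,
    regression_scope = regression_scope,
    dropout_rate = dropout_rate
  ), class = "two_stage_params")
}

managed_progression_grid <- function(params) {
  if (!is.null(params$progression_rate_managed)) {
    rate_grid(params$progression_rate_managed)
  } else {
    rate_grid(params$progression_rate_unmanaged) * params$progression_effect_managed
  }
}

#' Advance a two-stage disease sub-model one year
#'
#' Order within the step: deaths first (managed stocks die at
#' `mortality * (1 - treatment_mortality_effect)`), then all transition flows
#' simultaneously from the post-death stocks: incidence (healthy ->
#' pre-unmanaged), regression (pre -> healthy), progression (pre -> disease,
#' managed stock at the managed rate), uptake (unmanaged -> managed).
#' Migration and ageing are handled by the caller.
#'
#' @param stocks a `two_stage_stocks`.
#' @param params a `two_stage_params`.
#' @param mortality annual death fraction: scalar, female/male pair, or grid.
#' @param on_negative `"error"` (default) to fail when combined outflows exceed
#'   a stock, or `"clamp"` to scale the cell's outflows down with a warning.
#' @return the next-year `two_stage_stocks`, with attribute `"deaths"` (the
#'   total deaths removed) for conservation accounting.
#' @export
step_two_stage <- function(stocks, params, mortality,
                           on_negative = c("error", "clamp")) {
  on_negative <- match.arg(on_negative)
  m <- rate_grid(mortality)
  if (any(m < 0 | m > 1)) stop("mortality outside [0, 1]", call. = FALSE)
  mm <- m * (1 - params$treatment_mortality_effect)

  h <- unclass(stocks$healthy) * (1 - m)
  pu <- unclass(stocks$pre_unmanaged) * (1 - m)
  pm <- unclass(stocks$pre_managed) * (1 - mm)
  du <- unclass(stocks$disease_unmanaged) * (1 - m)
  dm <- unclass(stocks$disease_managed) * (1 - mm)
  deaths <- grid_total(stocks_total(stocks)) - (sum(h) + sum(pu) + sum(pm) + sum(du) + sum(dm))

  prog_u_rate <- rate_grid(params$progression_rate_unmanaged)
  prog_m_rate <- managed_progression_grid(params)
  up_pre <- if (params$uptake_stages %in% c("both", "pre")) params$uptake_rate else 0
  up_dis <- if (params$uptake_stages %in% c("both", "disease")) params$uptake_rate else 0
  reg_u_rate <- if (params$regression_scope == "both") params$regression_rate else 0

  inc <- h * params$incidence_rate
  reg_u <- pu * reg_u_rate
  reg_m <- pm * params$regression_rate
  prog_u <- pu * prog_u_rate
  prog_m <- pm * prog_m_rate
  upt_pre <- pu * up_pre
  upt_dis <- du * up_dis
  drop_pre <- pm * params$dropout_rate
  drop_dis <- dm * params$dropout_rate

  # guard against combined outflows exceeding the source stock
  chk <- list(healthy = list(h, inc),
              pre_unmanaged = list(pu, reg_u + prog_u + upt_pre),
              pre_managed = list(pm, reg_m + prog_m + drop_pre),
              disease_unmanaged = list(du, upt_dis),
              disease_managed = list(dm, drop_dis))
  scale <- lapply(chk, function(x) outflow_scale(x[[1]], x[[2]], on_negative))
  inc <- inc * scale$healthy
  reg_u <- reg_u * scale$pre_unmanaged; prog_u <- prog_u * scale$pre_unmanaged
  upt_pre <- upt_pre * scale$pre_unmanaged
  reg_m <- reg_m * scale$pre_managed; prog_m <- prog_m * scale$pre_managed
  drop_pre <- drop_pre * scale$pre_managed
  upt_dis <- upt_dis * scale$disease_unmanaged
  drop_dis <- drop_dis * scale$disease_managed

  out <- two_stage_stocks(
    healthy = h - inc + reg_u + reg_m,
    pre_unmanaged = pu + inc - reg_u - prog_u - upt_pre + drop_pre,
    pre_managed = pm + upt_pre - reg_m - prog_m - drop_pre,
    disease_unmanaged = du + prog_u - upt_dis + drop_dis,
    disease_managed = dm + prog_m + upt_dis - drop_dis
  )
  attr(out, "deaths") <- deaths
  out
}

outflow_scale <- function(stock, outflow, on_negative) {
  bad <- outflow > stock + 1e-12
  if (!any(bad)) return(1)
  if (on_negative == "error") {
    stop("combined outflows exceed a stock; reduce rates or use on_negative = 'clamp'",
         call. = FALSE)
  }
  warning("outflows exceeded a stock in ", sum(bad), " cell(s); scaled down", call. = FALSE)
  s <- matrix(1, nrow(stock), ncol(stock))
  s[bad] <- stock[bad] / outflow[bad]
  s
}

#' Stocks of the smoking sub-model
#'
#' @param never,current,former `cohort_grid`s (scalars expanded): never
#'   smokers, current smokers and former smokers.
#' @return an object of class `smoking_stocks`.
#' @export
smoking_stocks <- function(never, current = 0, former = 0) {
  structure(list(
    never = as_grid_arg(never),
    current = as_grid_arg(current),
    former = as_grid_arg(former)
  ), class = "smoking_stocks")
}

#' Parameters of the smoking sub-model
#'
#' @param initiation_rate never -> current, per year.
#' @param cessation_rate current -> former, per year.
#' @param relapse_rate former -> current, per year.
#' @return an object of class `smoking_params`.
#' @export
smoking_params <- function(initiation_rate, cessation_rate, relapse_rate) {
  if (any(c(initiation_rate, cessation_rate, relapse_rate) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  structure(list(initiation_rate = initiation_rate,
                 cessation_rate = cessation_rate,
                 relapse_rate = relapse_rate), class = "smoking_params")
}

#' Advance the smoking sub-model one year
#'
#' Deaths first (same mortality in all three states), then simultaneous flows
#' initiation (never -> current), cessation (current -> former) and relapse
#' (former -> current), then 18-year-old entrants join the never-smoker stock.
#'
#' @param stocks a `smoking_stocks`.
#' @param params a `smoking_params`.
#' @param mortality annual death fraction: scalar, pair or grid.
#' @param new_18_entrants persons added to the age-18 never-smoker cell,
#'   length-2 (female, male).
#' @param on_negative see [step_two_stage()].
#' @return next-year `smoking_stocks` with attribute `"deaths"`.
#' @export
step_smoking <- function(stocks, params, mortality,
                         new_18_entrants = c(female = 0, male = 0),
                         on_negative = c("error", "clamp")) {
  on_negative <- match.arg(on_negative)
  m <- rate_grid(mortality)
  if (any(m < 0 | m > 1)) stop("mortality outside [0, 1]", call. = FALSE)
  nv <- unclass(stocks$never) * (1 - m)
  cu <- unclass(stocks$current) * (1 - m)
  fo <- unclass(stocks$former) * (1 - m)
  deaths <- grid_total(stocks_total(stocks)) - (sum(nv) + sum(cu) + sum(fo))

  init <- nv * params$initiation_rate * outflow_scale(nv, nv * params$initiation_rate, on_negative)
  ces <- cu * params$cessation_rate * outflow_scale(cu, cu * params$cessation_rate, on_negative)
  rel <- fo * params$relapse_rate * outflow_scale(fo, fo * params$relapse_rate, on_negative)

  nv2 <- nv - init
  nv2["18", ] <- nv2["18", ] + as.numeric(new_18_entrants)
  out <- smoking_stocks(
    never = nv2,
    current = cu + init + rel - ces,
    former = fo + ces - rel
  )
  attr(out, "deaths") <- deaths
  out
}

#' Prevalence of a sub-model state
#'
#' Per-cell and population-weighted aggregate prevalence. Cells with zero total
#' population carry `NA` per-cell prevalence and are excluded from the
#' aggregate.
#'
#' @param stocks a `two_stage_stocks` or `smoking_stocks`.
#' @param state which numerator to use. Two-stage: `"disease"` (default),
#'   `"pre"`, `"managed_disease"`, `"managed_pre"`. Smoking: `"current"`
#'   (default), `"former"`, `"ever"`.
#' @return a list with `cell` (a grid of fractions, `NA` where empty) and
#'   `aggregate` (a single population-weighted fraction, `NA` if the sub-model
#'   is empty).
#' @export
prevalence <- function(stocks, state = NULL) UseMethod("prevalence")

#' @export
prevalence.two_stage_stocks <- function(stocks, state = c("disease", "pre", "managed_disease", "managed_pre")) {
  state <- match.arg(state)
  num <- switch(state,
    disease = unclass(stocks$disease_unmanaged) + unclass(stocks$disease_managed),
    pre = unclass(stocks$pre_unmanaged) + unclass(stocks$pre_managed),
    managed_disease = unclass(stocks$disease_managed),
    managed_pre = unclass(stocks$pre_managed)
  )
  prevalence_of(num, stocks_total(stocks))
}

#' @export
prevalence.smoking_stocks <- function(stocks, state = c("current", "former", "ever")) {
  state <- match.arg(state)
  num <- switch(state,
    current = unclass(stocks$current),
    former = unclass(stocks$former),
    ever = unclass(stocks$current) + unclass(stocks$former)
  )
  prevalence_of(num, stocks_total(stocks))
}

prevalence_of <- function(num, total) {
  tot <- unclass(total)
  cell <- num / tot
  cell[tot <= 0] <- NA_real_
  agg <- if (sum(tot) > 0) sum(num) / sum(tot) else NA_real_
  list(cell = cell, aggregate = agg)
}

#' Managed share of a condition
#'
#' Fraction of persons with the (pre-)condition who are managed, per cell and
#' aggregate.
#'
#' @param stocks a `two_stage_stocks`.
#' @param stage `"disease"` (default) or `"pre"`.
#' @return list with `cell` grid (`NA` where nobody has the condition) and
#'   `aggregate` share.
#' @export
managed_share <- function(stocks, stage = c("disease", "pre")) {
  stage <- match.arg(stage)
  if (stage == "disease") {
    num <- unclass(stocks$disease_managed)
    den <- num + unclass(stocks$disease_unmanaged)
  } else {
    num <- unclass(stocks$pre_managed)
    den <- num + unclass(stocks$pre_unmanaged)
  }
  cell <- num / den
  cell[den <= 0] <- NA_real_
  agg <- if (sum(den) > 0) sum(num) / sum(den) else NA_real_
  list(cell = cell, aggregate = agg)
}
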