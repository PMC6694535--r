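# Calibration: per-group logistic intercepts from an expert distribution of
# CVD events, and transition-rate fitting to prevalence/event time series.

#' Expert distribution of CVD events by risk group
#'
#' @param fractions named non-negative length-8 vector summing to 1 (names as
#'   [risk_groups()]).
#' @return an object of class `event_distribution`.
#' @export
event_distribution <- function(fractions) {
  fractions <- fractions[risk_groups()]
  if (anyNA(fractions)) stop("fractions must be named after all eight risk groups", call. = FALSE)
  if (any(fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  structure(fractions, class = "event_distribution")
}

#' Packaged expert event distribution
#'
#' The expert-elicited share of CVD events falling in each comorbidity group:
#' none 1%, D 20%, H 10%, S 5%, D+H 29%, D+S 5%, H+S 15%, D+H+S 15%
#' (the upper-triangular expert table read as: diagonal = single-factor
#' groups, off-diagonal = pairs, the pair-column crossed with the smoking row
#' = the triple).
#'
#' @return an `event_distribution`.
#' @export
default_event_distribution <- function() {
  event_distribution(c(none = 0.01, D = 0.20, H = 0.10, S = 0.05,
                       DH = 0.29, DS = 0.05, HS = 0.15, DHS = 0.15))
}

#' Calibration target series
#'
#' @param prevalence matrix or data.frame of observed aggregate prevalences:
#'   rows = years (rownames), columns among
#'   `diabetes, hypertension, smoking`.
#' @param total_events named numeric vector of annual CVD events (names =
#'   years).
#' @param event_distribution an [event_distribution()].
#' @return an object of class `calibration_targets`.
#' @export
calibration_targets <- function(prevalence, total_events, event_distribution) {
  prevalence <- as.matrix(prevalence)
  stopifnot(!is.null(rownames(prevalence)), !is.null(names(total_events)))
  structure(list(
    prevalence = prevalence,
    total_events = total_events,
    event_distribution = event_distribution
  ), class = "calibration_targets")
}

#' Calibrate per-group intercepts to an event distribution
#'
#' For each risk group g, solves the one-dimensional monotone problem
#' `sum over cells of pop_g * plogis(beta0 + lin) = total_events * fraction_g`
#' where `lin` is the known part of the linear predictor, by safeguarded
#' Newton iteration to an event mismatch below `tol`.
#'
#' @param targets a `calibration_targets` (the first year of `total_events`
#'   is the calibration anchor) or a single total-event count with the
#'   distribution supplied via `distribution`.
#' @param pop_by_group array `[group, age, sex]` of persons at risk.
#' @param params a `risk_engine_params` supplying the slope coefficients
#'   (its `beta0` entries are ignored).
#' @param distribution an [event_distribution()]; defaults to the one inside
#'   `targets`.
#' @param tol absolute tolerance on the event mismatch.
#' @return named length-8 vector of intercepts. Groups with zero target events
#'   but positive population get `-Inf` with a warning; a target at or above
#'   the group population is an error.
#' @export
calibrate_beta0 <- function(targets, pop_by_group, params,
                            distribution = NULL, tol = 1e-10) {
  if (inherits(targets, "calibration_targets")) {
    total <- targets$total_events[[1]]
    if (is.null(distribution)) distribution <- targets$event_distribution
  } else {
    total <- as.numeric(targets)
  }
  if (is.null(distribution)) stop("an event distribution is required", call. = FALSE)
  out <- stats::setNames(numeric(8), risk_groups())
  for (g in risk_groups()) {
    pop <- pop_by_group[g, , ]
    lin <- group_linear_predictor(g, params)
    target <- total * distribution[[g]]
    P <- sum(pop)
    if (target == 0) {
      if (P > 0) warning("group ", g, ": zero target events; beta0 = -Inf", call. = FALSE)
      out[g] <- -Inf
      next
    }
    if (P <= 0) stop("group ", g, ": nonzero target events but empty population", call. = FALSE)
    if (target >= P) stop("group ", g, ": target events >= group population; infeasible", call. = FALSE)
    out[g] <- solve_beta0(pop, lin, target, tol)
  }
  out
}

# Safeguarded Newton on f(b) = sum(pop * plogis(b + lin)) - target.
solve_beta0 <- function(pop, lin, target, tol) {
  f <- function(b) sum(pop * stats::plogis(b + lin)) - target
  # bracket: plogis is monotone, so these bounds always enclose the root
  lo <- stats::qlogis(target / sum(pop)) - max(lin)
  hi <- stats::qlogis(target / sum(pop)) - min(lin)
  lo <- lo - 1; hi <- hi + 1
  b <- stats::qlogis(target / sum(pop)) - sum(pop * lin) / sum(pop)
  b <- min(max(b, lo), hi)
  for (i in 1:100) {
    p <- stats::plogis(b + lin)
    fb <- sum(pop * p) - target
    if (abs(fb) <= tol) return(b)
    if (fb > 0) hi <- min(hi, b) else lo <- max(lo, b)
    deriv <- sum(pop * p * (1 - p))
    b_new <- if (deriv > 0) b - fb / deriv else NA_real_
    if (!is.finite(b_new) || b_new <= lo || b_new >= hi) b_new <- (lo + hi) / 2
    b <- b_new
  }
  r <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)
  r$root
}

#' Fit free transition rates to target series
#'
#' Minimizes the sum of squared (relative, by default) errors between
#' simulated and observed prevalence/event series over the named free
#' parameters, within box bounds, using a deterministic quasi-Newton
#' optimizer started from the supplied values.
#'
#' @param free_params named numeric vector of starting values; names are
#'   config paths (e.g. `"diabetes.incidence_rate"`).
#' @param targets a `calibration_targets`.
#' @param inputs,state,config the simulation world the candidate parameters
#'   are evaluated in (base-case scenario, no overrides).
#' @param lower,upper box bounds (recycled; defaults `0` and `1`).
#' @param loss `"relative"` (default; residuals divided by the observation) or
#'   `"absolute"`.
#' @param use_events include the total-event series in the loss (default
#'   `TRUE` when present).
#' @return a list with `par` (fitted values), `value` (final loss),
#'   `residuals` (per-series relative residual matrix), `converged` (logical)
#'   and `counts`. Non-convergence is flagged, never silent.
#' @export
fit_rates <- function(free_params, targets, inputs, state, config,
                      lower = 0, upper = 1,
                      loss = c("relative", "absolute"),
                      use_events = TRUE) {
  loss <- match.arg(loss)
  if (length(free_params) == 0L) {
    res <- fit_residuals(numeric(0), targets, inputs, state, config, loss, use_events)
    return(list(par = free_params, value = sum(res$res^2),
                residuals = res$res, converged = TRUE,
                counts = c(`function` = 1L, gradient = 0L)))
  }
  stopifnot(!is.null(names(free_params)))
  if (nrow(targets$prevalence) < 2L) stop("targets must span >= 2 years", call. = FALSE)
  for (p in names(free_params)) config_get(config, p)  # fail fast
  lower <- rep_len(lower, length(free_params))
  upper <- rep_len(upper, length(free_params))
  obj <- function(par) {
    r <- fit_residuals(stats::setNames(par, names(free_params)),
                       targets, inputs, state, config, loss, use_events)
    sum(r$res^2)
  }
  opt <- stats::optim(unname(free_params), obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e7, maxit = 200,
                                     parscale = pmax(abs(free_params), 1e-4)))
  par <- stats::setNames(opt$par, names(free_params))
  res <- fit_residuals(par, targets, inputs, state, config, loss, use_events)
  conv <- opt$convergence == 0
  if (!conv) warning("fit_rates did not converge: ", opt$message, call. = FALSE)
  list(par = par, value = opt$value, residuals = res$res,
       converged = conv, counts = opt$counts)
}

fit_residuals <- function(par, targets, inputs, state, config, loss, use_events) {
  cfg <- config
  for (nm in names(par)) cfg <- config_set(cfg, nm, par[[nm]])
  yrs <- as.integer(rownames(targets$prevalence))
  cfg$horizon$start <- min(yrs)
  cfg$horizon$end <- max(yrs)
  sim <- run_model(inputs, state, cfg, scenario = "calibration")
  sim_prev <- cbind(diabetes = sim$prev_diabetes,
                    hypertension = sim$prev_hypertension,
                    smoking = sim$prev_smoking)
  rownames(sim_prev) <- sim$year
  res <- c()
  for (f in colnames(targets$prevalence)) {
    obs <- targets$prevalence[, f]
    mod <- sim_prev[rownames(targets$prevalence), f]
    r <- if (loss == "relative") (mod - obs) / ifelse(obs != 0, obs, 1) else mod - obs
    res <- c(res, stats::setNames(r, paste0(f, ".", rownames(targets$prevalence))))
  }
  if (use_events && length(targets$total_events)) {
    obs <- targets$total_events
    mod <- sim$events[match(as.integer(names(obs)), sim$year)]
    r <- if (loss == "relative") (mod - obs) / ifelse(obs != 0, obs, 1) else mod - obs
    res <- c(res, stats::setNames(r, paste0("events.", names(obs))))
  }
  list(res = res, sim = sim)
}
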