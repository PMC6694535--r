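# Model configuration: the packaged defaults are the published parameter
# table of the model (transition rates, risk-engine coefficients, treatment
# relative risks), plus simulation span and engine mode switches.

#' Default model configuration
#'
#' Returns the full parameter set of the simulator with its packaged default
#' values: the three risk-factor sub-model rate tables, the CVD risk-engine
#' coefficients (per-group intercepts, sex-specific age/diabetes/hypertension/
#' smoking slopes, treatment relative risks, event fatality, post-CVD excess
#' mortality), the simulation span, and the engine mode switches.
#'
#' Mode switches:
#' \describe{
#'   \item{`eq10_literal`}{`TRUE` (default): the treated fraction's risk is
#'     multiplied by `1 - RR` (the model's printed adjustment equation; this
#'     reproduces the headline scenario ordering). `FALSE`: multiplied by `RR`.}
#'   \item{`partition_mode`}{`"independence"` or `"even_split"` risk-group
#'     allocation.}
#'   \item{`smoking_definition`}{`"ever"` (default): smoking groups contain
#'     current + former smokers and cessation coverage is the former-smoker
#'     share; `"current"`: current smokers only, quitters leave the group.}
#'   \item{`hazard`}{treat rates as instantaneous hazards (`1 - exp(-r)`).}
#'   \item{`renormalize`}{rescale sub-model stocks to the demographic ledger
#'     each year (default `TRUE`).}
#' }
#'
#' @return a nested named list of class `cvdsim_config`.
#' @export
default_config <- function() {
  cfg <- list(
    horizon = list(start = 2010L, end = 2040L),
    dt = 1,
    modes = list(
      eq10_literal = TRUE,
      partition_mode = "independence",
      smoking_definition = "ever",
      hazard = FALSE,
      renormalize = TRUE,
      on_negative = "error"
    ),
    demography = list(
      fecund_correction = 1
    ),
    diabetes = list(
      incidence_rate = 0.0328368,
      progression_rate_managed = 0.0134,
      progression_rate_unmanaged = 0.0556,
      regression_rate = 0.193,
      uptake_rate = 0.05,
      treatment_mortality_effect = 0.13
    ),
    hypertension = list(
      incidence_rate = 0.0237906,
      progression_rate_unmanaged = c(female = 0.06975, male = 0.080125),
      progression_effect_managed = 0.33,
      regression_rate = 0.25,
      uptake_rate = 0.035,
      treatment_mortality_effect = 0.13
    ),
    smoking = list(
      initiation_rate = 0.0082388,
      relapse_rate = 0.1,
      cessation_rate = 0.162
    ),
    cvd = list(
      beta0 = c(none = -11.968, D = -5.53323, H = -6.91289, S = -5.33926,
                DH = -6.74229, DS = -8.09581, HS = -7.10026, DHS = -8.18119),
      beta_age = c(female = 0.0699, male = 0.0488),
      beta_diabetes = c(female = 0.5604, male = 0.3492),
      beta_hypertension = c(female = 0.0161, male = 0.0152),
      beta_smoking = c(female = 0.5419, male = 0.5224),
      rr_treated_diabetes = 0.8,
      rr_treated_hypertension = 0.5,
      rr_treated_smoking = 0.5,
      event_death_rate = 0.2,
      rr_death_post_cvd = 1.6,
      treatment_mortality_effect = 0.13,
      fraction_post_cvd_treated = 1
    )
  )
  structure(cfg, class = "cvdsim_config")
}

#' Risk-engine parameters from a configuration
#'
#' @param config a `cvdsim_config` (default: packaged defaults).
#' @return a [risk_engine_params()] object.
#' @export
default_engine_params <- function(config = default_config()) {
  cv <- config$cvd
  risk_engine_params(
    beta0 = cv$beta0, beta_age = cv$beta_age, beta_diabetes = cv$beta_diabetes,
    beta_hypertension = cv$beta_hypertension, beta_smoking = cv$beta_smoking,
    rr_treated_diabetes = cv$rr_treated_diabetes,
    rr_treated_hypertension = cv$rr_treated_hypertension,
    rr_treated_smoking = cv$rr_treated_smoking,
    event_death_rate = cv$event_death_rate,
    rr_death_post_cvd = cv$rr_death_post_cvd,
    treatment_mortality_effect = cv$treatment_mortality_effect,
    fraction_post_cvd_treated = cv$fraction_post_cvd_treated
  )
}

two_stage_params_from_config <- function(block, on_negative = "error") {
  two_stage_params(
    incidence_rate = block$incidence_rate,
    regression_rate = block$regression_rate,
    progression_rate_unmanaged = unlist(block$progression_rate_unmanaged),
    progression_rate_managed = block$progression_rate_managed,
    progression_effect_managed = block$progression_effect_managed,
    uptake_rate = block$uptake_rate,
    treatment_mortality_effect = block$treatment_mortality_effect
  )
}

smoking_params_from_config <- function(block) {
  smoking_params(block$initiation_rate, block$cessation_rate, block$relapse_rate)
}

#' Validate a configuration
#'
#' Checks structure (unknown keys rejected by comparison against the default
#' skeleton) and bounds; errors name the offending key.
#'
#' @param config a list shaped like [default_config()].
#' @return the validated config, invisibly, classed `cvdsim_config`.
#' @export
validate_config <- function(config) {
  check_keys(config, default_config(), "config")
  with(config, {
    if (horizon$start >= horizon$end) stop("config: horizon start must precede end", call. = FALSE)
    if (dt <= 0) stop("config: dt must be > 0", call. = FALSE)
  })
  bounds01 <- c(
    "diabetes.uptake_rate", "diabetes.treatment_mortality_effect",
    "hypertension.uptake_rate", "hypertension.progression_effect_managed",
    "hypertension.treatment_mortality_effect",
    "cvd.rr_treated_diabetes", "cvd.rr_treated_hypertension",
    "cvd.rr_treated_smoking", "cvd.event_death_rate",
    "cvd.treatment_mortality_effect", "cvd.fraction_post_cvd_treated"
  )
  for (p in bounds01) {
    v <- config_get(config, p)
    if (any(v < 0 | v > 1)) {
      stop("config: ", p, " = ", v[1], " outside [0, 1]", call. = FALSE)
    }
  }
  nonneg <- c(
    "diabetes.incidence_rate", "diabetes.progression_rate_managed",
    "diabetes.progression_rate_unmanaged", "diabetes.regression_rate",
    "hypertension.incidence_rate", "hypertension.progression_rate_unmanaged",
    "hypertension.regression_rate",
    "smoking.initiation_rate", "smoking.relapse_rate", "smoking.cessation_rate",
    "cvd.rr_death_post_cvd"
  )
  for (p in nonneg) {
    v <- config_get(config, p)
    if (any(v < 0)) stop("config: ", p, " must be >= 0", call. = FALSE)
  }
  if (!config$modes$partition_mode %in% c("independence", "even_split")) {
    stop("config: modes.partition_mode must be independence or even_split", call. = FALSE)
  }
  if (!config$modes$smoking_definition %in% c("ever", "current")) {
    stop("config: modes.smoking_definition must be ever or current", call. = FALSE)
  }
  invisible(structure(config, class = "cvdsim_config"))
}

check_keys <- function(x, skeleton, path) {
  extra <- setdiff(names(x), names(skeleton))
  if (length(extra)) {
    stop("config: unknown key ", path, ".", extra[1], call. = FALSE)
  }
  missing <- setdiff(names(skeleton), names(x))
  if (length(missing)) {
    stop("config: missing key ", path, ".", missing[1], call. = FALSE)
  }
  for (nm in names(skeleton)) {
    if (is.list(skeleton[[nm]]) && !is.null(names(skeleton[[nm]])) &&
        !is.numeric(skeleton[[nm]])) {
      check_keys(x[[nm]], skeleton[[nm]], paste0(path, ".", nm))
    }
  }
  invisible(TRUE)
}

#' Get a configuration value by dotted path
#'
#' @param config a `cvdsim_config`.
#' @param path dotted key path, e.g. `"diabetes.uptake_rate"` or
#'   `"cvd.beta0.DH"`.
#' @return the value.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- config
  for (k in keys) {
    if (is.null(x) || !k %in% names(x)) {
      stop("unknown config path: ", path, call. = FALSE)
    }
    x <- x[[k]]
  }
  x
}

#' Set a configuration value by dotted path
#'
#' Errors on unknown paths, so scenario overrides fail before a run starts.
#'
#' @param config a `cvdsim_config`.
#' @param path dotted key path (see [config_get()]).
#' @param value replacement value (same length as the existing one).
#' @return the modified config.
#' @export
config_set <- function(config, path, value) {
  old <- config_get(config, path)   # errors on unknown path
  if (length(old) != length(value) && length(value) != 1L) {
    stop("config_set: length mismatch at ", path, call. = FALSE)
  }
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    if (length(keys) == 1L) {
      if (is.list(x)) {
        x[[keys]] <- if (length(old) > 1L && length(value) == 1L) {
          stats::setNames(rep(value, length(old)), names(old))
        } else value
      } else {
        x[keys] <- value
      }
      return(x)
    }
    x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    x
  }
  structure(rec(unclass(config), keys), class = "cvdsim_config")
}

#' Read a configuration from JSON
#'
#' The file may specify any subset of keys; unspecified keys take the packaged
#' defaults. Unknown keys and out-of-bounds values are rejected.
#'
#' @param path JSON file path.
#' @return a validated `cvdsim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), raw, "config")
  validate_config(cfg)
}

merge_config <- function(base, override, path) {
  extra <- setdiff(names(override), names(base))
  if (length(extra)) stop("config: unknown key ", path, ".", extra[1], call. = FALSE)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], paste0(path, ".", nm))
    } else {
      v <- override[[nm]]
      old <- base[[nm]]
      if (!is.null(names(old)) && is.numeric(old)) {
        v <- unlist(v)[names(old)]
        if (anyNA(v)) stop("config: ", path, ".", nm, " must name ", paste(names(old), collapse = "/"), call. = FALSE)
      }
      base[[nm]] <- v
    }
  }
  base
}

#' Write a configuration to JSON
#'
#' @param config a `cvdsim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  # jsonlite drops the names of atomic vectors; listify them so female/male
  # and per-group entries survive the round trip
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (length(x) > 1L && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(listify(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
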