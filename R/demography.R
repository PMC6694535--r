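# Demography: births, deaths, net migration and single-year ageing for the
# 18..100+ population, shared by all risk-factor sub-models.

#' Assemble demographic inputs
#'
#' Bundles the exogenous demographic series the simulator consumes. Mortality
#' and net migration are year x age x sex arrays; fertility is a per-year
#' series of births per fecund woman. Persons below the modelled range (age
#' 15-17) are approximated by women aged 18-49 times `fecund_correction`.
#'
#' @param initial_population a `cohort_grid` for the start year.
#' @param years integer vector of simulation years the series cover.
#' @param fertility_rate births per fecund woman per year; scalar or vector
#'   along `years`.
#' @param mortality_rate fraction dying per year: a single grid (held constant),
#'   or a `[year, age, sex]` array along `years`. All values must lie in
#'   \[0, 1\].
#' @param net_migration net migrants (persons/yr, may be negative): a grid or
#'   `[year, age, sex]` array. Default 0.
#' @param entrants persons turning 18 each year: a `[year, sex]` matrix, or
#'   `NULL` for the default "replacement" rule (each year's entrants equal the
#'   current age-18 cohort, holding it constant).
#' @param fecund_age_band modelled fecund ages; fixed at 15-49, with ages below
#'   18 folded into `fecund_correction`.
#' @param fecund_correction multiplier applied to women 18-49 to approximate
#'   the full 15-49 band (default 1).
#' @return an object of class `demography_inputs`.
#' @export
demography_inputs <- function(initial_population, years,
                              fertility_rate,
                              mortality_rate,
                              net_migration = 0,
                              entrants = NULL,
                              fecund_age_band = c(15, 49),
                              fecund_correction = 1) {
  initial_population <- as_cohort_grid(unclass(initial_population))
  years <- as.integer(years)
  stopifnot(length(years) >= 1L, !is.unsorted(years))
  fert <- rep_len(as.numeric(fertility_rate), length(years))
  if (any(fert < 0)) stop("fertility_rate must be >= 0", call. = FALSE)
  mort <- as_year_array(mortality_rate, years, "mortality_rate")
  if (any(mort < 0 | mort > 1)) {
    stop("mortality_rate must lie in [0, 1]", call. = FALSE)
  }
  mig <- as_year_array(net_migration, years, "net_migration")
  if (!is.null(entrants)) {
    entrants <- matrix(as.numeric(entrants), nrow = length(years), ncol = 2L,
                       dimnames = list(year = years, sex = CVDSIM_SEXES))
    if (any(entrants < 0)) stop("entrants must be >= 0", call. = FALSE)
  }
  stopifnot(identical(as.numeric(fecund_age_band), c(15, 49)))
  structure(
    list(
      initial_population = initial_population,
      years = years,
      fertility_rate = stats::setNames(fert, years),
      mortality_rate = mort,
      net_migration = mig,
      entrants = entrants,
      fecund_age_band = c(15L, 49L),
      fecund_correction = fecund_correction
    ),
    class = "demography_inputs"
  )
}

# Normalize a grid / scalar / [year, age, sex] array to the canonical array.
as_year_array <- function(x, years, what) {
  ny <- length(years)
  dn <- list(year = years, age = CVDSIM_AGES, sex = CVDSIM_SEXES)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1L] != ny) stop(what, ": year dimension mismatch", call. = FALSE)
    dimnames(x) <- dn
    return(x)
  }
  g <- rate_grid(x)
  arr <- array(0, dim = c(ny, 83L, 2L), dimnames = dn)
  for (i in seq_len(ny)) arr[i, , ] <- g
  arr
}

# Extract the grid for one simulation year from a [year, age, sex] array.
year_slice <- function(arr, years, year) {
  i <- match(year, years)
  if (is.na(i)) stop("year ", year, " outside the input series range", call. = FALSE)
  m <- arr[i, , ]
  dimnames(m) <- list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)
  m
}

#' Annual births from the fecund female population
#'
#' @param fecund_women women of fecund age (persons), already corrected for the
#'   unmodelled 15-17 band.
#' @param fertility_rate births per fecund woman per year.
#' @return births per year (persons/yr).
#' @examples
#' births(100000, 0.05)  # 5000
#' @export
births <- function(fecund_women, fertility_rate) {
  if (any(fecund_women < 0) || any(fertility_rate < 0)) {
    stop("births: inputs must be non-negative", call. = FALSE)
  }
  fecund_women * fertility_rate
}

#' Fecund female population of a grid
#'
#' Women aged 18-49 scaled by the 15-17 correction factor.
#'
#' @param pop a `cohort_grid`.
#' @param correction multiplier approximating the unmodelled 15-17 ages.
#' @return persons.
#' @export
fecund_women <- function(pop, correction = 1) {
  sum(pop[as.character(18:49), "female"]) * correction
}

#' Advance the population grid one year
#'
#' Applies, in this fixed order: deaths, net migration, ageing with age-18
#' entry. Rates are annual fractions by default; with `hazard = TRUE` the
#' mortality entries are treated as instantaneous hazards and converted via
#' `1 - exp(-r)`.
#'
#' @param pop a `cohort_grid`.
#' @param inputs a `demography_inputs`.
#' @param year simulation year (must lie within `inputs$years`).
#' @param hazard interpret mortality as a hazard rather than a fraction.
#' @param detail if `TRUE` return a list with the flow totals alongside the
#'   next-year grid (used for conservation accounting).
#' @return the next-year `cohort_grid`, or a list when `detail = TRUE` with
#'   elements `population`, `deaths`, `migration`, `entrants`.
#' @export
step_demography <- function(pop, inputs, year, hazard = FALSE, detail = FALSE) {
  m <- year_slice(inputs$mortality_rate, inputs$years, year)
  if (hazard) m <- 1 - exp(-m)
  if (any(m < 0 | m > 1)) stop("mortality outside [0, 1]", call. = FALSE)
  mig <- year_slice(inputs$net_migration, inputs$years, year)
  deaths <- unclass(pop) * m
  after <- unclass(pop) - deaths + mig
  if (any(after < -1e-9)) {
    stop("net out-migration exceeds surviving population", call. = FALSE)
  }
  after[after < 0] <- 0
  entrants <- entrants_for_year(inputs, year, pop)
  nxt <- age_shift(as_cohort_grid(after), entrants)
  if (!detail) return(nxt)
  list(population = nxt, deaths = sum(deaths), migration = sum(mig),
       entrants = sum(entrants))
}

# Entrant cohort for a year; NULL entrants series = replacement of the current
# age-18 cohort.
entrants_for_year <- function(inputs, year, pop) {
  if (is.null(inputs$entrants)) {
    return(stats::setNames(as.numeric(pop["18", ]), CVDSIM_SEXES))
  }
  i <- match(year, inputs$years)
  if (is.na(i)) stop("year ", year, " outside the input series range", call. = FALSE)
  stats::setNames(as.numeric(inputs$entrants[i, ]), CVDSIM_SEXES)
}

#' Write demographic inputs as long-format CSV
#'
#' Columns `year, age, sex, variable, value`, covering initial_population
#' (at the first year), fertility_rate, mortality_rate, net_migration and, if
#' present, entrants.
#'
#' @param inputs a `demography_inputs`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_demography_csv <- function(inputs, path) {
  rows <- list()
  y0 <- inputs$years[1L]
  grid_rows <- function(g, year, variable) {
    data.frame(year = year, age = rep(CVDSIM_AGES, 2L),
               sex = rep(CVDSIM_SEXES, each = 83L),
               variable = variable, value = as.numeric(g))
  }
  rows[[1]] <- grid_rows(inputs$initial_population, y0, "initial_population")
  rows[[2]] <- data.frame(year = inputs$years, age = NA_integer_, sex = NA_character_,
                          variable = "fertility_rate",
                          value = as.numeric(inputs$fertility_rate))
  for (i in seq_along(inputs$years)) {
    yr <- inputs$years[i]
    rows[[length(rows) + 1L]] <- grid_rows(inputs$mortality_rate[i, , ], yr, "mortality_rate")
    rows[[length(rows) + 1L]] <- grid_rows(inputs$net_migration[i, , ], yr, "net_migration")
  }
  if (!is.null(inputs$entrants)) {
    rows[[length(rows) + 1L]] <- data.frame(
      year = rep(inputs$years, 2L), age = NA_integer_,
      sex = rep(CVDSIM_SEXES, each = length(inputs$years)),
      variable = "entrants", value = as.numeric(inputs$entrants))
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read demographic inputs from long-format CSV
#'
#' Inverse of [write_demography_csv()].
#'
#' @param path CSV path.
#' @param fecund_correction passed through to [demography_inputs()].
#' @return a `demography_inputs`.
#' @export
read_demography_csv <- function(path, fecund_correction = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "age", "sex", "variable", "value") %in% names(df)))
  years <- sort(unique(df$year[df$variable == "mortality_rate"]))
  pick_grid <- function(sub) {
    g <- matrix(0, 83L, 2L, dimnames = list(age = CVDSIM_AGES, sex = CVDSIM_SEXES))
    g[cbind(match(sub$age, CVDSIM_AGES), match(sub$sex, CVDSIM_SEXES))] <- sub$value
    g
  }
  init <- pick_grid(df[df$variable == "initial_population", ])
  fert <- df[df$variable == "fertility_rate", ]
  fert <- fert$value[match(years, fert$year)]
  arr_of <- function(variable) {
    arr <- array(0, dim = c(length(years), 83L, 2L),
                 dimnames = list(year = years, age = CVDSIM_AGES, sex = CVDSIM_SEXES))
    for (i in seq_along(years)) {
      arr[i, , ] <- pick_grid(df[df$variable == variable & df$year == years[i], ])
    }
    arr
  }
  ent <- NULL
  if (any(df$variable == "entrants")) {
    e <- df[df$variable == "entrants", ]
    ent <- matrix(0, length(years), 2L, dimnames = list(year = years, sex = CVDSIM_SEXES))
    ent[cbind(match(e$year, years), match(e$sex, CVDSIM_SEXES))] <- e$value
  }
  demography_inputs(
    initial_population = as_cohort_grid(init), years = years,
    fertility_rate = fert, mortality_rate = arr_of("mortality_rate"),
    net_migration = arr_of("net_migration"), entrants = ent,
    fecund_correction = fecund_correction
  )
}
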