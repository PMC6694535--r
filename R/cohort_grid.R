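#' @keywords internal
"_PACKAGE"

# Modelled age range: single-year cohorts 18..99 plus an open-ended 100+ class
# (represented by age label "100"). Sexes are always ordered female, male.
CVDSIM_AGES <- 18:100
CVDSIM_SEXES <- c("female", "male")

#' Age- and sex-structured population grid
#'
#' The universal population container of the simulator: a non-negative matrix
#' of person counts indexed by single year of age (18 to 100, where 100 stands
#' for the open-ended 100-and-older class) and sex (female, male).
#'
#' @param value a scalar, a vector recycled column-wise, or an 83 x 2 matrix of
#'   person counts.
#' @return an object of class `cohort_grid`: an 83 x 2 numeric matrix with
#'   dimnames `age` (18..100) and `sex` (female, male).
#' @examples
#' g <- cohort_grid(100)        # 100 persons in every age/sex cell
#' grid_total(g)
#' @export
cohort_grid <- function(value = 0) {
  m <- matrix(as.numeric(value),
    nrow = length(CVDSIM_AGES), ncol = length(CVDSIM_SEXES),
    dimnames = list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)
  )
  validate_cohort_grid(m)
  structure(m, class = c("cohort_grid", "matrix", "array"))
}

#' Coerce a matrix to a cohort grid
#'
#' @param x an 83 x 2 numeric matrix (ages 18..100 by female/male).
#' @return a `cohort_grid`.
#' @export
as_cohort_grid <- function(x) {
  if (inherits(x, "cohort_grid")) return(x)
  stopifnot(is.matrix(x), nrow(x) == length(CVDSIM_AGES), ncol(x) == 2L)
  dimnames(x) <- list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)
  validate_cohort_grid(x)
  structure(x, class = c("cohort_grid", "matrix", "array"))
}

validate_cohort_grid <- function(m, what = "cohort grid") {
  if (anyNA(m)) stop(what, " contains NA values", call. = FALSE)
  # tolerate floating-point dust from repeated flow arithmetic
  if (any(m < -1e-9)) stop(what, " has negative entries", call. = FALSE)
  invisible(m)
}

#' Total persons in a grid
#' @param g a `cohort_grid`.
#' @return total person count.
#' @export
grid_total <- function(g) sum(g)

#' Shift a population grid one year of age
#'
#' Every cohort moves up one year; the 100+ class is absorbing (persons ageing
#' into it accumulate there); `entrants` become the new age-18 cohort.
#'
#' @param g a `cohort_grid`.
#' @param entrants persons entering at age 18, length-2 numeric (female, male).
#' @return the aged `cohort_grid`.
#' @export
age_shift <- function(g, entrants = c(female = 0, male = 0)) {
  stopifnot(length(entrants) == 2L, all(entrants >= 0))
  n <- nrow(g)
  out <- unclass(g)
  out[2:n, ] <- g[1:(n - 1L), ]
  out[n, ] <- out[n, ] + g[n, ]   # 100+ absorbs
  out[1L, ] <- as.numeric(entrants)
  as_cohort_grid(out)
}

# Expand a scalar or per-sex named vector into a full grid-shaped matrix.
rate_grid <- function(r) {
  if (inherits(r, "cohort_grid") || (is.matrix(r) && all(dim(r) == c(83L, 2L)))) {
    return(unclass(r))
  }
  if (length(r) == 1L) {
    return(matrix(r, nrow = length(CVDSIM_AGES), ncol = 2L,
                  dimnames = list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)))
  }
  if (length(r) == 2L) {
    r <- r[CVDSIM_SEXES]
    if (anyNA(r)) stop("per-sex rates must be named female/male", call. = FALSE)
    return(matrix(rep(as.numeric(r), each = length(CVDSIM_AGES)), ncol = 2L,
                  dimnames = list(age = CVDSIM_AGES, sex = CVDSIM_SEXES)))
  }
  stop("rate must be a scalar, a named female/male pair, or a grid", call. = FALSE)
}
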