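dia_params <- function(...) {
  args <- utils::modifyList(list(
    incidence_rate = 0, regression_rate = 0,
    progression_rate_unmanaged = 0, progression_rate_managed = 0,
    uptake_rate = 0, treatment_mortality_effect = 0
  ), list(...))
  do.call(two_stage_params, args)
}

test_that("step_two_stage moves people along the declared flows", {
  # single active flow: incidence only
  s <- two_stage_stocks(healthy = 1000 / 166)   # 1000 persons spread over cells
  out <- step_two_stage(s, dia_params(incidence_rate = 0.1), mortality = 0)
  expect_equal(grid_total(out$healthy), 900)
  expect_equal(grid_total(out$pre_unmanaged), 100)

  # identity when all rates and mortality are zero
  s2 <- two_stage_stocks(healthy = 3, pre_unmanaged = 2, pre_managed = 1,
                         disease_unmanaged = 4, disease_managed = 5)
  out2 <- step_two_stage(s2, dia_params(), mortality = 0)
  for (nm in names(s2)) expect_equal(unclass(out2[[nm]]), unclass(s2[[nm]]))

  # simultaneous outflows from the published rates:
  # 100 * (1 - 0.0556 - 0.05 - 0.193) = 70.14
  s3 <- two_stage_stocks(healthy = 0, pre_unmanaged = 100 / 166)
  out3 <- step_two_stage(
    s3, dia_params(progression_rate_unmanaged = 0.0556, uptake_rate = 0.05,
                   regression_rate = 0.193),
    mortality = 0
  )
  expect_equal(grid_total(out3$pre_unmanaged), 70.14)
  expect_equal(grid_total(out3$pre_managed), 5)
  expect_equal(grid_total(out3$disease_unmanaged), 5.56)
  expect_equal(grid_total(out3$healthy), 19.3)
})

test_that("step_two_stage conserves persons up to deaths", {
  set.seed(1)
  p <- dia_params(incidence_rate = 0.03, regression_rate = 0.19,
                  progression_rate_unmanaged = c(female = 0.06, male = 0.08),
                  progression_rate_managed = NULL,
                  progression_effect_managed = 0.33,
                  uptake_rate = 0.05, treatment_mortality_effect = 0.13)
  s <- two_stage_stocks(
    healthy = matrix(runif(166, 0, 100), 83, 2),
    pre_unmanaged = matrix(runif(166, 0, 30), 83, 2),
    pre_managed = matrix(runif(166, 0, 30), 83, 2),
    disease_unmanaged = matrix(runif(166, 0, 20), 83, 2),
    disease_managed = matrix(runif(166, 0, 20), 83, 2)
  )
  m <- matrix(runif(166, 0, 0.1), 83, 2)
  out <- step_two_stage(s, p, m)
  expect_equal(grid_total(stocks_total(out)),
               grid_total(stocks_total(s)) - attr(out, "deaths"),
               tolerance = 1e-12)
  expect_true(all(stocks_total(out) >= 0))
})

test_that("oversized combined outflows error by default and clamp on request", {
  s <- two_stage_stocks(healthy = 0, pre_unmanaged = 10)
  p <- dia_params(progression_rate_unmanaged = 0.6, uptake_rate = 0.3,
                  regression_rate = 0.3)
  expect_error(step_two_stage(s, p, mortality = 0), "outflows")
  expect_warning(step_two_stage(s, p, mortality = 0, on_negative = "clamp"),
                 "scaled down")
  out <- suppressWarnings(step_two_stage(s, p, mortality = 0, on_negative = "clamp"))
  expect_equal(grid_total(out$pre_unmanaged), 0, tolerance = 1e-9)
  expect_equal(grid_total(stocks_total(out)), grid_total(stocks_total(s)))
})

test_that("step_smoking applies cessation, relapse and entrants", {
  sp <- smoking_params(initiation_rate = 0, cessation_rate = 0.162, relapse_rate = 0)
  s <- smoking_stocks(never = 0, current = 100 / 166)
  out <- step_smoking(s, sp, mortality = 0)
  expect_equal(grid_total(out$current), 83.8)
  expect_equal(grid_total(out$former), 16.2)

  # rates zero: unchanged except entrants join the never stock at age 18
  s2 <- smoking_stocks(never = 5, current = 3, former = 2)
  out2 <- step_smoking(s2, smoking_params(0, 0, 0), mortality = 0,
                       new_18_entrants = c(female = 7, male = 9))
  expect_equal(unname(out2$never["18", ]), c(12, 14))
  expect_equal(grid_total(out2$current), grid_total(s2$current))
  expect_equal(grid_total(out2$former), grid_total(s2$former))

  # relapse moves 10% of former smokers back
  s3 <- smoking_stocks(never = 0, current = 0, former = 50 / 166)
  out3 <- step_smoking(s3, smoking_params(0, 0, relapse_rate = 0.1), mortality = 0)
  expect_equal(grid_total(out3$current), 5)
  expect_equal(grid_total(out3$former), 45)
})

test_that("prevalence pools correctly and flags empty cohorts", {
  s <- two_stage_stocks(healthy = 900 / 166, disease_unmanaged = 100 / 166)
  p <- prevalence(s, "disease")
  expect_equal(p$aggregate, 0.1)

  # 3-cohort toy: (10/100, 20/200, 0/0) -> aggregate 30/300
  g_tot <- matrix(0, 83, 2); g_dis <- matrix(0, 83, 2)
  g_tot[c(1, 10), 1] <- c(100, 200); g_dis[c(1, 10), 1] <- c(10, 20)
  g_tot[20, 1] <- 0
  s2 <- two_stage_stocks(healthy = g_tot - g_dis, disease_unmanaged = g_dis)
  p2 <- prevalence(s2, "disease")
  expect_equal(p2$aggregate, 0.1)
  expect_equal(p2$cell[1, 1], 0.1)
  expect_true(is.na(p2$cell[20, 1]))   # empty cohort flagged missing

  empty <- two_stage_stocks(healthy = 0)
  expect_true(is.na(prevalence(empty, "disease")$aggregate))
})

test_that("raising uptake never decreases the managed share", {
  p0 <- dia_params(incidence_rate = 0.03, regression_rate = 0.19,
                   progression_rate_unmanaged = 0.06,
                   progression_rate_managed = 0.013, uptake_rate = 0.05)
  s0 <- two_stage_stocks(healthy = 70, pre_unmanaged = 10, pre_managed = 5,
                         disease_unmanaged = 8, disease_managed = 7)
  shares <- sapply(c(0.05, 0.1, 0.2), function(u) {
    p <- dia_params(incidence_rate = 0.03, regression_rate = 0.19,
                    progression_rate_unmanaged = 0.06,
                    progression_rate_managed = 0.013, uptake_rate = u)
    s <- s0
    for (k in 1:15) s <- step_two_stage(s, p, mortality = 0.01)
    managed_share(s)$aggregate
  })
  expect_true(all(diff(shares) >= 0))
})

test_that("with no mortality benefit, the managed/unmanaged split is inert (merge test)", {
  # equal progression rates and zero treatment mortality effect: the
  # per-stage totals must evolve as if the split did not exist
  p <- dia_params(incidence_rate = 0.02, regression_rate = 0.1,
                  progression_rate_unmanaged = 0.05,
                  progression_rate_managed = 0.05,
                  uptake_rate = 0.07, treatment_mortality_effect = 0)
  split <- two_stage_stocks(healthy = 50, pre_unmanaged = 12, pre_managed = 8,
                            disease_unmanaged = 6, disease_managed = 4)
  merged <- two_stage_stocks(healthy = 50, pre_unmanaged = 20, pre_managed = 0,
                             disease_unmanaged = 10, disease_managed = 0)
  for (k in 1:10) {
    split <- step_two_stage(split, p, mortality = 0.02)
    merged <- step_two_stage(merged, p, mortality = 0.02)
  }
  pre <- function(s) unclass(s$pre_unmanaged) + unclass(s$pre_managed)
  dis <- function(s) unclass(s$disease_unmanaged) + unclass(s$disease_managed)
  expect_equal(unclass(split$healthy), unclass(merged$healthy), tolerance = 1e-12)
  expect_equal(pre(split), pre(merged), tolerance = 1e-12)
  expect_equal(dis(split), dis(merged), tolerance = 1e-12)
})

test_that("smoking shares converge to the analytic stationary distribution", {
  # closed cohort, no deaths, no never-smokers: the current/former sub-chain
  # has stationary current share relapse / (relapse + cessation)
  ces <- 0.162; rel <- 0.1
  sp <- smoking_params(initiation_rate = 0, cessation_rate = ces, relapse_rate = rel)
  s <- smoking_stocks(never = 0, current = 1000 / 166, former = 0)
  for (k in 1:80) s <- step_smoking(s, sp, mortality = 0)
  cur_share <- grid_total(s$current) /
    (grid_total(s$current) + grid_total(s$former))
  expect_equal(cur_share, rel / (rel + ces), tolerance = 1e-6)
})
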