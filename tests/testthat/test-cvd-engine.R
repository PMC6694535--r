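test_that("independence partition multiplies marginals", {
  sh <- partition_risk_groups(0.2, 0.5, 0.1)
  expect_equal(sh["DHS", 1, 1], 0.2 * 0.5 * 0.1)
  expect_equal(sh["none", 1, 1], 0.8 * 0.5 * 0.9)
  expect_equal(sh["DH", 1, 1], 0.2 * 0.5 * 0.9)
  expect_equal(unname(apply(sh, c(2, 3), sum)), matrix(1, 83, 2))

  # a zero prevalence empties every group containing that factor
  sh0 <- partition_risk_groups(0, 0.5, 0.1)
  expect_equal(max(abs(sh0[c("D", "DH", "DS", "DHS"), , ])), 0)

  # degenerate all-ones
  sh1 <- partition_risk_groups(1, 1, 1)
  expect_equal(sh1["DHS", 1, 1], 1)
  expect_equal(sum(sh1[setdiff(risk_groups(), "DHS"), , ]), 0)

  expect_error(partition_risk_groups(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("even-split partition reconciles to the marginals", {
  sh <- partition_risk_groups(0.2, 0.5, 0.1, mode = "even_split")
  mem <- sapply(c("D", "H", "S"), function(f) grepl(f, risk_groups()))
  expect_equal(sum(sh[mem[, "D"], 1, 1]), 0.2, tolerance = 1e-9)
  expect_equal(sum(sh[mem[, "H"], 1, 1]), 0.5, tolerance = 1e-9)
  expect_equal(sum(sh[mem[, "S"], 1, 1]), 0.1, tolerance = 1e-9)
  expect_equal(sum(sh[, 1, 1]), 1, tolerance = 1e-9)
})

test_that("cvd_probability evaluates the logistic risk equations", {
  params <- default_engine_params()
  zero <- risk_engine_params(
    beta0 = setNames(rep(0, 8), risk_groups()),
    beta_age = c(female = 0, male = 0), beta_diabetes = c(female = 0, male = 0),
    beta_hypertension = c(female = 0, male = 0), beta_smoking = c(female = 0, male = 0),
    rr_treated_diabetes = 1, rr_treated_hypertension = 1, rr_treated_smoking = 1,
    event_death_rate = 0, rr_death_post_cvd = 1,
    treatment_mortality_effect = 0, fraction_post_cvd_treated = 0
  )
  expect_equal(cvd_probability("none", 40, "female", zero), 0.5)
  expect_equal(cvd_probability("DHS", 90, "male", zero), 0.5)

  # no-risk-factor female aged 80 under the packaged coefficients
  expect_equal(cvd_probability("none", 80, "female", params),
               1 / (1 + exp(-(-11.968 + 0.0699 * 80))), tolerance = 1e-12)
  # frozen from an independent evaluation of 1/(1 + e^6.376)
  expect_equal(cvd_probability("none", 80, "female", params), 0.0016990254,
               tolerance = 1e-7)

  # diabetic-only male aged 60
  expect_equal(cvd_probability("D", 60, "male", params),
               1 / (1 + exp(2.25603)), tolerance = 1e-10)
  expect_equal(cvd_probability("D", 60, "male", params), 0.0948, tolerance = 1e-3)
})

test_that("cvd_probability is bounded and monotone in age", {
  params <- default_engine_params()
  for (g in risk_groups()) {
    p <- cvd_probability(g, 18:100, rep("male", 83), params)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(diff(p) > 0))   # beta_age > 0
  }
})

test_that("adjusted_probability honours its limits and ordering", {
  expect_equal(adjusted_probability(0.1, 0, 0.8), 0.1)
  expect_equal(adjusted_probability(0.1, 1, 0.8), 0.08)
  expect_equal(adjusted_probability(0.1, 0.5, 0.5), 0.075)
  expect_error(adjusted_probability(1.5, 0, 1), "\\[0, 1\\]")
  expect_error(adjusted_probability(0.1, 0.5, 0), "\\(0, 1\\]")

  # AP <= p with equality iff coverage 0 or rr 1
  set.seed(3)
  p <- runif(50); cov <- runif(50); rr <- runif(50, 0.01, 1)
  ap <- adjusted_probability(p, cov, rr)
  expect_true(all(ap <= p + 1e-15))
  eq <- abs(ap - p) < 1e-15
  expect_true(all(eq == (cov < 1e-15 | abs(rr - 1) < 1e-15 | p < 1e-15)))
})

test_that("compute_events multiplies and sums", {
  pop <- array(0, dim = c(8, 83, 2)); p <- array(0, dim = c(8, 83, 2))
  pop[1, 1, 1] <- 10000; p[1, 1, 1] <- 0.01
  expect_equal(sum(compute_events(pop, p)), 100)
  expect_equal(sum(compute_events(pop * 0, p)), 0)
  pop[2, 5, 2] <- 1000; p[2, 5, 2] <- 0.02
  pop[3, 9, 1] <- 500; p[3, 9, 1] <- 0.04
  expect_equal(sum(compute_events(pop, p)), 100 + 20 + 20)
})

test_that("update_post_cvd books events, deaths and survivors", {
  params <- default_engine_params()
  st <- cvd_state(post_cvd = 0)
  ev <- matrix(0, 83, 2); ev[40, 1] <- 100
  out <- update_post_cvd(st, ev, params, mortality = 0)
  expect_equal(out$annual_event_deaths, 20)      # fatality 0.2
  expect_equal(grid_total(out$post_cvd), 80)

  # zero fatality: the stock grows by all events
  p0 <- default_engine_params(config_set(default_config(), "cvd.event_death_rate", 0))
  out0 <- update_post_cvd(st, ev, p0, mortality = 0)
  expect_equal(grid_total(out0$post_cvd), 100)

  # chained mortality multipliers: 1000 * 0.01 * 1.6 * (1 - 0.13) = 13.92
  st1 <- cvd_state(post_cvd = 1000 / 166)
  out1 <- update_post_cvd(st1, 0, params, mortality = 0.01)
  expect_equal(out1$annual_post_cvd_deaths, 13.92, tolerance = 1e-9)
})

test_that("post-CVD stock telescopes over a long run", {
  fx <- get_fixture()
  res <- get_base_result()
  # post_cvd(t+1) = post_cvd(t) + survivors(t) - post_cvd_deaths(t)
  survivors <- res$events - res$cvd_deaths
  recon <- res$post_cvd[1] + cumsum(survivors - res$post_cvd_deaths)
  expect_equal(res$post_cvd[-1], recon[-length(recon)],
               tolerance = 1e-9)
})

test_that("age standardization weights rates by the standard population", {
  ev <- matrix(0, 83, 2); pop <- matrix(0, 83, 2); std <- matrix(0, 83, 2)
  # uniform rate is invariant to the standard
  pop[, ] <- 100; ev[, ] <- 1; std[, ] <- runif(166, 1, 10)
  expect_equal(age_adjusted_incidence(ev, pop, std), 0.01)

  # two cells, equal weights -> plain average
  ev2 <- matrix(0, 83, 2); pop2 <- matrix(0, 83, 2); std2 <- matrix(0, 83, 2)
  pop2[1:2, 1] <- 100; ev2[1:2, 1] <- c(1, 3); std2[1:2, 1] <- 1
  expect_equal(age_adjusted_incidence(ev2, pop2, std2), 0.02)

  # weights 0.75/0.25
  std2[1:2, 1] <- c(3, 1)
  expect_equal(age_adjusted_incidence(ev2, pop2, std2), 0.015)

  # empty population cells are excluded with a warning
  std2[3, 1] <- 1
  expect_warning(age_adjusted_incidence(ev2, pop2, std2), "excluded")
})

test_that("group risk multipliers compose per managed factor", {
  cfg <- default_config()
  cfg$modes$eq10_literal <- FALSE   # multiplier = RR directly
  fx <- get_fixture()
  st <- fx$state
  # build engine quantities through the public step and through scalars below
  p <- default_engine_params(cfg)
  cov_d <- 0.4; cov_h <- 0.3; cov_s <- 0.2
  m <- cvdsim:::group_risk_multiplier(cov_d, cov_h, cov_s, 0.8, 0.5, 0.5)
  expect_equal(m["none", 1, 1], 1)
  expect_equal(m["D", 1, 1], 1 - 0.4 + 0.4 * 0.8)
  expect_equal(m["DHS", 1, 1],
               (1 - 0.4 + 0.4 * 0.8) * (1 - 0.3 + 0.3 * 0.5) * (1 - 0.2 + 0.2 * 0.5))
})
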