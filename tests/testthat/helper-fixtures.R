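# Shared fixtures, memoized: several test files need the same synthetic
# population and its calibrated configuration.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(scale = 1, horizon = c(2010, 2040)) {
  key <- paste0("fx_", scale, "_", horizon[1], "_", horizon[2])
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_singapore_like_fixture(scale = scale,
                                                         horizon = horizon)
  }
  .fixture_cache[[key]]
}

get_base_result <- function() {
  if (is.null(.fixture_cache$base_result)) {
    fx <- get_fixture()
    .fixture_cache$base_result <- run_scenario(preset_scenario("base"),
                                               fx$inputs, fx$state, fx$config)
  }
  .fixture_cache$base_result
}

# A grid with three occupied cells, small enough for per-person oracles.
toy_grid <- function(counts = c(1000, 800, 500)) {
  g <- matrix(0, 83, 2)
  g[match(50, 18:100), 1] <- counts[1]   # female 50
  g[match(60, 18:100), 2] <- counts[2]   # male 60
  g[match(80, 18:100), 1] <- counts[3]   # female 80
  as_cohort_grid(g)
}

# Constant-mortality demography over an arbitrary horizon.
toy_inputs <- function(pop, years, mortality = 0.01, migration = 0,
                       entrants = NULL, fertility = 0.03) {
  demography_inputs(
    initial_population = pop, years = years, fertility_rate = fertility,
    mortality_rate = mortality, net_migration = migration, entrants = entrants
  )
}
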