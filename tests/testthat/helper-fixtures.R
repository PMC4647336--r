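# Shared fixtures, computed lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, .fixture_cache, inherits = FALSE))
    assign(name, compute(), .fixture_cache)
  get(name, .fixture_cache, inherits = FALSE)
}

# default-scale simulation (n = 5000, seed 1) and its GP fit, reused by the
# recovery, invariance and acceptance tests
sim5000 <- function() fixture("sim5000", function()
  simulate_districts(generator_config(n_districts = 5000, seed = 1)))

fit5000_gp <- function() fixture("fit5000_gp", function() {
  sim <- sim5000()
  ztnb_fit(build_design(sim$table, sim$truth$spec_gp))
})

# compact three-column world: pop_density (strong), city (strong), plus an
# optional null covariate; 3 regions. Used for coverage / selection
# replicates where hundreds of fits must stay cheap.
compact_truth <- c("(Intercept)" = 1.9, pop_density = 0.3, city = 0.15,
                   regionR02 = 0.125, regionR03 = 0.25)

simulate_compact <- function(n, seed, sigma = 0.05, with_null = FALSE,
                             null_beta = 0) {
  specs <- default_covariate_specs()
  use <- c("pop_density", "city", if (with_null) "gdp_per_capita")
  cov <- draw_covariates(specs[use], n, seed = seed)
  region <- assign_regions(n, 3L, seed = seed + 1L)
  ia <- draw_inhabitants(cov$pop_density, seed = seed + 2L)
  tab <- cbind(data.frame(region = region, inhabitants = ia$inhabitants,
                          area = ia$area), cov)
  metric <- c("pop_density", if (with_null) "gdp_per_capita")
  truth <- compact_truth
  if (with_null) truth <- c(truth, gdp_per_capita = null_beta)
  spec_gp <- model_spec("gp_count", "population", metric = metric,
                        binary = "city", ref_region = "R01")
  spec_sp <- model_spec("sp_count", "population", metric = metric,
                        binary = "city", ref_region = "R01")
  tab$gp_count <- simulate_counts(tab, spec_gp, truth, sigma,
                                  seed = seed + 3L)
  sp_truth <- truth
  sp_truth["(Intercept)"] <- 1.5
  tab$sp_count <- simulate_counts(tab, spec_sp, sp_truth, sigma,
                                  seed = seed + 4L)
  list(table = tab, truth = truth, sp_truth = sp_truth, spec = spec_gp,
       spec_sp = spec_sp, sigma = sigma)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
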