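# ---------------------------------------------------------------------------
# Seeded synthetic district tables: covariates emulating the published
# district-level summary distributions (412 districts, 17 ASHIP regions),
# inhabitants/area consistent with the population-density column, and
# GP/specialist counts drawn from the zero-truncated negative-binomial
# model with a log population offset.
# ---------------------------------------------------------------------------

# run expr with a private, seeded RNG stream; global RNG state untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Covariate specification
#'
#' Distributional summary of one district-level variable: metric variables
#' carry mean/SD/min/max (interpreted as the parent parameters and the
#' truncation bounds of a truncated normal), binary variables carry a
#' frequency.
#'
#' @param name column name.
#' @param kind `"metric"` or `"binary"`.
#' @param mean,sd,min,max metric summaries (units as labelled); `sd > 0` and
#'   `min <= mean <= max`.
#' @param frequency binary frequency in `[0, 1]`.
#' @param label human-readable description.
#' @param in_model whether the variable belongs to the default count model
#'   (the remaining summary variables are generated but carry no effect).
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("metric", "binary"), mean = NULL,
                           sd = NULL, min = NULL, max = NULL,
                           frequency = NULL, label = name, in_model = FALSE) {
  kind <- match.arg(kind)
  if (kind == "metric") {
    if (is.null(mean) || is.null(sd) || is.null(min) || is.null(max))
      stop_domain("metric spec '", name, "' needs mean, sd, min, max")
    if (sd <= 0) stop_domain("spec '", name, "': sd must be positive")
    if (min > mean || mean > max)
      stop_domain("spec '", name, "': need min <= mean <= max")
  } else {
    if (is.null(frequency) || frequency < 0 || frequency > 1)
      stop_domain("binary spec '", name, "' needs frequency in [0, 1]")
  }
  structure(list(name = name, kind = kind, mean = mean, sd = sd, min = min,
                 max = max, frequency = frequency, label = label,
                 in_model = in_model), class = "covariate_spec")
}

#' Default district covariate specifications
#'
#' One specification per published district-level summary row (n = 412
#' districts): metric variables with mean, standard deviation, minimum and
#' maximum, and binary variables with their observed frequencies. Variables
#' retained in the final published count models are flagged `in_model`; the
#' others (morbidity proxies, GDP, nursing beds, several travel times, ...)
#' are generated but carry no effect in the default simulation, mirroring
#' their dropping out of the final models.
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  m <- function(name, mean, sd, min, max, label, in_model = FALSE)
    covariate_spec(name, "metric", mean = mean, sd = sd, min = min,
                   max = max, label = label, in_model = in_model)
  b <- function(name, frequency, label, in_model = FALSE)
    covariate_spec(name, "binary", frequency = frequency, label = label,
                   in_model = in_model)
  specs <- list(
    m("pop_density", 518.68, 674.91, 37.09, 4355.28,
      "Population density (per km2)", TRUE),
    m("old_age_dependency", 32.14, 4.22, 22.03, 45.53,
      "Old-age dependency ratio"),
    m("life_exp_women", 25.08, 0.63, 23.10, 27.10,
      "Life-expectancy women (from 60 years)"),
    m("life_exp_men", 21.56, 0.94, 19.40, 24.60,
      "Life-expectancy men (from 60 years)"),
    m("mortality", 10.91, 1.59, 6.90, 15.40,
      "Mortality (deaths per 1000 inhabitants)"),
    m("household_income", 1548.93, 199.31, 1157.90, 2585.00,
      "Household income (EUR per month)", TRUE),
    m("privately_insured", 13.46, 4.32, 3.53, 27.00,
      "Rate of privately insured persons (%)", TRUE),
    m("hospital_beds", 64.49, 38.70, 0.00, 215.90,
      "Hospital beds (per 10 000 inhabitants)", TRUE),
    m("nursing_beds", 108.94, 28.83, 47.10, 256.60,
      "Nursing home beds (per 10 000 inhabitants)"),
    m("middle_order_centers", 2.24, 2.16, 0.00, 11.00,
      "Number of middle-order centers", TRUE),
    m("high_order_centers", 0.39, 0.56, 0.00, 4.00,
      "Number of high-order centers", TRUE),
    m("unemployment", 7.41, 3.31, 1.90, 17.40,
      "Unemployment rate (%)", TRUE),
    m("highly_qualified", 8.23, 3.80, 3.00, 26.50,
      "Rate of highly qualified workers (%)", TRUE),
    m("gdp_per_capita", 27.58, 10.24, 13.20, 83.60,
      "GDP per capita (EUR 1000)"),
    m("touristic_attractiveness", 5.27, 7.56, 0.00, 90.60,
      "Touristic attractiveness (guest-nights per capita)", TRUE),
    m("building_area_attractiveness", 125.47, 117.34, 0.00, 1031.80,
      "Building area attractiveness"),
    m("migration_balance_10y", 4.54, 46.13, -171.40, 100.30,
      "Migration balance (last 10 years)"),
    m("migration_balance_5y", -3.98, 21.85, -69.80, 61.80,
      "Migration balance (last 5 years)", TRUE),
    m("travel_time_airport", 54.41, 24.11, 7.60, 161.50,
      "Travel time to nearest airport (min)", TRUE),
    m("travel_time_train", 22.36, 14.42, 0.00, 61.60,
      "Travel time to high-speed train station (min)"),
    m("travel_time_middle_center", 8.26, 6.40, 0.00, 36.60,
      "Travel time to middle-order center (min)", TRUE),
    m("travel_time_high_center", 26.56, 17.83, 0.00, 76.20,
      "Travel time to high-order center (min)"),
    b("state_capital", 16 / 412, "State capital in district", TRUE),
    b("city", 68 / 412, "City >100 000 inhabitants in district", TRUE),
    b("university_hospital", 33 / 412, "University hospital in district"),
    b("east_germany", 86 / 412, "District in former East Germany"),
    b("urban_district", 206 / 412, "Urban district"))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

# truncated-normal mean and sd for a parent N(mean, sd) on [min, max]
truncnorm_moments <- function(spec) {
  a <- (spec$min - spec$mean) / spec$sd
  b <- (spec$max - spec$mean) / spec$sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  mu <- spec$mean + spec$sd * (da - db) / Z
  v <- spec$sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = mu, sd = sqrt(v))
}

#' Draw district covariate columns
#'
#' Metric variables are drawn from a normal distribution truncated to the
#' spec's `[min, max]` with the spec's mean/SD as parent parameters (exact
#' inverse-CDF sampling); binaries are Bernoulli draws. Covariates are
#' independent by default; an optional Gaussian-copula mode imposes a
#' user-supplied correlation among the metric variables.
#'
#' @param specs list of [covariate_spec()] objects.
#' @param n number of districts.
#' @param seed RNG seed (draws are deterministic given the seed).
#' @param correlation optional correlation matrix over (a subset of) the
#'   metric variables, applied through a Gaussian copula.
#' @return A data.frame with one column per spec.
#' @export
draw_covariates <- function(specs, n, seed = NULL, correlation = NULL) {
  if (n < 1) stop_domain("n must be >= 1")
  with_seed(seed, {
    cols <- lapply(specs, function(sp) {
      if (sp$kind == "binary") return(stats::rbinom(n, 1L, sp$frequency))
      lo <- stats::pnorm(sp$min, sp$mean, sp$sd)
      hi <- stats::pnorm(sp$max, sp$mean, sp$sd)
      if (hi <= lo)
        stop_domain("spec '", sp$name, "': truncation bounds leave no mass")
      stats::qnorm(lo + stats::runif(n) * (hi - lo), sp$mean, sp$sd)
    })
    out <- as.data.frame(cols, optional = TRUE)
    names(out) <- vapply(specs, `[[`, "", "name")
    if (!is.null(correlation)) {
      vars <- colnames(correlation)
      if (is.null(vars) || !all(vars %in% names(out)))
        stop_domain("correlation matrix must name metric covariates")
      R <- chol(correlation)
      z <- matrix(stats::rnorm(n * length(vars)), n) %*% R
      u <- stats::pnorm(z)
      for (j in seq_along(vars)) {
        sp <- specs[[vars[j]]]
        if (sp$kind != "metric")
          stop_domain("copula mode applies to metric covariates only")
        lo <- stats::pnorm(sp$min, sp$mean, sp$sd)
        hi <- stats::pnorm(sp$max, sp$mean, sp$sd)
        out[[vars[j]]] <- stats::qnorm(lo + u[, j] * (hi - lo), sp$mean,
                                       sp$sd)
      }
    }
    out
  })
}

#' Assign districts to ASHIP regions
#'
#' Every region receives at least one district (one each, then the rest
#' uniformly at random); the assignment is shuffled but deterministic given
#' the seed. Labels are `"R01" ... "Rkk"`.
#'
#' @param n_districts,n_regions counts with `n_districts >= n_regions >= 1`.
#' @param seed RNG seed.
#' @return Character vector of region labels, length `n_districts`.
#' @export
assign_regions <- function(n_districts, n_regions, seed = NULL) {
  if (n_regions < 1 || n_districts < n_regions)
    stop_domain("need n_districts >= n_regions >= 1")
  with_seed(seed, {
    idx <- c(seq_len(n_regions),
             if (n_districts > n_regions)
               sample.int(n_regions, n_districts - n_regions, replace = TRUE))
    sprintf("R%02d", sample(idx))
  })
}

#' Draw inhabitants and derive district areas
#'
#' Inhabitants are drawn from a log-normal distribution (median and log-SD
#' as configured) truncated to plausible German district sizes and rounded
#' to whole persons; the district area is then derived as
#' inhabitants/density so the population-density column stays exact. The
#' inhabitants distribution itself is a synthetic choice (the published
#' summaries do not report it).
#'
#' @param density positive vector of population densities (per km^2).
#' @param seed RNG seed.
#' @param median,sdlog,min,max log-normal parameters and truncation bounds.
#' @return data.frame with integer `inhabitants` and `area` columns.
#' @export
draw_inhabitants <- function(density, seed = NULL, median = 150000,
                             sdlog = 0.8, min = 35000, max = 3500000) {
  if (any(density <= 0)) stop_domain("density must be positive")
  if (min <= 0 || max <= min || median <= min || median >= max)
    stop_domain("need 0 < min < median < max")
  with_seed(seed, {
    meanlog <- log(median)
    lo <- stats::plnorm(min, meanlog, sdlog)
    hi <- stats::plnorm(max, meanlog, sdlog)
    inh <- round(stats::qlnorm(lo + stats::runif(length(density)) * (hi - lo),
                               meanlog, sdlog))
    data.frame(inhabitants = as.integer(inh), area = inh / density)
  })
}

#' Simulate zero-truncated negative-binomial physician counts
#'
#' For each district the untruncated mean is
#' `mu = exp(region intercept + X beta + log(inhabitants/10^4))` with the
#' design built exactly as at fit time ([build_design()]); counts are drawn
#' from the negative binomial with variance `mu + sigma mu^2` and zeros are
#' rejected and redrawn, so every count is at least 1.
#'
#' @param table district data.frame (covariates, region, inhabitants).
#' @param spec a [model_spec()] describing the design to build.
#' @param coefficients named vector covering every design column.
#' @param sigma dispersion (`> 0`); variance is `mu + sigma mu^2`.
#' @param seed RNG seed.
#' @return Integer vector of counts (`>= 1`), with attribute `mu`.
#' @export
simulate_counts <- function(table, spec, coefficients, sigma, seed = NULL) {
  if (sigma <= 0) stop_domain("sigma must be positive")
  d <- build_design(table, spec, allow_missing_response = TRUE)
  miss <- setdiff(colnames(d$X), names(coefficients))
  if (length(miss))
    stop_domain("coefficients missing for design columns: ",
                paste(miss, collapse = ", "))
  beta <- coefficients[colnames(d$X)]
  eta <- drop(d$X %*% beta) + d$offset
  mu <- exp(eta)
  if (any(!is.finite(mu)) || any(mu > 1e7)) {
    j <- which.max(abs(eta))
    stop_domain("mean overflow at row ", j, " (eta = ", format(eta[j]),
                "); check coefficient '",
                colnames(d$X)[which.max(abs(d$X[j, ] * beta))], "'")
  }
  with_seed(seed, {
    y <- stats::rnbinom(length(mu), size = 1 / sigma, mu = mu)
    for (i in 1:1000) {
      z <- which(y == 0L)
      if (!length(z)) break
      y[z] <- stats::rnbinom(length(z), size = 1 / sigma, mu = mu[z])
    }
    if (any(y == 0L))
      stop_domain("zero-truncation rejection failed to terminate ",
                  "(means too close to zero)")
    structure(as.integer(y), mu = mu)
  })
}

#' Default true coefficients for the synthetic count models
#'
#' Published final-model estimates used as ground-truth effects for the
#' two-SD-scaled covariates, binaries and the population-density-by-city
#' interaction of the GP and specialist models. Region intercept offsets
#' (relative to the reference region `R01`) are equally spaced on
#' `[0, 0.25]`.
#'
#' @param model `"gp"` or `"sp"`.
#' @param n_regions number of ASHIP regions.
#' @return Named coefficient vector over the default design columns.
#' @export
default_true_coefficients <- function(model = c("gp", "sp"),
                                      n_regions = 17) {
  model <- match.arg(model)
  core <- if (model == "gp") c(
    "(Intercept)" = 1.736, pop_density = -0.136, household_income = 0.018,
    privately_insured = 0.042, hospital_beds = 0.073,
    middle_order_centers = -0.005, high_order_centers = 0.036,
    city = -0.021, state_capital = 0.127, highly_qualified = 0.019,
    unemployment = 0.052, touristic_attractiveness = 0.046,
    migration_balance_5y = -0.012, travel_time_airport = 0.049,
    travel_time_middle_center = -0.064, "pop_density:city" = 0.099)
  else c(
    "(Intercept)" = 1.919, pop_density = 0.349, household_income = 0.093,
    privately_insured = 0.123, hospital_beds = 0.253,
    middle_order_centers = -0.074, high_order_centers = 0.057,
    city = 0.146, state_capital = 0.278, highly_qualified = 0.106,
    unemployment = 0.139, touristic_attractiveness = -0.004,
    migration_balance_5y = 0.072, travel_time_airport = 0.021,
    travel_time_middle_center = -0.177, "pop_density:city" = -0.422)
  reg <- seq(0, 0.25, length.out = n_regions)[-1]
  names(reg) <- sprintf("regionR%02d", seq_len(n_regions)[-1])
  c(core, reg)
}

#' Generator configuration
#'
#' Everything needed to generate one synthetic district table: size, region
#' count, seed, covariate specs, true coefficients and dispersion per count
#' model, and the inhabitants distribution.
#'
#' @param n_districts,n_regions table dimensions (defaults 412 and 17).
#' @param seed RNG seed driving all draws.
#' @param specs covariate specs, default [default_covariate_specs()].
#' @param coef_gp,coef_sp named true-coefficient vectors.
#' @param sigma_gp,sigma_sp dispersions of the count models.
#' @param inhabitants list of log-normal parameters for
#'   [draw_inhabitants()].
#' @param correlation optional metric-covariate correlation matrix.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_districts = 412, n_regions = 17, seed = 1,
                             specs = default_covariate_specs(),
                             coef_gp = default_true_coefficients("gp",
                                                                 n_regions),
                             coef_sp = default_true_coefficients("sp",
                                                                 n_regions),
                             sigma_gp = 0.05, sigma_sp = 0.05,
                             inhabitants = list(median = 150000, sdlog = 0.8,
                                                min = 35000, max = 3500000),
                             correlation = NULL) {
  if (n_regions < 1 || n_districts < n_regions)
    stop_domain("need n_districts >= n_regions >= 1")
  if (sigma_gp <= 0 || sigma_sp <= 0) stop_domain("dispersion must be > 0")
  structure(list(n_districts = n_districts, n_regions = n_regions,
                 seed = seed, specs = specs, coef_gp = coef_gp,
                 coef_sp = coef_sp, sigma_gp = sigma_gp,
                 sigma_sp = sigma_sp, inhabitants = inhabitants,
                 correlation = correlation), class = "generator_config")
}

#' Generate a synthetic district table
#'
#' End-to-end generator: covariates, region labels, inhabitants/area, and
#' GP/specialist counts from the zero-truncated negative-binomial models.
#' Deterministic given the config (sub-draws use seeds derived from
#' `config$seed`).
#'
#' @param config a [generator_config()].
#' @return List with `table` (the district data.frame) and `truth` (true
#'   coefficients, dispersions and the model specs used).
#' @export
simulate_districts <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_districts
  seed <- as.integer(config$seed) %% 1000000L
  cov <- draw_covariates(config$specs, n, seed = seed * 7L + 1L,
                         correlation = config$correlation)
  region <- assign_regions(n, config$n_regions, seed = seed * 7L + 2L)
  ia <- draw_inhabitants(cov$pop_density, seed = seed * 7L + 3L,
                         median = config$inhabitants$median,
                         sdlog = config$inhabitants$sdlog,
                         min = config$inhabitants$min,
                         max = config$inhabitants$max)
  tab <- cbind(data.frame(district_id = sprintf("D%04d", seq_len(n)),
                          region = region, inhabitants = ia$inhabitants,
                          area = ia$area, stringsAsFactors = FALSE), cov)
  spec_gp <- default_model_spec("gp", ref_region = "R01")
  spec_sp <- default_model_spec("sp", ref_region = "R01")
  tab$gp_count <- simulate_counts(tab, spec_gp, config$coef_gp,
                                  config$sigma_gp, seed = seed * 7L + 4L)
  tab$sp_count <- simulate_counts(tab, spec_sp, config$coef_sp,
                                  config$sigma_sp, seed = seed * 7L + 5L)
  list(table = tab,
       truth = list(coef_gp = config$coef_gp, coef_sp = config$coef_sp,
                    sigma_gp = config$sigma_gp, sigma_sp = config$sigma_sp,
                    spec_gp = spec_gp, spec_sp = spec_sp))
}
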