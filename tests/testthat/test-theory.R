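# Two-region practice-location model: closed forms, numeric oracle,
# equilibrium solver and comparative statics.

h_unit <- household_params(income = 1, payroll_tax = 0, coinsurance = 0,
                           price_gp = 1, price_sp = 1, time_value = 1,
                           time_budget = 1, pref_gp = 1, pref_sp = 2,
                           pref_other = 1)

random_household <- function() {
  household_params(
    income = runif(1, 0.5, 5000), payroll_tax = runif(1, 0, 0.4),
    coinsurance = runif(1, 0, 1), price_gp = runif(1, 0.1, 60),
    price_sp = runif(1, 0.1, 90), time_value = runif(1, 0.1, 20),
    time_budget = runif(1, 1, 200), pref_gp = runif(1, 0.2, 2),
    pref_sp = runif(1, 2.1, 4), pref_other = runif(1, 0.2, 4))
}

test_that("parameter constructors enforce domain invariants", {
  expect_error(household_params(income = -1), "positive")
  expect_error(household_params(income = 1, payroll_tax = 1), "payroll_tax")
  expect_error(household_params(income = 1, coinsurance = 1.2),
               "coinsurance")
  expect_error(household_params(income = 1, pref_gp = 2, pref_sp = 1),
               "pref_sp")
  expect_error(region_geometry(area_urban = 500, area_rural = 400),
               "area_urban")
  expect_error(time_cost_params(0.5, 0.3), "q_sp")
  expect_error(time_cost_params(0, 0.5), "strictly")
  expect_error(supply_side_params(preference_weight = 0.9), ">= 1")
})

test_that("time_cost follows (count/area)^(-q) and is decreasing in density", {
  expect_equal(time_cost(5, 5, 0.3), 1.0)
  expect_equal(time_cost(4, 1, 0.5), 0.5)
  expect_equal(time_cost(2, 8, 0.25), sqrt(2), tolerance = 1e-12)
  dens <- seq(0.2, 5, length.out = 30)
  tc <- time_cost(dens, 1, 0.7)
  expect_true(all(diff(tc) < 0))
  expect_error(time_cost(-1, 1, 0.5), "positive")
  expect_error(time_cost(1, 1, 1), "\\(0, 1\\)")
})

test_that("closed-form demand matches hand example and scaling laws", {
  d <- optimal_demand(h_unit, 1, 1)
  expect_equal(d$demand_gp, 0.5)
  expect_equal(d$demand_sp, 1.0)
  expect_equal(d$other, 0.5)
  # with zero coinsurance, demand for GP visits is inversely proportional
  # to its time cost while S and Z are untouched
  d2 <- optimal_demand(h_unit, 2, 1)
  expect_equal(d2$demand_gp, d$demand_gp / 2)
  expect_equal(d2$demand_sp, d$demand_sp)
  expect_equal(d2$other, d$other)
  # joint scaling of income and time budget scales all demands
  hk <- household_params(income = 3, payroll_tax = 0, coinsurance = 0,
                         price_gp = 1, price_sp = 1, time_value = 1,
                         time_budget = 3, pref_gp = 1, pref_sp = 2,
                         pref_other = 1)
  dk <- optimal_demand(hk, 1, 1)
  expect_equal(unlist(dk[c("demand_gp", "demand_sp", "other")]),
               3 * unlist(d[c("demand_gp", "demand_sp", "other")]))
})

test_that("demand bundles satisfy the merged budget and first-order ratios", {
  set.seed(41)
  for (i in 1:25) {
    h <- random_household()
    t_gp <- runif(1, 0.05, 6); t_sp <- runif(1, 0.05, 6)
    d <- optimal_demand(h, t_gp, t_sp)
    expect_lt(abs(d$budget_residual), 1e-9 * d$full_income)
    # Z decomposes exactly into goods spend plus valued leisure
    expect_equal(d$other, d$goods_spend + h$time_value * d$leisure,
                 tolerance = 1e-12)
    cg <- h$coinsurance * h$price_gp + h$time_value * t_gp
    cs <- h$coinsurance * h$price_sp + h$time_value * t_sp
    expect_rel_equal(d$demand_sp / d$demand_gp,
                     (cg / cs) * (h$pref_sp / h$pref_gp), 1e-9)
    expect_rel_equal(d$other / d$demand_sp,
                     cs * h$pref_other / h$pref_sp, 1e-9)
    expect_rel_equal(d$other / d$demand_gp,
                     cg * h$pref_other / h$pref_gp, 1e-9)
  }
})

test_that("numeric utility oracle agrees with the closed form", {
  o <- oracle_max_utility(h_unit, 1, 1)
  expect_equal(o$demand_gp, 0.5, tolerance = 1e-5)
  expect_equal(o$demand_sp, 1.0, tolerance = 1e-5)
  expect_equal(o$other, 0.5, tolerance = 1e-5)
  # first-order-condition check at positive coinsurance
  h2 <- household_params(income = 1, payroll_tax = 0, coinsurance = 0.5,
                         price_gp = 1, price_sp = 1, time_value = 1,
                         time_budget = 1, pref_gp = 1, pref_sp = 2,
                         pref_other = 1)
  o2 <- oracle_max_utility(h2, 0.7, 1.3)
  cg <- 0.5 + 0.7; cs <- 0.5 + 1.3
  expect_rel_equal(o2$demand_sp / o2$demand_gp, (cg / cs) * 2, 1e-6)
})

test_that("oracle sweep: 50 seeded draws within 1e-5 of the closed form", {
  set.seed(7)
  worst <- 0
  for (i in 1:50) {
    h <- random_household()
    t_gp <- runif(1, 0.05, 6); t_sp <- runif(1, 0.05, 6)
    cf <- optimal_demand(h, t_gp, t_sp)
    or <- oracle_max_utility(h, t_gp, t_sp)
    dev <- max(abs(c(or$demand_gp / cf$demand_gp,
                     or$demand_sp / cf$demand_sp,
                     or$other / cf$other) - 1))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-5)
})

test_that("physician_income is margin * demand * n / count", {
  expect_equal(physician_income(1, 0.5, 1000, 100), 5.0)
  expect_equal(physician_income(2, 0.25, 400, 10), 20.0)
  expect_equal(physician_income(1, 0.5, 1000, 200),
               physician_income(1, 0.5, 1000, 100) / 2)
  expect_error(physician_income(1, 0.5, 1000, 0), "count")
})

test_that("closed-form ratio and the SP/GP multiplier", {
  g1 <- region_geometry(1, 1, 1)
  expect_equal(closed_form_urban_rural_ratio(0.3, g1, 1), 1.0)
  g4 <- region_geometry(1, 1, 4)
  expect_equal(closed_form_urban_rural_ratio(0.5, g4, 1), 4.0)
  expect_equal(closed_form_urban_rural_ratio(0.5, g1, 1.21), 1.4641,
               tolerance = 1e-12)
  expect_error(closed_form_urban_rural_ratio(1, g4, 1), "\\(0, 1\\)")
  # multiplier identities
  expect_equal(sp_gp_ratio_multiplier(time_cost_params(0.3, 0.3), g4), 1.0)
  g16 <- region_geometry(1, 1, 16)
  expect_equal(sp_gp_ratio_multiplier(time_cost_params(0.25, 0.5), g16),
               16^(2 / 3), tolerance = 1e-12)
  expect_equal(sp_gp_ratio_multiplier(time_cost_params(0.25, 0.5), g1), 1.0)
  # equals ratio(q_sp)/ratio(q_gp) at w = 1
  expect_rel_equal(sp_gp_ratio_multiplier(time_cost_params(0.25, 0.5), g16),
                   closed_form_urban_rural_ratio(0.5, g16, 1) /
                     closed_form_urban_rural_ratio(0.25, g16, 1), 1e-12)
})

base_zero_coins <- function() {
  p <- default_equilibrium_params()
  p$h$coinsurance <- 0
  p
}

test_that("solver reproduces the closed form at zero coinsurance", {
  p <- base_zero_coins()
  p$tc <- time_cost_params(0.5, 0.6)
  p$geometry <- region_geometry(1e5, 100, 400)
  p$supply$preference_weight <- 1
  eq <- solve_equilibrium(100, 60, p$h, p$geometry, p$tc, p$supply)
  expect_equal(eq$gp_urban, 80, tolerance = 1e-8)
  expect_equal(eq$gp_rural, 20, tolerance = 1e-8)
  expect_equal(eq$gp_urban + eq$gp_rural, 100, tolerance = 1e-10)
  expect_lt(abs(eq$residual_gp), 1e-10)
  expect_lt(abs(eq$residual_sp), 1e-10)
})

test_that("symmetric regions with no preference split 50/50", {
  p <- base_zero_coins()
  p$geometry <- region_geometry(1e5, 200, 200)
  p$supply$preference_weight <- 1
  eq <- solve_equilibrium(100, 60, p$h, p$geometry, p$tc, p$supply)
  expect_equal(eq$gp_urban, 50, tolerance = 1e-8)
  expect_equal(eq$sp_urban, 30, tolerance = 1e-8)
})

test_that("equilibrium sweep: solver vs closed form, Eq-21 identity", {
  set.seed(11)
  for (i in 1:20) {
    p <- base_zero_coins()
    p$h <- random_household()
    p$h$coinsurance <- 0
    q_gp <- runif(1, 0.05, 0.8)
    p$tc <- time_cost_params(q_gp, runif(1, q_gp + 0.01, 0.9))
    p$geometry <- region_geometry(1e5, runif(1, 50, 200), runif(1, 210, 900))
    p$supply <- supply_side_params(runif(1, 1, 40), runif(1, 1, 50),
                                   runif(1, 1, 1.5))
    eq <- solve_equilibrium(runif(1, 20, 300), runif(1, 10, 200), p$h,
                            p$geometry, p$tc, p$supply)
    w <- p$supply$preference_weight
    expect_rel_equal(eq$gp_ratio,
                     closed_form_urban_rural_ratio(p$tc$q_gp, p$geometry, w),
                     1e-8)
    expect_rel_equal(eq$sp_ratio,
                     closed_form_urban_rural_ratio(p$tc$q_sp, p$geometry, w),
                     1e-8)
    # SP_u/GP_u = (SP_r/GP_r) * multiplier
    expect_rel_equal(eq$sp_urban / eq$gp_urban,
                     (eq$sp_rural / eq$gp_rural) * eq$sp_gp_multiplier,
                     1e-8)
  }
})

test_that("income equilibrium holds at positive coinsurance (no closed form)", {
  p <- default_equilibrium_params()
  p$h$coinsurance <- 0.5
  eq <- solve_equilibrium(100, 60, p$h, p$geometry, p$tc, p$supply)
  w <- p$supply$preference_weight
  expect_lt(abs(eq$income_gp_rural - w * eq$income_gp_urban),
            1e-8 * w * eq$income_gp_urban)
  expect_lt(abs(eq$income_sp_rural - w * eq$income_sp_urban),
            1e-8 * w * eq$income_sp_urban)
})

test_that("the equilibrium condition is strictly monotone on its bracket", {
  p <- default_equilibrium_params()
  fi <- physupply:::full_income(p$h)
  f <- function(share) {
    gp_u <- 100 * share; gp_r <- 100 * (1 - share)
    t_u <- time_cost(gp_u, p$geometry$area_urban, p$tc$q_gp)
    t_r <- time_cost(gp_r, p$geometry$area_rural, p$tc$q_gp)
    au <- optimal_demand(p$h, t_u, 1)$demand_gp
    ar <- optimal_demand(p$h, t_r, 1)$demand_gp
    physician_income(p$supply$margin_gp, ar, p$geometry$population, gp_r) -
      p$supply$preference_weight *
        physician_income(p$supply$margin_gp, au, p$geometry$population, gp_u)
  }
  vals <- vapply(seq(0.01, 0.99, length.out = 60), f, 0)
  expect_true(all(diff(vals) > 0))
  expect_equal(sum(sign(diff(sign(vals))) != 0), 1)  # exactly one crossing
})

test_that("comparative statics support the four propositions", {
  base <- default_equilibrium_params()
  base$h$coinsurance <- 0
  # proposition 1: inequality rises with the urban preference weight
  cw <- comparative_statics(base, "preference_weight", c(1.0, 1.1, 1.2))
  expect_true(all(diff(cw$gp_ratio) > 0))
  expect_true(all(diff(cw$sp_ratio) > 0))
  # proposition 2: inequality rises with the rural/urban area ratio
  ca <- comparative_statics(base, "area_ratio", c(1, 2, 4))
  expect_true(all(diff(ca$gp_ratio) > 0))
  expect_true(all(diff(ca$sp_ratio) > 0))
  # proposition 3: urban SP/GP mix exceeds the rural mix when q_sp > q_gp
  eq <- solve_equilibrium(base$gp_total, base$sp_total, base$h,
                          base$geometry, base$tc, base$supply)
  expect_gt(eq$sp_urban / eq$gp_urban, eq$sp_rural / eq$gp_rural)
  expect_gt(eq$sp_gp_multiplier, 1)
  # proposition 4: more out-of-pocket payment weakens the imbalance
  cc <- comparative_statics(default_equilibrium_params(), "coinsurance",
                            c(0, 0.25, 0.5))
  expect_true(all(diff(cc$gp_ratio) <= 0))
  expect_true(all(diff(cc$sp_ratio) <= 0))
})

test_that("comparative statics mark failed grid points as missing", {
  base <- default_equilibrium_params()
  out <- comparative_statics(base, "preference_weight", c(1.1, 0.5))
  expect_false(anyNA(out[1, ]))
  expect_true(all(is.na(out[2, -1])))
  expect_error(comparative_statics(base, "no_such_param", 1), "unknown")
})

test_that("a specialist-specific preference weight shifts only specialists", {
  p <- base_zero_coins()
  shared <- solve_equilibrium(100, 60, p$h, p$geometry, p$tc, p$supply)
  p$supply <- supply_side_params(preference_weight = p$supply$preference_weight,
                                 preference_weight_sp = 1.4)
  split <- solve_equilibrium(100, 60, p$h, p$geometry, p$tc, p$supply)
  expect_equal(split$gp_ratio, shared$gp_ratio, tolerance = 1e-10)
  expect_gt(split$sp_ratio, shared$sp_ratio)
  expect_rel_equal(split$sp_ratio,
                   closed_form_urban_rural_ratio(p$tc$q_sp, p$geometry, 1.4),
                   1e-8)
  expect_error(supply_side_params(preference_weight_sp = 0.8), ">= 1")
})
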