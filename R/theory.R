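#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Two-region economic model of physician practice location.
#
# A representative consumer with Cobb-Douglas utility U = A^a S^s Z^z demands
# GP services A, specialist services S and other consumption Z subject to a
# merged money+time budget. Per-visit time cost falls with regional physician
# density, t = (count/area)^(-q).  Physicians locate so that rural income
# equals w times urban income (w >= 1: urban preference).
# ---------------------------------------------------------------------------

stop_domain <- function(...) stop(..., call. = FALSE)

#' Consumer-side parameters
#'
#' Bundles every consumer-side parameter of the demand model: gross income,
#' payroll tax financing health insurance, the co-insurance rate paid
#' out of pocket, service prices, the opportunity cost of time, the time
#' budget, and the Cobb-Douglas preference exponents for GP services,
#' specialist services and other consumption.
#'
#' @param income gross income per period (currency); must be positive.
#' @param payroll_tax health-insurance payroll tax rate, in `[0, 1)`.
#' @param coinsurance share of the service price paid out of pocket, in
#'   `[0, 1]`. `0` means full insurance coverage.
#' @param price_gp,price_sp price of one service unit of a GP / specialist.
#' @param time_value opportunity cost of one time unit (currency/time).
#' @param time_budget total time budget per period.
#' @param pref_gp,pref_sp,pref_other Cobb-Douglas exponents `a`, `s`, `z`.
#'   Specialist services must be preferred: `pref_sp > pref_gp`.
#' @return An object of class `household_params`.
#' @export
#' @examples
#' h <- household_params(income = 1, payroll_tax = 0, coinsurance = 0,
#'                       price_gp = 1, price_sp = 1, time_value = 1,
#'                       time_budget = 1, pref_gp = 1, pref_sp = 2,
#'                       pref_other = 1)
#' optimal_demand(h, t_gp = 1, t_sp = 1)
household_params <- function(income, payroll_tax = 0.15, coinsurance = 0.1,
                             price_gp = 30, price_sp = 45, time_value = 10,
                             time_budget = 160, pref_gp = 1, pref_sp = 1.2,
                             pref_other = 3) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_domain(nm, " must be a finite numeric scalar")
    x
  }
  income      <- num1(income, "income")
  payroll_tax <- num1(payroll_tax, "payroll_tax")
  coinsurance <- num1(coinsurance, "coinsurance")
  price_gp    <- num1(price_gp, "price_gp")
  price_sp    <- num1(price_sp, "price_sp")
  time_value  <- num1(time_value, "time_value")
  time_budget <- num1(time_budget, "time_budget")
  pref_gp     <- num1(pref_gp, "pref_gp")
  pref_sp     <- num1(pref_sp, "pref_sp")
  pref_other  <- num1(pref_other, "pref_other")
  if (income <= 0 || time_budget <= 0 || time_value <= 0 ||
      price_gp <= 0 || price_sp <= 0)
    stop_domain("income, time_budget, time_value and prices must be positive")
  if (payroll_tax < 0 || payroll_tax >= 1)
    stop_domain("payroll_tax must lie in [0, 1)")
  if (coinsurance < 0 || coinsurance > 1)
    stop_domain("coinsurance must lie in [0, 1]")
  if (pref_gp <= 0 || pref_other <= 0)
    stop_domain("preference exponents must be positive")
  if (pref_sp <= pref_gp)
    stop_domain("pref_sp must exceed pref_gp (specialists are preferred)")
  structure(list(income = income, payroll_tax = payroll_tax,
                 coinsurance = coinsurance, price_gp = price_gp,
                 price_sp = price_sp, time_value = time_value,
                 time_budget = time_budget, pref_gp = pref_gp,
                 pref_sp = pref_sp, pref_other = pref_other),
            class = "household_params")
}

#' Two-region geometry
#'
#' Both regions hold the same population `n` but the rural region is larger,
#' so population density is higher in the urban region.
#'
#' @param population inhabitants per region (identical by assumption).
#' @param area_urban,area_rural region sizes in km^2, `area_urban < area_rural`
#'   (equality tolerated for symmetric boundary cases).
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(population = 1e5, area_urban = 100,
                            area_rural = 400) {
  if (population <= 0) stop_domain("population must be positive")
  if (area_urban <= 0 || area_rural <= 0) stop_domain("areas must be positive")
  if (area_urban > area_rural)
    stop_domain("area_urban must not exceed area_rural")
  structure(list(population = population, area_urban = area_urban,
                 area_rural = area_rural), class = "region_geometry")
}

#' Time-cost elasticities
#'
#' Exponents of the per-visit time-cost function `t = (count/area)^(-q)`.
#' Both lie strictly in `(0, 1)` and the specialist exponent exceeds the GP
#' exponent: finding an appropriate specialist costs relatively more search
#' and travel time.
#'
#' @param q_gp,q_sp elasticities in `(0, 1)` with `q_sp >= q_gp`
#'   (`q_sp == q_gp` is admitted only so the ratio identity can be checked
#'   at its boundary).
#' @return An object of class `time_cost_params`.
#' @export
time_cost_params <- function(q_gp = 0.3, q_sp = 0.5) {
  if (q_gp <= 0 || q_gp >= 1 || q_sp <= 0 || q_sp >= 1)
    stop_domain("time-cost elasticities must lie strictly in (0, 1)")
  if (q_sp < q_gp) stop_domain("q_sp must be >= q_gp")
  structure(list(q_gp = q_gp, q_sp = q_sp), class = "time_cost_params")
}

#' Physician-side parameters
#'
#' Per-service margins (price minus marginal cost) and the regional
#' preference weight `w`: the income multiple a physician demands to practice
#' rurally. `w = 1` means no regional preference; `w > 1` urban preference.
#'
#' @param margin_gp,margin_sp price minus marginal cost per service unit;
#'   both positive.
#' @param preference_weight regional preference weight `w >= 1`, shared by
#'   both physician types by default.
#' @param preference_weight_sp optional specialist-specific weight (an
#'   extension flag; `NULL`, the default, shares `preference_weight`).
#' @return An object of class `supply_side_params`.
#' @export
supply_side_params <- function(margin_gp = 20, margin_sp = 30,
                               preference_weight = 1.1,
                               preference_weight_sp = NULL) {
  if (margin_gp <= 0 || margin_sp <= 0)
    stop_domain("margins must be positive")
  if (preference_weight < 1 ||
      (!is.null(preference_weight_sp) && preference_weight_sp < 1))
    stop_domain("preference weights must be >= 1")
  structure(list(margin_gp = margin_gp, margin_sp = margin_sp,
                 preference_weight = preference_weight,
                 preference_weight_sp = preference_weight_sp),
            class = "supply_side_params")
}

#' Per-visit time cost
#'
#' Time needed to consume one physician service (travel, search, waiting and
#' consultation) as a function of regional physician density:
#' `t = (count/area)^(-q)`. Strictly decreasing in density; `q < 1` because
#' travel is only one component of the total visit time.
#'
#' @param count physicians in the region (positive, continuous).
#' @param area region size in km^2.
#' @param q time-cost elasticity in `(0, 1)`.
#' @return Time units per visit.
#' @export
#' @examples
#' time_cost(5, 5, 0.3)    # density 1 -> cost 1 for any exponent
#' time_cost(4, 1, 0.5)    # 4^(-1/2) = 0.5
time_cost <- function(count, area, q) {
  if (any(count <= 0) || any(area <= 0))
    stop_domain("count and area must be positive")
  if (any(q <= 0) || any(q >= 1))
    stop_domain("q must lie strictly in (0, 1)")
  (count / area)^(-q)
}

full_income <- function(h) {
  h$income * (1 - h$payroll_tax) + h$time_value * h$time_budget
}

# effective unit cost of a visit: out-of-pocket price + valued time
visit_cost <- function(h, price, t) h$coinsurance * price + h$time_value * t

#' Utility-maximizing demand (closed form)
#'
#' Closed-form Maximizer of `U = A^a S^s Z^z` subject to the merged money and
#' time constraint. The demand for each physician type is the preference
#' share of full income divided by the effective visit cost
#' (out-of-pocket price plus valued time):
#' `A = a (y(1-b) + rho*l) / ((a' p_A + rho t_A)(a + z + s))`, and analogously
#' for `S`. Other consumption `Z` absorbs the remaining full income. Goods
#' spending `Y` and leisure `L` are recovered as accounting identities;
#' only the merged constraint is enforced, so `L` may be negative.
#'
#' @param h a [household_params()] object.
#' @param t_gp,t_sp per-visit time cost for GP / specialist services.
#' @return An object of class `demand_bundle`: a list with `demand_gp`,
#'   `demand_sp`, `other` (Z), `goods_spend` (Y), `leisure` (L),
#'   `full_income`, and `budget_residual` (merged-constraint residual,
#'   zero up to rounding).
#' @export
optimal_demand <- function(h, t_gp, t_sp) {
  stopifnot(inherits(h, "household_params"))
  if (t_gp <= 0 || t_sp <= 0) stop_domain("time costs must be positive")
  fi <- full_income(h)
  if (fi <= 0) stop_domain("degenerate input: full income must be positive")
  denom <- h$pref_gp + h$pref_other + h$pref_sp
  c_gp <- visit_cost(h, h$price_gp, t_gp)
  c_sp <- visit_cost(h, h$price_sp, t_sp)
  A <- h$pref_gp * fi / (c_gp * denom)
  S <- h$pref_sp * fi / (c_sp * denom)
  Z <- h$pref_other * fi / denom
  Y <- h$income * (1 - h$payroll_tax) -
    h$coinsurance * (h$price_gp * A + h$price_sp * S)
  L <- h$time_budget - t_gp * A - t_sp * S
  resid <- Z - (Y + h$time_value * L)
  structure(list(demand_gp = A, demand_sp = S, other = Z, goods_spend = Y,
                 leisure = L, full_income = fi, budget_residual = resid),
            class = "demand_bundle")
}

#' Numeric utility-maximization oracle
#'
#' Independent check on [optimal_demand()]: maximizes the log-utility
#' `a log A + s log S + z log Z` with `Z` eliminated through the merged
#' budget constraint, by Nelder-Mead followed by a BFGS polish on
#' `(log A, log S)`. Deliberately shares no algebra with the closed form.
#'
#' @inheritParams optimal_demand
#' @param control list of optimizer settings: `reltol` (default `1e-12`) and
#'   `maxit` (default `2000`).
#' @return A `demand_bundle`, as [optimal_demand()], plus attributes
#'   `convergence` and `value`.
#' @export
oracle_max_utility <- function(h, t_gp, t_sp, control = list()) {
  stopifnot(inherits(h, "household_params"))
  if (t_gp <= 0 || t_sp <= 0) stop_domain("time costs must be positive")
  fi <- full_income(h)
  if (fi <= 0) stop_domain("degenerate input: full income must be positive")
  reltol <- if (is.null(control$reltol)) 1e-14 else control$reltol
  maxit <- if (is.null(control$maxit)) 5000L else control$maxit
  c_gp <- visit_cost(h, h$price_gp, t_gp)
  c_sp <- visit_cost(h, h$price_sp, t_sp)
  negobj <- function(par) {
    A <- exp(par[1]); S <- exp(par[2])
    Z <- fi - c_gp * A - c_sp * S
    if (!is.finite(Z) || Z <= 0) return(1e12 + sum(par^2))
    -(h$pref_gp * par[1] + h$pref_sp * par[2] + h$pref_other * log(Z))
  }
  # neutral start: one third of full income on each composite good
  p0 <- c(log(fi / (3 * c_gp)), log(fi / (3 * c_sp)))
  o1 <- stats::optim(p0, negobj, method = "Nelder-Mead",
                     control = list(reltol = reltol, maxit = maxit))
  o2 <- stats::optim(o1$par, negobj, method = "BFGS",
                     control = list(reltol = reltol, maxit = maxit))
  if (o2$convergence != 0 && o1$convergence != 0)
    stop_domain("utility-maximization oracle failed to converge ",
                "(codes ", o1$convergence, "/", o2$convergence, ")")
  best <- if (o2$value <= o1$value) o2 else o1
  A <- exp(best$par[1]); S <- exp(best$par[2])
  Z <- fi - c_gp * A - c_sp * S
  Y <- h$income * (1 - h$payroll_tax) -
    h$coinsurance * (h$price_gp * A + h$price_sp * S)
  L <- h$time_budget - t_gp * A - t_sp * S
  out <- structure(list(demand_gp = A, demand_sp = S, other = Z,
                        goods_spend = Y, leisure = L, full_income = fi,
                        budget_residual = Z - (Y + h$time_value * L)),
                   class = "demand_bundle")
  attr(out, "convergence") <- best$convergence
  attr(out, "value") <- -best$value
  out
}

#' Physician income
#'
#' Income of one physician: margin times per-capita demand times regional
#' population, shared equally among the physicians of that type in the
#' region.
#'
#' @param margin price minus marginal cost per service unit.
#' @param percap_demand per-capita service demand in the region.
#' @param n regional population.
#' @param count physicians of this type in the region.
#' @return Income per physician (currency per period).
#' @export
physician_income <- function(margin, percap_demand, n, count) {
  if (any(c(margin, percap_demand, n) <= 0))
    stop_domain("margin, percap_demand and n must be positive")
  if (any(count <= 0)) stop_domain("physician count must be positive")
  margin * percap_demand * n / count
}

#' Closed-form urban/rural allocation ratio
#'
#' Under full insurance coverage (zero co-insurance) the equilibrium
#' allocation of one physician type has the closed form
#' `count_u / count_r = (m_r/m_u)^(q/(1-q)) * w^(1/(1-q))`. The ratio is at
#' least 1: urban density exceeds rural density whenever areas differ or
#' physicians prefer urban regions.
#'
#' @param q time-cost elasticity of the physician type, in `(0, 1)`.
#' @param geometry a [region_geometry()] object.
#' @param w regional preference weight, `w >= 1`.
#' @return The urban/rural count ratio.
#' @export
#' @examples
#' closed_form_urban_rural_ratio(0.5, region_geometry(1, 1, 4), 1)  # 4
closed_form_urban_rural_ratio <- function(q, geometry, w = 1) {
  stopifnot(inherits(geometry, "region_geometry"))
  if (q <= 0 || q >= 1) stop_domain("q must lie strictly in (0, 1)")
  if (w < 1) stop_domain("w must be >= 1")
  mr_mu <- geometry$area_rural / geometry$area_urban
  mr_mu^(q / (1 - q)) * w^(1 / (1 - q))
}

#' Urban amplification of the specialist/GP mix
#'
#' Ratio of the specialist urban/rural ratio to the GP urban/rural ratio:
#' `((m_r/m_u) w)^((q_S - q_A)/((1-q_A)(1-q_S)))`, the quotient of the two
#' closed-form allocation ratios. Because specialists carry the larger
#' time-cost elasticity, the specialist-to-GP mix is tilted toward the
#' urban region by exactly this factor. With no regional preference
#' (`w = 1`, the default) the base reduces to the area ratio alone.
#'
#' @param tc a [time_cost_params()] object (`q_gp == q_sp` admitted for the
#'   boundary identity).
#' @param geometry a [region_geometry()] object.
#' @param w regional preference weight entering both closed forms.
#' @return Multiplier `>= 1` when `q_sp >= q_gp` and `m_r >= m_u`.
#' @export
sp_gp_ratio_multiplier <- function(tc, geometry, w = 1) {
  stopifnot(inherits(tc, "time_cost_params"),
            inherits(geometry, "region_geometry"))
  if (w < 1) stop_domain("w must be >= 1")
  mr_mu <- geometry$area_rural / geometry$area_urban
  (mr_mu * w)^((tc$q_sp - tc$q_gp) / ((1 - tc$q_gp) * (1 - tc$q_sp)))
}

# Urban/rural split of one physician type by root-finding on the log
# urban/rural ratio x (so extreme allocations keep full relative
# precision). f(x) = Y_rural - w * Y_urban is strictly increasing in x, so
# the root is unique. Works for any coinsurance rate.
split_one_type <- function(total, h, geometry, q, price, margin, pref, w,
                           xmax = 60, tol = 1e-13) {
  fi <- full_income(h)
  denom <- h$pref_gp + h$pref_other + h$pref_sp
  percap <- function(count, area) {
    t <- (count / area)^(-q)
    pref * fi / (visit_cost(h, price, t) * denom)
  }
  inc <- function(count, area) {
    margin * percap(count, area) * geometry$population / count
  }
  f <- function(x) {
    inc(total * stats::plogis(-x), geometry$area_rural) -
      w * inc(total * stats::plogis(x), geometry$area_urban)
  }
  flo <- f(-xmax); fhi <- f(xmax)
  if (!is.finite(flo) || !is.finite(fhi) || flo > 0 || fhi < 0)
    stop_domain("equilibrium root not bracketed on (-", xmax, ", ", xmax,
                "): f(lo)=", format(flo), ", f(hi)=", format(fhi))
  root <- stats::uniroot(f, c(-xmax, xmax), tol = tol)$root
  # secant polish to push the income residual toward machine precision
  x0 <- root; x1 <- root + 1e-7
  for (i in 1:10) {
    f0 <- f(x0); f1 <- f(x1)
    if (!is.finite(f0) || !is.finite(f1) || f1 == f0) break
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    if (!is.finite(x2) || abs(x2) >= xmax) break
    x0 <- x1; x1 <- x2
    if (abs(f(x1)) <= abs(f(root))) root <- x1
  }
  cu <- total * stats::plogis(root); cr <- total * stats::plogis(-root)
  list(urban = cu, rural = cr, log_ratio = root,
       income_urban = inc(cu, geometry$area_urban),
       income_rural = inc(cr, geometry$area_rural),
       residual = f(root))
}

#' Regional equilibrium allocation of physicians
#'
#' Splits a fixed total of GPs and of specialists between the urban and the
#' rural region so that the rural income of each type equals `w` times its
#' urban income. The split of each type is found by root-finding on the
#' urban share (the income difference is strictly monotone in the share, so
#' the equilibrium is unique); with zero co-insurance the resulting ratios
#' coincide with [closed_form_urban_rural_ratio()].
#'
#' @param gp_total,sp_total total physicians of each type (positive,
#'   continuous).
#' @param h a [household_params()] object.
#' @param geometry a [region_geometry()] object.
#' @param tc a [time_cost_params()] object.
#' @param supply a [supply_side_params()] object.
#' @return An object of class `equilibrium_solution`: urban/rural counts and
#'   incomes per type, per-region demand bundles, the urban/rural count
#'   ratios, the specialist/GP mix multiplier, and relative equilibrium
#'   residuals.
#' @export
solve_equilibrium <- function(gp_total, sp_total, h, geometry, tc, supply) {
  stopifnot(inherits(h, "household_params"),
            inherits(geometry, "region_geometry"),
            inherits(tc, "time_cost_params"),
            inherits(supply, "supply_side_params"))
  if (gp_total <= 0 || sp_total <= 0) stop_domain("totals must be positive")
  w <- supply$preference_weight
  w_sp <- if (is.null(supply$preference_weight_sp)) w
          else supply$preference_weight_sp
  gp <- split_one_type(gp_total, h, geometry, tc$q_gp, h$price_gp,
                       supply$margin_gp, h$pref_gp, w)
  sp <- split_one_type(sp_total, h, geometry, tc$q_sp, h$price_sp,
                       supply$margin_sp, h$pref_sp, w_sp)
  t_gp_u <- time_cost(gp$urban, geometry$area_urban, tc$q_gp)
  t_sp_u <- time_cost(sp$urban, geometry$area_urban, tc$q_sp)
  t_gp_r <- time_cost(gp$rural, geometry$area_rural, tc$q_gp)
  t_sp_r <- time_cost(sp$rural, geometry$area_rural, tc$q_sp)
  structure(list(
    gp_urban = gp$urban, gp_rural = gp$rural,
    sp_urban = sp$urban, sp_rural = sp$rural,
    income_gp_urban = gp$income_urban, income_gp_rural = gp$income_rural,
    income_sp_urban = sp$income_urban, income_sp_rural = sp$income_rural,
    demand_urban = optimal_demand(h, t_gp_u, t_sp_u),
    demand_rural = optimal_demand(h, t_gp_r, t_sp_r),
    gp_ratio = exp(gp$log_ratio),
    sp_ratio = exp(sp$log_ratio),
    sp_gp_multiplier = sp_gp_ratio_multiplier(tc, geometry, w),
    residual_gp = gp$residual / (w * gp$income_urban),
    residual_sp = sp$residual / (w_sp * sp$income_urban)),
    class = "equilibrium_solution")
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat("Regional equilibrium\n")
  cat(sprintf("  GPs:         urban %.4f / rural %.4f (ratio %.4f)\n",
              x$gp_urban, x$gp_rural, x$gp_ratio))
  cat(sprintf("  Specialists: urban %.4f / rural %.4f (ratio %.4f)\n",
              x$sp_urban, x$sp_rural, x$sp_ratio))
  cat(sprintf("  SP/GP urban amplification: %.4f\n", x$sp_gp_multiplier))
  cat(sprintf("  relative residuals: GP %.2e, SP %.2e\n",
              x$residual_gp, x$residual_sp))
  invisible(x)
}

#' Default parameter set for the two-region model
#'
#' One documented baseline used by the comparative-statics grids and the
#' examples: monthly income 2000, 15% payroll tax, 10% co-insurance,
#' service prices 30/45, time valued at 10 per hour over a 160-hour budget,
#' preferences (1, 1.2, 3), urban 100 km^2 vs rural 400 km^2 with 100 000
#' inhabitants each, elasticities (0.3, 0.5), margins (20, 30), w = 1.1,
#' 100 GPs and 60 specialists.
#'
#' @return Named list with components `h`, `geometry`, `tc`, `supply`,
#'   `gp_total`, `sp_total`.
#' @export
default_equilibrium_params <- function() {
  list(h = household_params(income = 2000),
       geometry = region_geometry(),
       tc = time_cost_params(),
       supply = supply_side_params(),
       gp_total = 100, sp_total = 60)
}

# where each tunable parameter lives within the base parameter list
.vary_slots <- c(
  income = "h", payroll_tax = "h", coinsurance = "h", price_gp = "h",
  price_sp = "h", time_value = "h", time_budget = "h", pref_gp = "h",
  pref_sp = "h", pref_other = "h", population = "geometry",
  area_urban = "geometry", area_rural = "geometry", q_gp = "tc",
  q_sp = "tc", margin_gp = "supply", margin_sp = "supply",
  preference_weight = "supply", gp_total = "", sp_total = "")

#' Comparative statics over a parameter grid
#'
#' Re-solves the regional equilibrium along a grid of values for one
#' parameter, returning the urban/rural allocation and ratios at each grid
#' point. Supports the model's testable propositions: inequality rises with
#' the preference weight `w` and with the rural/urban area ratio, the
#' specialist mix is more urban than the GP mix, and a higher co-insurance
#' rate (less insurance coverage) weakens the regional imbalance.
#'
#' @param base parameter list as returned by [default_equilibrium_params()].
#' @param vary name of the parameter to vary (a field of `h`, `geometry`,
#'   `tc`, `supply`, or `gp_total`/`sp_total`; also `"area_ratio"`, which
#'   rescales `area_rural` relative to `area_urban`).
#' @param grid numeric vector of values.
#' @return A data.frame with one row per grid point: the varied value,
#'   urban/rural counts and incomes, `gp_ratio`, `sp_ratio`,
#'   `sp_gp_multiplier` and residuals. Failed solves yield `NA` rows.
#' @export
comparative_statics <- function(base = default_equilibrium_params(), vary,
                                grid) {
  if (!vary %in% c(names(.vary_slots), "area_ratio"))
    stop_domain("unknown parameter: ", vary)
  rows <- lapply(grid, function(v) {
    p <- base
    if (vary == "area_ratio") {
      p$geometry$area_rural <- v * p$geometry$area_urban
    } else {
      slot <- .vary_slots[[vary]]
      if (slot == "") p[[vary]] <- v else p[[slot]][[vary]] <- v
    }
    res <- tryCatch({
      # rebuild through the constructors so invalid grid values are caught
      p$h <- do.call(household_params, unclass(p$h))
      p$geometry <- do.call(region_geometry, unclass(p$geometry))
      p$tc <- do.call(time_cost_params, unclass(p$tc))
      p$supply <- do.call(supply_side_params, unclass(p$supply))
      solve_equilibrium(p$gp_total, p$sp_total, p$h, p$geometry, p$tc,
                        p$supply)
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(value = v, gp_urban = NA_real_, gp_rural = NA_real_,
                 sp_urban = NA_real_, sp_rural = NA_real_,
                 gp_ratio = NA_real_, sp_ratio = NA_real_,
                 sp_gp_multiplier = NA_real_, residual_gp = NA_real_,
                 residual_sp = NA_real_)
    } else {
      data.frame(value = v, gp_urban = res$gp_urban, gp_rural = res$gp_rural,
                 sp_urban = res$sp_urban, sp_rural = res$sp_rural,
                 gp_ratio = res$gp_ratio, sp_ratio = res$sp_ratio,
                 sp_gp_multiplier = res$sp_gp_multiplier,
                 residual_gp = res$residual_gp, residual_sp = res$residual_sp)
    }
  })
  do.call(rbind, rows)
}
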