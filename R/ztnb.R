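# ---------------------------------------------------------------------------
# Zero-truncated negative-binomial regression with log link, offset and
# region (ASHIP) intercepts. Mean-dispersion parameterization: variance
# mu + sigma*mu^2, sigma estimated on the log scale. Metric covariates are
# standardized by two standard deviations so their coefficients compare
# directly with binary covariates.
# ---------------------------------------------------------------------------

#' Model specification for a district count model
#'
#' @param response name of the count column (`"gp_count"` or `"sp_count"`).
#' @param offset `"population"` for `log(inhabitants/10^4)` (the model then
#'   estimates physician density per 10 000) or the name of a count column,
#'   e.g. `"sp_count"` for the GP/specialist ratio model.
#' @param metric names of metric covariates (two-SD standardized).
#' @param binary names of binary covariates (left 0/1).
#' @param interactions list of length-2 character vectors; each interaction
#'   column is the product of the transformed parents.
#' @param region_col name of the region (ASHIP) column.
#' @param ref_region reference region absorbed in the intercept; `NULL`
#'   selects the region with the lowest observed mean density at build time.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, offset = "population",
                       metric = character(), binary = character(),
                       interactions = list(), region_col = "region",
                       ref_region = NULL) {
  terms <- c(metric, binary)
  if (response %in% terms)
    stop_domain("response cannot appear among the terms")
  for (ia in interactions) {
    if (length(ia) != 2L || !all(ia %in% terms))
      stop_domain("interaction parents must be listed terms: ",
                  paste(ia, collapse = ":"))
  }
  structure(list(response = response, offset = offset, metric = metric,
                 binary = binary, interactions = interactions,
                 region_col = region_col, ref_region = ref_region),
            class = "model_spec")
}

#' Default model specification
#'
#' The final published model's term set: twelve two-SD-scaled metric
#' covariates, the city and state-capital binaries, and the population
#' density by city interaction. `"gp"`/`"sp"` use the log population
#' offset; `"ratio"` models GP counts with a log specialist-count offset so
#' that `exp(linear predictor)` is the GP/specialist ratio.
#'
#' @param model `"gp"`, `"sp"` or `"ratio"`.
#' @param terms optional shared term list (defaults to the final-model set).
#' @param interactions list of interaction pairs.
#' @param ref_region passed to [model_spec()].
#' @return A `model_spec`.
#' @export
default_model_spec <- function(model = c("gp", "sp", "ratio"), terms = NULL,
                               interactions = list(c("pop_density", "city")),
                               ref_region = NULL) {
  model <- match.arg(model)
  metric_default <- c("pop_density", "household_income", "privately_insured",
                      "hospital_beds", "middle_order_centers",
                      "high_order_centers", "highly_qualified",
                      "unemployment", "touristic_attractiveness",
                      "migration_balance_5y", "travel_time_airport",
                      "travel_time_middle_center")
  binary_default <- c("city", "state_capital")
  if (is.null(terms)) {
    metric <- metric_default; binary <- binary_default
  } else {
    metric <- intersect(terms, metric_default)
    binary <- intersect(terms, binary_default)
    extra <- setdiff(terms, c(metric, binary))
    metric <- c(metric, extra)  # unknown terms default to metric handling
  }
  keep <- vapply(interactions, function(ia) all(ia %in% c(metric, binary)),
                 TRUE)
  switch(model,
    gp = model_spec("gp_count", "population", metric, binary,
                    interactions[keep], ref_region = ref_region),
    sp = model_spec("sp_count", "population", metric, binary,
                    interactions[keep], ref_region = ref_region),
    ratio = model_spec("gp_count", "sp_count", metric, binary,
                       interactions[keep], ref_region = ref_region))
}

#' Two-standard-deviation standardization
#'
#' Centers a metric column and divides by twice its standard deviation, so
#' a coefficient measures the effect of a two-SD increase and is directly
#' comparable to a binary coefficient. The centering record is retained for
#' back-translation of effects.
#'
#' @param x numeric vector with positive SD.
#' @return List with `values` (scaled column, sample mean 0 and SD 0.5),
#'   `center` and `scale` (the original mean and SD).
#' @export
two_sd_standardize <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop_domain("degenerate column: standard deviation must be positive")
  list(values = (x - m) / (2 * s), center = m, scale = s)
}

#' Build the design matrix, response and offset
#'
#' Metric covariates are two-SD standardized, binaries enter as 0/1,
#' interaction columns are products of the transformed parents, and region
#' dummies are added for every region except the reference (default: the
#' region with the lowest observed mean density). The offset is
#' `log(inhabitants/10^4)` or the log of a count column per the spec.
#'
#' @param table district data.frame.
#' @param spec a [model_spec()].
#' @param allow_missing_response build without a response column (used when
#'   simulating counts); the reference region must then be given explicitly.
#' @return List with `X` (full-column-rank design matrix), `y`, `offset`,
#'   `scaling` (per-metric center/scale records), `term_cols`, `ref_region`
#'   and the `spec`.
#' @export
build_design <- function(table, spec, allow_missing_response = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$metric, spec$binary, spec$region_col)
  if (spec$offset == "population") need <- c(need, "inhabitants")
  else need <- c(need, spec$offset)
  if (!allow_missing_response) need <- c(need, spec$response)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_domain("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(table)
  offset <- if (spec$offset == "population")
    log(table$inhabitants / 1e4) else log(table[[spec$offset]])
  y <- if (allow_missing_response && !spec$response %in% names(table))
    NULL else table[[spec$response]]

  region <- as.character(table[[spec$region_col]])
  levels <- sort(unique(region))
  if (any(tabulate(factor(region, levels)) == 0L))
    stop_domain("every region must contain at least one district")
  ref <- spec$ref_region
  if (is.null(ref)) {
    if (is.null(y))
      stop_domain("ref_region must be given when building without response")
    dens <- tapply(y / exp(offset), region, mean)
    ref <- names(dens)[which.min(dens)]
  } else if (!ref %in% levels) {
    stop_domain("reference region '", ref, "' not present")
  }

  scaling <- list()
  cols <- list("(Intercept)" = rep(1, n))
  for (v in spec$metric) {
    zs <- two_sd_standardize(table[[v]])
    scaling[[v]] <- list(center = zs$center, scale = zs$scale)
    cols[[v]] <- zs$values
  }
  for (v in spec$binary) {
    x <- table[[v]]
    if (!all(x %in% c(0, 1)))
      stop_domain("binary column '", v, "' must contain only 0/1")
    cols[[v]] <- as.numeric(x)
  }
  for (ia in spec$interactions) {
    cols[[paste(ia, collapse = ":")]] <- cols[[ia[1]]] * cols[[ia[2]]]
  }
  for (lv in setdiff(levels, ref)) {
    cols[[paste0("region", lv)]] <- as.numeric(region == lv)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_domain("design matrix is rank deficient; collinear columns: ",
                paste(bad, collapse = ", "))
  }
  term_cols <- c(spec$metric, spec$binary,
                 vapply(spec$interactions, paste, "", collapse = ":"))
  list(X = X, y = y, offset = offset, scaling = scaling,
       term_cols = term_cols, ref_region = ref, spec = spec)
}

#' Negative-binomial probability mass
#'
#' Mean-dispersion form with variance `mu + sigma*mu^2`:
#' `P(Y=y) = Gamma(y+1/sigma)/(Gamma(1/sigma) y!) (1/(1+sigma mu))^(1/sigma)
#' (sigma mu/(1+sigma mu))^y`. Computed on the log scale via `lbeta` so it
#' stays accurate for very small dispersion (the Poisson limit).
#'
#' @param y non-negative integer counts.
#' @param mu positive mean.
#' @param sigma positive dispersion.
#' @param log return log-probability.
#' @return (Log-)probabilities, recycled over the longest argument.
#' @export
nb_pmf <- function(y, mu, sigma, log = FALSE) {
  if (any(y < 0) || any(y != floor(y)))
    stop_domain("y must be non-negative integers")
  if (any(mu <= 0) || any(sigma <= 0))
    stop_domain("mu and sigma must be positive")
  th <- 1 / sigma
  # log choose(y+th-1, y) = -log(y) - lbeta(y, th), stable for large th
  coef <- ifelse(y == 0, 0, -base::log(y) - lbeta(y, th))
  lp <- coef - log1p(mu * sigma) / sigma +
    ifelse(y == 0, 0, y * (base::log(mu) - base::log(th + mu)))
  if (log) lp else exp(lp)
}

#' Zero-truncated negative-binomial log probability
#'
#' Log pmf of the negative binomial conditioned on `y >= 1`:
#' `log nb(y) - log(1 - nb(0))`. Districts with zero physicians do not
#' occur, so the likelihood must normalize over positive counts only.
#'
#' @param y integer counts `>= 1` (a zero signals a truncation violation
#'   upstream and is an error).
#' @inheritParams nb_pmf
#' @return Log-probabilities.
#' @export
ztnb_logpmf <- function(y, mu, sigma) {
  if (any(y < 1)) stop_domain("zero-truncated counts must be >= 1")
  lp0 <- -log1p(mu * sigma) / sigma        # log P(Y = 0)
  nb_pmf(y, mu, sigma, log = TRUE) - log1p(-exp(lp0))
}

# log-likelihood contributions and analytic gradient pieces.
# params = c(beta, log_sigma); mu_i = exp(X_i beta + offset_i).
ztnb_nll <- function(params, X, y, offset) {
  k <- ncol(X)
  beta <- params[seq_len(k)]
  sigma <- exp(params[k + 1L])
  eta <- drop(X %*% beta) + offset
  if (any(eta > 500)) return(sqrt(.Machine$double.xmax))
  mu <- exp(eta)
  nll <- -sum(ztnb_logpmf(y, mu, sigma))
  if (!is.finite(nll)) sqrt(.Machine$double.xmax) else nll
}

ztnb_nll_grad <- function(params, X, y, offset) {
  k <- ncol(X)
  beta <- params[seq_len(k)]
  ls <- params[k + 1L]
  sigma <- exp(ls)
  th <- 1 / sigma
  eta <- drop(X %*% beta) + offset
  eta <- pmin(eta, 500)
  mu <- exp(eta)
  lp0 <- -log1p(mu * sigma) / sigma
  P0 <- exp(lp0)
  om <- -expm1(lp0)                      # 1 - P0
  dl_dmu <- y / mu - (y + th) / (th + mu) - th * P0 / ((th + mu) * om)
  gbeta <- -drop(crossprod(X, dl_dmu * mu))
  dl_dth <- digamma(y + th) - digamma(th) + base::log(th / (th + mu)) + 1 -
    (y + th) / (th + mu) +
    P0 * (base::log(th / (th + mu)) + mu / (th + mu)) / om
  gls <- sum(dl_dth * th)               # d(-l)/dlogsigma = -sum(dl_dth)*(-th)
  g <- c(gbeta, gls)
  g[!is.finite(g)] <- 0
  g
}

# central finite-difference Jacobian of the analytic gradient
ztnb_hessian <- function(params, X, y, offset, h = 1e-5) {
  p <- length(params)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    step <- h * (1 + abs(params[j]))
    up <- dn <- params
    up[j] <- up[j] + step
    dn[j] <- dn[j] - step
    H[, j] <- (ztnb_nll_grad(up, X, y, offset) -
                 ztnb_nll_grad(dn, X, y, offset)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Optimizer settings for [ztnb_fit()]
#'
#' @param restarts jittered restarts after the deterministic start.
#' @param jitter_sd SD of the start jitter.
#' @param restart_seed seed making the jitters reproducible.
#' @param grad_tol gradient max-norm required at the optimum.
#' @param maxit iteration cap per optimizer call.
#' @param log_sigma_bounds box for the log-dispersion (the lower bound is
#'   the effective Poisson limit).
#' @return List of settings.
#' @export
ztnb_control <- function(restarts = 3L, jitter_sd = 0.1, restart_seed = 1L,
                         grad_tol = 1e-6, maxit = 1000L,
                         log_sigma_bounds = c(-12, 5)) {
  list(restarts = restarts, jitter_sd = jitter_sd,
       restart_seed = restart_seed, grad_tol = grad_tol, maxit = maxit,
       log_sigma_bounds = log_sigma_bounds)
}

#' Fit a zero-truncated negative-binomial GLM
#'
#' Maximum-likelihood fit of the count model with log link and offset:
#' L-BFGS-B on `(beta, log sigma)` with analytic gradients, a deterministic
#' start (`beta = 0` except the intercept at the log mean density,
#' `log sigma = 0`) plus seeded jittered restarts, followed by a Newton
#' polish until the gradient max-norm drops below `grad_tol`. Standard
#' errors come from the inverse finite-difference Hessian; p-values are
#' two-sided Wald against the standard normal.
#'
#' @param design as returned by [build_design()] (or a list with `X`, `y`,
#'   `offset`).
#' @param control a [ztnb_control()] list.
#' @return Object of class `ztnb_fit`: `coefficients`, `log_sigma`,
#'   `sigma`, `vcov`, `se`, `z`, `p`, `loglik`, `n`, `k`, `bic`,
#'   `convergence` (gradient norm, iterations, restarts, bound flag) and
#'   the design metadata (`scaling`, `term_cols`, `ref_region`, `spec`).
#' @export
ztnb_fit <- function(design, control = ztnb_control()) {
  X <- design$X; y <- design$y; offset <- design$offset
  if (is.null(y)) stop_domain("design carries no response")
  if (any(y < 1)) stop_domain("all responses must be >= 1 (zero-truncated)")
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1L) stop_domain("need more rows than parameters")
  start <- c(base::log(mean(y / exp(offset))), rep(0, k - 1L), 0)
  names(start) <- c(colnames(X), "log_sigma")
  starts <- list(start)
  if (control$restarts > 0L) {
    jit <- with_seed(control$restart_seed,
                     matrix(stats::rnorm(control$restarts * (k + 1L),
                                         sd = control$jitter_sd),
                            control$restarts))
    for (r in seq_len(control$restarts))
      starts[[r + 1L]] <- start + jit[r, ]
  }
  lower <- c(rep(-Inf, k), control$log_sigma_bounds[1])
  upper <- c(rep(Inf, k), control$log_sigma_bounds[2])
  best <- NULL
  iters <- 0L
  for (s in starts) {
    o <- try(stats::optim(s, ztnb_nll, ztnb_nll_grad, X = X, y = y,
                          offset = offset, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = control$maxit,
                                         factr = 10)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    iters <- iters + o$counts[1]
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop_domain("ztnb fit failed from every start")
  par <- best$par
  # Newton polish toward gradient max-norm <= grad_tol
  H <- NULL
  for (i in 1:25) {
    g <- ztnb_nll_grad(par, X, y, offset)
    g_eff <- g
    at_lo <- par[k + 1L] <= lower[k + 1L] + 1e-10 && g[k + 1L] > 0
    at_hi <- par[k + 1L] >= upper[k + 1L] - 1e-10 && g[k + 1L] < 0
    if (at_lo || at_hi) g_eff[k + 1L] <- 0
    if (max(abs(g_eff)) <= control$grad_tol) break
    H <- ztnb_hessian(par, X, y, offset)
    step <- try(solve(H, g_eff), silent = TRUE)
    if (inherits(step, "try-error")) break
    f0 <- ztnb_nll(par, X, y, offset)
    lam <- 1
    repeat {
      cand <- par - lam * step
      cand[k + 1L] <- min(max(cand[k + 1L], lower[k + 1L]), upper[k + 1L])
      if (ztnb_nll(cand, X, y, offset) <= f0 + 1e-12 * abs(f0)) {
        par <- cand; break
      }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (lam < 1e-8) break
  }
  g <- ztnb_nll_grad(par, X, y, offset)
  at_bound <- par[k + 1L] <= lower[k + 1L] + 1e-8 ||
    par[k + 1L] >= upper[k + 1L] - 1e-8
  g_eff <- g
  if (at_bound) g_eff[k + 1L] <- 0
  converged <- max(abs(g_eff)) <= control$grad_tol
  H <- ztnb_hessian(par, X, y, offset)
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(!is.finite(V)) ||
      any(diag(V) < 0)) {
    ev <- eigen(H, symmetric = TRUE)
    pos <- pmax(ev$values, max(ev$values) * 1e-12)
    V <- ev$vectors %*% diag(1 / pos, length(pos)) %*% t(ev$vectors)
    warning("Hessian not positive definite; covariance pseudo-inverted")
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(start), names(start))
  se <- sqrt(pmax(diag(V), 0))
  z <- par / se
  p <- 2 * stats::pnorm(-abs(z))
  ll <- -ztnb_nll(par, X, y, offset)
  kk <- k + 1L
  structure(list(
    coefficients = par[seq_len(k)], log_sigma = unname(par[k + 1L]),
    sigma = unname(exp(par[k + 1L])), vcov = V,
    se = se[seq_len(k)], z = z[seq_len(k)], p = p[seq_len(k)],
    se_log_sigma = unname(se[k + 1L]), p_log_sigma = unname(p[k + 1L]),
    loglik = ll, n = n, k = kk, bic = -2 * ll + kk * base::log(n),
    convergence = list(converged = converged,
                       grad_max_norm = max(abs(g_eff)),
                       iterations = unname(iters),
                       restarts = control$restarts,
                       sigma_at_bound = at_bound),
    scaling = design$scaling, term_cols = design$term_cols,
    ref_region = design$ref_region, spec = design$spec),
    class = "ztnb_fit")
  }

#' @export
print.ztnb_fit <- function(x, ...) {
  cat("Zero-truncated negative-binomial GLM (log link)\n")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, BIC = %.1f\n",
              x$n, x$k, x$loglik, x$bic))
  cat(sprintf("  sigma = %.5f (log_sigma = %.3f)%s\n", x$sigma, x$log_sigma,
              if (isTRUE(x$convergence$sigma_at_bound)) " [at bound]" else ""))
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$se, 4), z = round(x$z, 2),
                    p = signif(x$p, 3))
  print(utils::head(tab, 25))
  if (nrow(tab) > 25) cat("  ...", nrow(tab) - 25, "more rows\n")
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param fit a `ztnb_fit`.
#' @return data.frame with term, estimate, se, z, p.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "ztnb_fit"))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             z = unname(fit$z), p = unname(fit$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predicted physician density per 10 000 inhabitants
#'
#' Back-transforms a linear predictor (without the offset) to the expected
#' density per 10 000 inhabitants: `exp(eta)`, the untruncated mean. This
#' matches the published back-transformation arithmetic (e.g. a log density
#' of 1.919 corresponds to 6.81 specialists per 10 000). The truncated mean
#' `mu / (1 - P0)` is available via `truncated = TRUE`.
#'
#' @param fit a `ztnb_fit` with a population offset.
#' @param x named numeric vector over design columns; defaults to the
#'   baseline district (reference region, metric terms at their mean,
#'   binaries 0), i.e. the intercept alone.
#' @param truncated report the zero-truncated mean instead.
#' @return Expected density per 10 000 inhabitants.
#' @export
predicted_density <- function(fit, x = NULL, truncated = FALSE) {
  stopifnot(inherits(fit, "ztnb_fit"))
  eta <- if (is.null(x)) {
    unname(fit$coefficients["(Intercept)"])
  } else {
    bad <- setdiff(names(x), names(fit$coefficients))
    if (length(bad))
      stop_domain("unknown design columns: ", paste(bad, collapse = ", "))
    unname(fit$coefficients["(Intercept)"] +
             sum(fit$coefficients[names(x)] * x))
  }
  mu <- exp(eta)
  if (!truncated) return(mu)
  mu / -expm1(-log1p(mu * fit$sigma) / fit$sigma)
}
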