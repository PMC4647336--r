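# ---------------------------------------------------------------------------
# Back-transformation of fitted coefficients into reportable quantities:
# baseline densities per 10 000 inhabitants, density changes for a two-SD
# covariate increase, and net coefficients where an interaction modifies a
# main effect.
# ---------------------------------------------------------------------------

#' Density per 10 000 from a log density
#'
#' @param eta finite log density (linear predictor without offset).
#' @return `exp(eta)`, the density per 10 000 inhabitants (or the
#'   GP/specialist ratio for the ratio model).
#' @export
#' @examples
#' density_from_eta(1.919)   # 6.81 specialists per 10 000
#' density_from_eta(-0.178)  # GP/specialist ratio 0.837
density_from_eta <- function(eta) {
  if (any(!is.finite(eta))) stop_domain("eta must be finite")
  exp(eta)
}

#' Density change for a two-SD covariate increase
#'
#' Change in expected density per 10 000 when a two-SD-standardized
#' covariate rises by two standard deviations from the baseline district:
#' `exp(eta) * (exp(beta) - 1)`, identically
#' `density_from_eta(eta + beta) - density_from_eta(eta)`.
#'
#' @param baseline_eta baseline log density.
#' @param beta coefficient of the (two-SD-scaled or binary) term.
#' @return Density change per 10 000 inhabitants.
#' @export
#' @examples
#' two_sd_effect(1.919, 0.253)  # +1.96 specialists per 10 000
two_sd_effect <- function(baseline_eta, beta) {
  if (any(!is.finite(baseline_eta)) || any(!is.finite(beta)))
    stop_domain("inputs must be finite")
  exp(baseline_eta) * (exp(beta) - 1)
}

#' Net coefficient under an interaction
#'
#' Log-scale effect of a metric term in districts where the interacting
#' binary equals 1: the main-effect coefficient plus the interaction
#' coefficient.
#'
#' @param beta_main,beta_interaction coefficients.
#' @return `beta_main + beta_interaction`.
#' @export
#' @examples
#' net_effect_with_interaction(-0.136, 0.099)  # -0.037
net_effect_with_interaction <- function(beta_main, beta_interaction) {
  if (any(!is.finite(beta_main)) || any(!is.finite(beta_interaction)))
    stop_domain("inputs must be finite")
  beta_main + beta_interaction
}

#' Effect summary for one fitted model
#'
#' One row per term: coefficient, p-value, the density change for a two-SD
#' increase from the baseline district (reference region, metric terms at
#' their sample mean, binaries 0), and, where an interaction modifies the
#' term, the net coefficient and its density effect. The baseline row
#' reports the intercept's back-transformed density.
#'
#' @param fit a `ztnb_fit`.
#' @return Object of class `effect_summary`: a data.frame plus attributes
#'   `baseline_eta` and `baseline_density`.
#' @export
effect_table <- function(fit) {
  stopifnot(inherits(fit, "ztnb_fit"))
  eta0 <- unname(fit$coefficients["(Intercept)"])
  terms <- fit$term_cols
  miss <- setdiff(setdiff(terms, names(fit$coefficients)), character())
  if (length(miss))
    stop_domain("fit lacks coefficients for: ", paste(miss, collapse = ", "))
  inter <- terms[grepl(":", terms, fixed = TRUE)]
  rows <- lapply(terms, function(tm) {
    beta <- unname(fit$coefficients[tm])
    mods <- inter[vapply(strsplit(inter, ":", fixed = TRUE),
                         function(pp) tm %in% pp, TRUE)]
    net <- if (length(mods) == 1L && !grepl(":", tm, fixed = TRUE))
      net_effect_with_interaction(beta, unname(fit$coefficients[mods]))
    else NA_real_
    is_metric <- tm %in% names(fit$scaling)
    data.frame(term = tm, estimate = beta, p = unname(fit$p[tm]),
               scale_center = if (is_metric) fit$scaling[[tm]]$center
                              else NA_real_,
               scale_sd = if (is_metric) fit$scaling[[tm]]$scale
                          else NA_real_,
               density_effect = two_sd_effect(eta0, beta),
               net_estimate = net,
               net_density_effect = if (is.na(net)) NA_real_
                                    else two_sd_effect(eta0, net),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), estimate = numeric(), p = numeric(),
               scale_center = numeric(), scale_sd = numeric(),
               density_effect = numeric(), net_estimate = numeric(),
               net_density_effect = numeric(), stringsAsFactors = FALSE)
  attr(out, "baseline_eta") <- eta0
  attr(out, "baseline_density") <- density_from_eta(eta0)
  class(out) <- c("effect_summary", class(out))
  out
}

#' Render the final pipeline report
#'
#' Writes the machine-readable JSON and a human-readable CSV mirroring the
#' published table layout: per surviving term the estimate, p-value and
#' significance stars in each model, the effect columns, the per-model
#' first/final BIC, and the drop history. Output ordering is fixed, so
#' re-rendering from the same artifacts is byte-identical.
#'
#' @param state a completed `triple_model_state`.
#' @param out_json,out_csv output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list.
#' @export
render_report <- function(state, out_json = NULL, out_csv = NULL) {
  stopifnot(inherits(state, "triple_model_state"))
  sel <- selection_report(state)
  effects <- lapply(state$fits, effect_table)
  report <- list(
    models = lapply(names(state$fits), function(nm) {
      f <- state$fits[[nm]]
      list(model = nm, response = f$spec$response, offset = f$spec$offset,
           ref_region = f$ref_region,
           baseline_eta = attr(effects[[nm]], "baseline_eta"),
           baseline_density = attr(effects[[nm]], "baseline_density"),
           log_sigma = f$log_sigma, loglik = f$loglik, n = f$n, k = f$k,
           bic_first = unname(state$bic_first[[nm]]),
           bic_final = unname(f$bic),
           coefficients = coef_table(f),
           effects = as.data.frame(effects[[nm]]))
    }),
    selection = sel,
    history = state$history)
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (!is.null(out_csv))
    utils::write.csv(sel, out_csv, row.names = FALSE)
  invisible(report)
}
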