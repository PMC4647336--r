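# ---------------------------------------------------------------------------
# Cross-model backward stepwise selection. Three models share one term
# list: GP density, specialist density (both with log population offset)
# and the GP/specialist ratio (GP counts with a log specialist-count
# offset). A term is kept if it is significant at alpha in ANY model;
# removal proceeds one term at a time, dropping the candidate that is
# least significant everywhere, and main effects are protected while
# their interaction remains.
# ---------------------------------------------------------------------------

fit_triple <- function(table, specs, control = ztnb_control()) {
  lapply(specs, function(sp) ztnb_fit(build_design(table, sp), control))
}

make_specs <- function(terms, interactions, ref_region) {
  list(gp = default_model_spec("gp", terms, interactions, ref_region),
       sp = default_model_spec("sp", terms, interactions, ref_region),
       ratio = default_model_spec("ratio", terms, interactions, ref_region))
}

#' Initial three-model state over the full term list
#'
#' Builds and fits the GP-density, specialist-density and GP/specialist
#' ratio models over one shared term list (all candidate covariates plus
#' the population-density-by-city interaction by default).
#'
#' @param table district data.frame.
#' @param terms shared term list; default: the full default term set.
#' @param interactions list of interaction pairs.
#' @param ref_region reference region (default: chosen per model from the
#'   data).
#' @param control a [ztnb_control()].
#' @return Object of class `triple_model_state`: `terms`, `interactions`,
#'   `specs`, `fits`, an empty drop `history`, and the initial BICs.
#' @export
full_model_specs <- function(table,
                             terms = c(default_model_spec("gp")$metric,
                                       default_model_spec("gp")$binary),
                             interactions = list(c("pop_density", "city")),
                             ref_region = NULL,
                             control = ztnb_control()) {
  interactions <- Filter(function(ia) all(ia %in% terms), interactions)
  specs <- make_specs(terms, interactions, ref_region)
  fits <- fit_triple(table, specs, control)
  structure(list(terms = terms, interactions = interactions, specs = specs,
                 fits = fits,
                 history = data.frame(step = integer(), term = character(),
                                      p_gp = numeric(), p_sp = numeric(),
                                      p_ratio = numeric(),
                                      stringsAsFactors = FALSE),
                 bic_first = vapply(fits, `[[`, 0, "bic"),
                 control = control, table_name = deparse(substitute(table))),
            class = "triple_model_state")
}

term_column <- function(term) term  # terms map 1:1 onto design columns

term_pvalues <- function(term, fits) {
  vapply(fits, function(f) {
    p <- f$p[term_column(term)]
    if (is.na(p)) stop_domain("term '", term, "' absent from fit")
    unname(p)
  }, 0)
}

#' Keep-or-drop rule for one term
#'
#' A term is kept when it is significant at `alpha` in at least one of the
#' three models, so the models stay comparable. A main effect is never
#' droppable while an interaction built on it remains (hierarchy).
#'
#' @param term term name.
#' @param state a `triple_model_state` (or a list of three `ztnb_fit`s plus
#'   `interactions`).
#' @param alpha significance level (default 0.05).
#' @return `"keep"` or `"droppable"`.
#' @export
keep_rule <- function(term, state, alpha = 0.05) {
  parent_of_live_interaction <-
    any(vapply(state$interactions, function(ia) term %in% ia, TRUE))
  if (parent_of_live_interaction) return("keep")
  if (min(term_pvalues(term, state$fits)) < alpha) "keep" else "droppable"
}

candidate_terms <- function(state) {
  c(state$terms,
    vapply(state$interactions, paste, "", collapse = ":"))
}

#' Backward stepwise selection across the three models
#'
#' Starting from the fitted full state, iteratively removes the single
#' droppable term that is least significant everywhere (largest minimum
#' p-value across the three models; ties broken by reverse entry order),
#' refits all three models, and stops when every remaining term is kept by
#' [keep_rule()]. Region intercepts and the model intercept are never
#' candidates. Dropping an interaction frees its parents for later steps.
#'
#' @param table district data.frame (the data the state was fitted on).
#' @param state a `triple_model_state` from [full_model_specs()].
#' @param alpha significance level of the keep rule.
#' @return The final `triple_model_state` with the drop `history`,
#'   `bic_first` and `bic_final` per model.
#' @export
backward_stepwise <- function(table, state, alpha = 0.05) {
  stopifnot(inherits(state, "triple_model_state"))
  step <- 0L
  repeat {
    cands <- candidate_terms(state)
    status <- vapply(cands, keep_rule, "", state = state, alpha = alpha)
    droppable <- cands[status == "droppable"]
    if (!length(droppable)) break
    minp <- vapply(droppable, function(tm)
      min(term_pvalues(tm, state$fits)), 0)
    # largest min-p goes; ties: the later-entered term (reverse order) wins
    worst <- max(minp)
    victim <- rev(droppable[minp >= worst - 1e-15])[1]
    step <- step + 1L
    pv <- term_pvalues(victim, state$fits)
    state$history <- rbind(state$history,
                           data.frame(step = step, term = victim,
                                      p_gp = pv[["gp"]], p_sp = pv[["sp"]],
                                      p_ratio = pv[["ratio"]],
                                      stringsAsFactors = FALSE))
    if (grepl(":", victim, fixed = TRUE)) {
      state$interactions <- Filter(function(ia)
        paste(ia, collapse = ":") != victim, state$interactions)
    } else {
      state$terms <- setdiff(state$terms, victim)
    }
    state$specs <- make_specs(state$terms, state$interactions,
                              state$specs$gp$ref_region)
    state$fits <- fit_triple(table, state$specs, state$control)
  }
  state$bic_final <- vapply(state$fits, `[[`, 0, "bic")
  state
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Selection report table
#'
#' One row per surviving term with the estimate, p-value and significance
#' stars (`* < 0.05`, `** < 0.01`, `*** < 0.001`) in each of the three
#' models, with the first/final BIC per model attached as attributes.
#'
#' @param state a completed `triple_model_state`.
#' @return data.frame; attributes `bic_first`, `bic_final`, `history`.
#' @export
selection_report <- function(state) {
  stopifnot(inherits(state, "triple_model_state"))
  terms <- c("(Intercept)", candidate_terms(state))
  rows <- lapply(terms, function(tm) {
    est <- vapply(state$fits, function(f)
      unname(f$coefficients[tm]), 0)
    p <- vapply(state$fits, function(f) unname(f$p[tm]), 0)
    data.frame(term = tm,
               estimate_gp = est[["gp"]], p_gp = p[["gp"]],
               stars_gp = p_stars(p[["gp"]]),
               estimate_sp = est[["sp"]], p_sp = p[["sp"]],
               stars_sp = p_stars(p[["sp"]]),
               estimate_ratio = est[["ratio"]], p_ratio = p[["ratio"]],
               stars_ratio = p_stars(p[["ratio"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bic_first") <- state$bic_first
  attr(out, "bic_final") <-
    if (is.null(state$bic_final)) vapply(state$fits, `[[`, 0, "bic")
    else state$bic_final
  attr(out, "history") <- state$history
  out
}
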