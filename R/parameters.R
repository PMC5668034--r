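#' Construct a full per-arm parameter set
#'
#' A `model_parameters` object carries everything one arm of the Markov
#' model needs: the trastuzumab-arm baseline annual probabilities (overall
#' death, any DFS event, distant metastases) split into first-year and
#' subsequent-year values, the arm's effective hazard-ratio multipliers and
#' benefit duration, the first-year cardiac event probability, per-state
#' first/subsequent-year costs and utilities, trastuzumab acquisition
#' inputs (trastuzumab arm only), discount rates, the cohort start age and
#' a background-mortality life table.
#'
#' Treatment-effect convention: baselines are the trastuzumab-arm survival
#' functions; the control arm is derived by dividing the trastuzumab hazard
#' by the trial hazard ratio (HR < 1 means trastuzumab is protective, so the
#' control hazard is larger). After `benefit_duration` cycles the hazard
#' ratios revert to 1 and both arms share the trastuzumab baselines.
#' Scenarios with directly observed control-arm survival supply
#' `control_baseline`, used instead of the HR division during the benefit
#' period.
#'
#' @param arm `"trastuzumab"` or `"control"`.
#' @param p_os,p_dfs,p_dm Named numeric vectors `c(first =, subsequent =)`
#'   of annual probabilities (trastuzumab-arm baselines).
#' @param hr Named numeric vector `c(dfs =, os =, dm =)` of trial hazard
#'   ratios (trastuzumab vs control); ignored for the trastuzumab arm.
#' @param benefit_duration Cycles during which the treatment effect lasts.
#' @param hr_dm_after_lr Hazard ratio for distant metastases after local
#'   recurrence, applied on the rate scale.
#' @param p_cardiac First-year cardiac event probability in this arm.
#' @param control_baseline Optional list with elements `p_os`, `p_dfs`,
#'   `p_dm` (same shape as the baselines) for directly observed control-arm
#'   survival.
#' @param state_costs,utilities Lists with elements `dfs`, `lr`, `dm`, each
#'   `c(first =, subsequent =)`: annual cost (2012 euros) and utility
#'   weight, relative to time since entering the state.
#' @param cardiac_disutility One-cycle utility decrement for a first-year
#'   cardiac event.
#' @param cardiac_monitoring_cost First-year cardiac monitoring cost.
#' @param cardiac_monitoring_scope `"arm"` (monitoring cost applies to the
#'   whole trastuzumab arm) or `"events"` (to the cardiac-event fraction).
#' @param trastuzumab_cost Acquisition inputs, a list with
#'   `vials_per_cycle`, `n_administrations`, `vial_price`, `admin_price`,
#'   `her2_testing`; `NULL` for the control arm.
#' @param discount_costs,discount_effects Annual discount rates.
#' @param start_age Cohort age at model start (years).
#' @param life_table Background-mortality table ([synthetic_life_table()]
#'   by default).
#' @param dm_mortality `"derived"` (distant-metastasis death probability is
#'   derived each cycle so total deaths track the overall-survival input)
#'   or a fixed annual probability.
#' @param horizon `"lifetime"` (run to attained age 110) or a number of
#'   cycles.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(arm = c("trastuzumab", "control"),
                             p_os, p_dfs, p_dm,
                             hr = c(dfs = 1, os = 1, dm = 1),
                             benefit_duration = 8,
                             hr_dm_after_lr = 1,
                             p_cardiac = 0,
                             control_baseline = NULL,
                             state_costs,
                             utilities,
                             cardiac_disutility = 0,
                             cardiac_monitoring_cost = 0,
                             cardiac_monitoring_scope = c("arm", "events"),
                             trastuzumab_cost = NULL,
                             discount_costs = 0.04,
                             discount_effects = 0.015,
                             start_age = 55,
                             life_table = synthetic_life_table(),
                             dm_mortality = "derived",
                             horizon = "lifetime") {
  arm <- match.arg(arm)
  cardiac_monitoring_scope <- match.arg(cardiac_monitoring_scope)
  chk_prob_pair <- function(x, what) {
    if (!all(c("first", "subsequent") %in% names(x)) ||
        any(x < 0 | x > 1)) {
      stop(sprintf("%s must be c(first=, subsequent=) probabilities in [0,1]",
                   what), call. = FALSE)
    }
    x[c("first", "subsequent")]
  }
  p_os <- chk_prob_pair(p_os, "p_os")
  p_dfs <- chk_prob_pair(p_dfs, "p_dfs")
  p_dm <- chk_prob_pair(p_dm, "p_dm")
  stopifnot(all(hr > 0), benefit_duration >= 0, hr_dm_after_lr > 0,
            p_cardiac >= 0, p_cardiac <= 1,
            discount_costs >= 0, discount_effects >= 0, start_age >= 0)
  for (s in c("dfs", "lr", "dm")) {
    if (is.null(state_costs[[s]]) || any(state_costs[[s]] < 0)) {
      stop(sprintf("state_costs$%s must be non-negative c(first=, subsequent=)",
                   s), call. = FALSE)
    }
    if (is.null(utilities[[s]]) ||
        any(utilities[[s]] < 0 | utilities[[s]] > 1)) {
      stop(sprintf("utilities$%s must lie in [0, 1]", s), call. = FALSE)
    }
  }
  if (!identical(dm_mortality, "derived")) {
    stopifnot(is.numeric(dm_mortality), dm_mortality >= 0, dm_mortality <= 1)
  }
  structure(list(
    arm = arm, p_os = p_os, p_dfs = p_dfs, p_dm = p_dm,
    hr = hr, benefit_duration = benefit_duration,
    hr_dm_after_lr = hr_dm_after_lr, p_cardiac = p_cardiac,
    control_baseline = control_baseline,
    state_costs = state_costs, utilities = utilities,
    cardiac_disutility = cardiac_disutility,
    cardiac_monitoring_cost = cardiac_monitoring_cost,
    cardiac_monitoring_scope = cardiac_monitoring_scope,
    trastuzumab_cost = trastuzumab_cost,
    discount_costs = discount_costs, discount_effects = discount_effects,
    start_age = start_age, life_table = validate_life_table(life_table),
    dm_mortality = dm_mortality, horizon = horizon
  ), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("<model_parameters> arm = %s, start age %g, benefit %g y\n",
              x$arm, x$start_age, x$benefit_duration))
  cat(sprintf("  p_os %.4f/%.4f  p_dfs %.4f/%.4f  p_dm %.4f/%.4f  cardiac %.3f\n",
              x$p_os[1], x$p_os[2], x$p_dfs[1], x$p_dfs[2],
              x$p_dm[1], x$p_dm[2], x$p_cardiac))
  invisible(x)
}

# Pick the first-year or subsequent-year value for a model cycle.
pick_period <- function(pair, cycle_index) {
  unname(if (cycle_index <= 1L) pair[["first"]] else pair[["subsequent"]])
}

# Arm-effective annual probability for one endpoint at one cycle: the
# control arm divides the trastuzumab hazard by the trial HR during the
# benefit period (or uses its own observed baseline when supplied), then
# reverts to the shared baseline.
effective_probability <- function(params, endpoint, cycle_index) {
  base <- pick_period(params[[endpoint]], cycle_index)
  if (params$arm == "trastuzumab") return(base)
  if (cycle_index > params$benefit_duration) return(base)
  if (!is.null(params$control_baseline)) {
    return(pick_period(params$control_baseline[[endpoint]], cycle_index))
  }
  hr_key <- c(p_os = "os", p_dfs = "dfs", p_dm = "dm")[[endpoint]]
  apply_hazard_ratio(base, 1 / params$hr[[hr_key]], cycle_index,
                     params$benefit_duration)
}

#' Build per-arm model parameters for a scenario
#'
#' Resolves a scenario configuration (and, for PSA, a parameter draw) into a
#' complete [model_parameters()] object for one arm. Both arms of one
#' comparison should be built from the same draw so that shared parameters
#' remain perfectly correlated.
#'
#' @param config A `her2cea_config` from [load_scenario_config()] /
#'   [her2cea_example_config()].
#' @param arm `"trastuzumab"` or `"control"`.
#' @param draw Optional named list of sampled values keyed by config path,
#'   as produced by [sample_parameters()]; when `NULL` the deterministic
#'   means are used.
#' @param life_table Background-mortality table; defaults to the bundled
#'   synthetic table.
#' @return A [model_parameters()] object.
#' @export
build_scenario_parameters <- function(config,
                                      arm = c("trastuzumab", "control"),
                                      draw = NULL,
                                      life_table = synthetic_life_table()) {
  arm <- match.arg(arm)
  if (!inherits(config, "her2cea_config")) config <- validate_config(config)
  val <- function(path) {
    if (!is.null(draw) && path %in% names(draw)) return(draw[[path]])
    node <- config_get(config, path)
    if (is.null(node)) return(NULL)
    as_param_dist(node, path)$mean
  }
  pair <- function(prefix) {
    c(first = val(paste0(prefix, ".first")),
      subsequent = val(paste0(prefix, ".subsequent")))
  }
  te <- config$treatment_effect
  p_cardiac <- val("transitions.p_cardiac")
  if (arm == "control") {
    p_cardiac <- min(1, max(0, p_cardiac / te$rr_cardiac))
  }
  control_baseline <- NULL
  if (arm == "control" && !is.null(config$control_transitions)) {
    control_baseline <- list(
      p_os = pair("control_transitions.p_os"),
      p_dfs = pair("control_transitions.p_dfs"),
      p_dm = pair("control_transitions.p_dm"))
  }
  state_costs <- list(dfs = pair("state_costs.dfs"),
                      lr = pair("state_costs.lr"),
                      dm = pair("state_costs.dm"))
  if (arm == "control" && !is.null(config$control_state_costs$dm)) {
    state_costs$dm <- pair("control_state_costs.dm")
  }
  utilities <- list(dfs = pair("utilities.dfs"),
                    lr = pair("utilities.lr"),
                    dm = pair("utilities.dm"))
  trastuzumab_cost <- NULL
  if (arm == "trastuzumab") {
    trastuzumab_cost <- list(
      vials_per_cycle = val("trastuzumab.vials_per_cycle"),
      n_administrations = val("trastuzumab.n_administrations"),
      vial_price = val("trastuzumab.vial_price"),
      admin_price = val("trastuzumab.admin_price"),
      her2_testing = val("trastuzumab.her2_testing"))
  }
  model_parameters(
    arm = arm,
    p_os = pair("transitions.p_os"),
    p_dfs = pair("transitions.p_dfs"),
    p_dm = pair("transitions.p_dm"),
    hr = c(dfs = te$hr_dfs, os = te$hr_os, dm = te$hr_dm),
    benefit_duration = te$benefit_duration,
    hr_dm_after_lr = te$hr_dm_after_lr,
    p_cardiac = p_cardiac,
    control_baseline = control_baseline,
    state_costs = state_costs,
    utilities = utilities,
    cardiac_disutility = config$cardiac_disutility,
    cardiac_monitoring_cost = if (arm == "trastuzumab" ||
                                  config$cardiac_monitoring_scope == "events")
      val("cardiac_monitoring") else 0,
    cardiac_monitoring_scope = config$cardiac_monitoring_scope,
    trastuzumab_cost = trastuzumab_cost,
    discount_costs = config$discount$costs,
    discount_effects = config$discount$effects,
    start_age = config$start_age,
    life_table = life_table,
    dm_mortality = config$dm_mortality)
}
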