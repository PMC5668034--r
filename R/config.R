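#' Load a scenario configuration
#'
#' Scenario configurations are JSON files mirroring the model's input
#' tables: annual transition probabilities (with standard errors and
#' distribution families for PSA), treatment-effect hazard ratios with a
#' benefit duration, per-state annual costs for the first year in a state
#' and subsequent years, trastuzumab acquisition inputs, utilities,
#' discount rates and the willingness-to-pay threshold. Three example
#' configurations ship with the package (see [her2cea_example_config()]).
#'
#' @param path Path to a JSON configuration file.
#' @return A validated configuration list of class `her2cea_config`.
#' @export
load_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' Bundled example scenario configurations
#'
#' Returns the path of (or loads) one of the three shipped scenario
#' configurations: `real_world` (trastuzumab-arm inputs from routine-care
#' cohort estimates), `guideline` (the subgroup treated per the 2005 Dutch
#' guideline) and `trial` (both arms parameterised from trial survival).
#' Inputs that are not publicly printed (trial hazard ratios, cardiac event
#' probability, non-first-year utilities, guideline/trial survival tables)
#' are synthetic placeholders, flagged in the files' `synthetic_fields`
#' entry; see the package vignette.
#'
#' @param scenario One of `"real_world"`, `"guideline"`, `"trial"`.
#' @param load If `TRUE` (default) return the parsed config, else the path.
#' @return A `her2cea_config` list, or a file path.
#' @export
her2cea_example_config <- function(scenario = c("real_world", "guideline", "trial"),
                                   load = TRUE) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", paste0(scenario, ".json"),
                      package = "her2cea", mustWork = TRUE)
  if (load) load_scenario_config(path) else path
}

# Required dotted paths; the loader rejects configs missing any of them.
config_required_paths <- function() {
  c("scenario",
    "transitions.p_os.first", "transitions.p_os.subsequent",
    "transitions.p_dfs.first", "transitions.p_dfs.subsequent",
    "transitions.p_dm.first", "transitions.p_dm.subsequent",
    "transitions.p_cardiac",
    "treatment_effect.hr_dfs", "treatment_effect.hr_os",
    "treatment_effect.hr_dm", "treatment_effect.rr_cardiac",
    "treatment_effect.benefit_duration",
    "state_costs.dfs.first", "state_costs.dfs.subsequent",
    "state_costs.lr.first", "state_costs.lr.subsequent",
    "state_costs.dm.first", "state_costs.dm.subsequent",
    "cardiac_monitoring",
    "trastuzumab.vials_per_cycle", "trastuzumab.n_administrations",
    "trastuzumab.vial_price", "trastuzumab.admin_price",
    "utilities.dfs.first", "utilities.dfs.subsequent",
    "utilities.lr.first", "utilities.lr.subsequent",
    "utilities.dm.first", "utilities.dm.subsequent",
    "cardiac_disutility",
    "discount.costs", "discount.effects",
    "start_age", "wtp")
}

config_get <- function(cfg, path) {
  node <- cfg
  for (key in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(node) || is.null(node[[key]])) return(NULL)
    node <- node[[key]]
  }
  node
}

config_set <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  # optional blocks may be absent from a config and created by an override
  optional_roots <- c("control_state_costs", "control_transitions",
                      "dm_mortality", "cardiac_monitoring_scope")
  if (is.null(config_get(cfg, path)) && !keys[1L] %in% optional_roots) {
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  cfg[[keys]] <- value
  cfg
}

#' Apply named overrides to a scenario configuration
#'
#' @param cfg A `her2cea_config`.
#' @param overrides Named list; names are dotted parameter paths that must
#'   already exist in the config (e.g. `"treatment_effect.benefit_duration"`,
#'   `"trastuzumab.vial_price"`), values their replacements. A distribution
#'   entry (`mean`/`se`/`dist`) can be replaced wholesale or field-wise
#'   (e.g. `"state_costs.dm.first.mean"`).
#' @return The modified, revalidated configuration.
#' @export
apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0L) return(cfg)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("overrides must be a fully named list", call. = FALSE)
  }
  for (path in names(overrides)) {
    cfg <- config_set(cfg, path, overrides[[path]])
  }
  validate_config(unclass(cfg))
}

validate_config <- function(cfg) {
  missing <- Filter(function(p) is.null(config_get(cfg, p)),
                    config_required_paths())
  if (length(missing) > 0L) {
    stop("scenario config is missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!cfg$scenario %in% c("real_world", "guideline", "trial")) {
    stop("scenario must be one of real_world, guideline, trial",
         call. = FALSE)
  }
  # optional fields with documented defaults
  if (is.null(cfg$treatment_effect$hr_dm_after_lr)) {
    cfg$treatment_effect$hr_dm_after_lr <- 1
    message("config: hr_dm_after_lr not set; defaulting to 1 ",
            "(local recurrence confers no extra distant-metastasis risk)")
  }
  if (is.null(cfg$trastuzumab$her2_testing)) {
    cfg$trastuzumab$her2_testing <- 0
    message("config: HER2 testing cost not set; defaulting to 0")
  }
  if (is.null(cfg$dm_mortality)) cfg$dm_mortality <- "derived"
  if (is.null(cfg$cardiac_monitoring_scope)) cfg$cardiac_monitoring_scope <- "arm"
  if (!cfg$cardiac_monitoring_scope %in% c("arm", "events")) {
    stop("cardiac_monitoring_scope must be 'arm' or 'events'", call. = FALSE)
  }
  stopifnot(cfg$discount$costs >= 0, cfg$discount$effects >= 0,
            cfg$wtp >= 0, cfg$start_age >= 0,
            cfg$treatment_effect$benefit_duration >= 0)
  structure(cfg, class = "her2cea_config")
}

# Coerce a config node ({mean,se,dist} list or bare number) to param_dist.
as_param_dist <- function(node, name) {
  if (inherits(node, "param_dist")) return(node)
  if (is.numeric(node) && length(node) == 1L) {
    return(param_dist(node, family = "fixed", name = name))
  }
  if (is.list(node) && !is.null(node$mean)) {
    fam <- if (is.null(node$dist)) "fixed" else tolower(node$dist)
    se <- if (is.null(node$se)) NA_real_ else node$se
    return(param_dist(node$mean, se, fam, name = name))
  }
  stop(sprintf("cannot interpret '%s' as a parameter distribution", name),
       call. = FALSE)
}

# All stochastic (or potentially stochastic) scalar inputs, in the canonical
# sampling order. The order is part of the reproducibility contract: PSA
# draws consume uniforms in exactly this sequence.
config_dist_paths <- function() {
  c("transitions.p_os.first", "transitions.p_os.subsequent",
    "transitions.p_dfs.first", "transitions.p_dfs.subsequent",
    "transitions.p_dm.first", "transitions.p_dm.subsequent",
    "transitions.p_cardiac",
    "control_transitions.p_os.first", "control_transitions.p_os.subsequent",
    "control_transitions.p_dfs.first", "control_transitions.p_dfs.subsequent",
    "control_transitions.p_dm.first", "control_transitions.p_dm.subsequent",
    "state_costs.dfs.first", "state_costs.dfs.subsequent",
    "state_costs.lr.first", "state_costs.lr.subsequent",
    "state_costs.dm.first", "state_costs.dm.subsequent",
    "control_state_costs.dm.first", "control_state_costs.dm.subsequent",
    "cardiac_monitoring",
    "trastuzumab.vials_per_cycle", "trastuzumab.n_administrations")
}
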