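#' Run a full scenario experiment end to end
#'
#' Builds both arms from a scenario configuration, runs the cohort engine
#' and the economic accumulator, computes the incremental
#' cost-effectiveness result, and optionally a probabilistic sensitivity
#' analysis with CEAC and EVPI. Three experiment settings reproduce the
#' analysis plan: the base case per scenario, the shorter (4-year)
#' treatment-benefit duration, and treatment-dependent distant-metastasis
#' costs (both via `overrides`).
#'
#' @param scenario `"real_world"`, `"guideline"` or `"trial"`; ignored when
#'   `config` is supplied.
#' @param config Optional `her2cea_config`; defaults to the bundled example
#'   config for `scenario`.
#' @param overrides Named list of dotted-path parameter substitutions
#'   applied before the run (see [apply_overrides()]), e.g.
#'   `list("treatment_effect.benefit_duration" = 4)`.
#' @param analysis `"deterministic"` or `"psa"`.
#' @param n_iterations PSA iterations (analysis default 10,000).
#' @param seed PSA seed.
#' @param life_table Background-mortality table.
#' @param wtp_grid CEAC grid (euros/QALY).
#' @return A `her2cea_experiment` list: `config`, per-arm `params`,
#'   `traces`, `outcomes`, the `cea` result, the reporting `table`
#'   ([cea_table()]), and for PSA runs `psa`, `ceac`, `evpi_pp`,
#'   `evpi_population` plus a reproducibility `manifest`.
#' @examples
#' ex <- run_experiment("real_world")
#' ex$cea
#' @export
run_experiment <- function(scenario = c("real_world", "guideline", "trial"),
                           config = NULL,
                           overrides = list(),
                           analysis = c("deterministic", "psa"),
                           n_iterations = 10000,
                           seed = 1,
                           life_table = synthetic_life_table(),
                           wtp_grid = seq(0, 200000, by = 1000)) {
  analysis <- match.arg(analysis)
  if (is.null(config)) {
    scenario <- match.arg(scenario)
    config <- her2cea_example_config(scenario)
  } else if (!inherits(config, "her2cea_config")) {
    config <- validate_config(config)
  }
  config <- apply_overrides(config, overrides)

  params <- lapply(stats::setNames(nm = c("trastuzumab", "control")),
                   function(a) build_scenario_parameters(config, a,
                                                         life_table = life_table))
  traces <- lapply(params, run_cohort)
  outcomes <- Map(accumulate, traces, params)
  cea <- compute_icer(outcomes$trastuzumab, outcomes$control,
                      wtp = config$wtp)
  result <- list(config = config, params = params, traces = traces,
                 outcomes = outcomes, cea = cea,
                 table = cea_table(outcomes$trastuzumab, outcomes$control),
                 analysis = analysis)
  if (analysis == "psa") {
    psa <- run_psa(config, n_iterations = n_iterations, seed = seed,
                   life_table = life_table)
    result$psa <- psa
    result$ceac <- ceac(psa, wtp_grid)
    result$evpi_pp <- evpi_per_patient(psa, wtp = config$wtp)
    result$evpi_population <- population_evpi(result$evpi_pp)
    result$manifest <- list(scenario = config$scenario, seed = seed,
                            n_iterations = n_iterations, wtp = config$wtp,
                            overrides = overrides,
                            timestamp = format(Sys.time(), tz = "UTC"))
  }
  structure(result, class = "her2cea_experiment")
}

#' @export
print.her2cea_experiment <- function(x, ...) {
  cat(sprintf("<her2cea_experiment> scenario: %s (%s)\n",
              x$config$scenario, x$analysis))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$cea)
  if (!is.null(x$psa)) {
    cat(sprintf("\nPSA: %d iterations; P(cost-effective at %.0f EUR/QALY) = %.3f\n",
                nrow(x$psa), x$config$wtp,
                x$ceac$prob_cost_effective[which.min(abs(x$ceac$wtp -
                                                           x$config$wtp))]))
    cat(sprintf("EVPI per patient %.0f EUR; population EVPI %.0f EUR\n",
                x$evpi_pp, x$evpi_population))
  }
  invisible(x)
}

#' One-way sensitivity sweep over a single parameter
#'
#' Re-runs the deterministic analysis for each value of one parameter,
#' holding everything else at the base case.
#'
#' @param scenario Scenario name or a `her2cea_config` via `config`.
#' @param parameter_path Dotted config path of the parameter to vary (e.g.
#'   `"treatment_effect.benefit_duration"`,
#'   `"trastuzumab.vial_price"`).
#' @param values Numeric (or list) values to substitute.
#' @param config Optional configuration overriding `scenario`.
#' @param ... Passed to [run_experiment()].
#' @return A data frame with one row per value: `value`, `delta_cost`,
#'   `delta_qaly`, `icer`, `label`; the experiment objects are attached as
#'   attribute `experiments`.
#' @export
oneway_sweep <- function(scenario = "real_world", parameter_path, values,
                         config = NULL, ...) {
  stopifnot(length(values) >= 1L)
  runs <- lapply(values, function(v) {
    ov <- stats::setNames(list(v), parameter_path)
    run_experiment(scenario, config = config, overrides = ov,
                   analysis = "deterministic", ...)
  })
  out <- data.frame(
    value = if (is.numeric(values)) values else seq_along(values),
    delta_cost = vapply(runs, function(r) r$cea$delta_cost, numeric(1L)),
    delta_qaly = vapply(runs, function(r) r$cea$delta_qaly, numeric(1L)),
    icer = vapply(runs, function(r) r$cea$icer, numeric(1L)),
    label = vapply(runs, function(r) r$cea$label, character(1L)))
  attr(out, "parameter_path") <- parameter_path
  attr(out, "experiments") <- runs
  out
}
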