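#' Sample one set of model parameters from their distributions
#'
#' Draws every stochastic input of a scenario configuration (Beta for
#' probabilities, Gamma for costs and resource counts; fixed inputs are
#' returned as-is) using the session RNG. Uniform deviates are consumed in
#' a canonical, documented order (the order of
#' `her2cea:::config_dist_paths()`, skipping paths absent from the config),
#' so a run is reproducible across platforms at the sequence level. Both
#' arms of a comparison are built from the same draw, keeping shared
#' parameters perfectly correlated; the hazard ratios carry no distribution
#' in the base configuration and stay fixed.
#'
#' @param config A `her2cea_config`.
#' @param se_scale Multiplier on every SE before sampling; `se_scale = 0`
#'   collapses all draws to their means (used to study how decision
#'   uncertainty vanishes as evidence accumulates).
#' @return A named list of sampled values keyed by config path, suitable
#'   for the `draw` argument of [build_scenario_parameters()].
#' @export
sample_parameters <- function(config, se_scale = 1) {
  if (!inherits(config, "her2cea_config")) config <- validate_config(config)
  draw <- list()
  for (path in config_dist_paths()) {
    node <- config_get(config, path)
    if (is.null(node)) next
    dist <- as_param_dist(node, path)
    draw[[path]] <- draw_param(dist, u = stats::runif(1L),
                               se_scale = se_scale)
  }
  draw
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: for each iteration one
#' parameter set is drawn with [sample_parameters()], both arms are run
#' through the cohort engine and the economic accumulator with that same
#' draw, and discounted totals are recorded.
#'
#' @param config A `her2cea_config` (see [her2cea_example_config()]).
#' @param n_iterations Number of Monte Carlo iterations (the analysis
#'   default is 10,000; tests use fewer).
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @param se_scale Multiplier on all SEs (see [sample_parameters()]).
#' @param life_table Background-mortality table.
#' @return A `psa_output` data frame with one row per iteration and columns
#'   `iteration`, `cost_trastuzumab`, `qaly_trastuzumab`, `cost_control`,
#'   `qaly_control`, `delta_cost`, `delta_qaly`; attributes `seed`,
#'   `wtp` and `scenario`.
#' @export
run_psa <- function(config, n_iterations = 1000, seed = 1, se_scale = 1,
                    life_table = synthetic_life_table()) {
  stopifnot(n_iterations >= 1)
  if (!inherits(config, "her2cea_config")) config <- validate_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  res <- matrix(NA_real_, nrow = n_iterations, ncol = 4L,
                dimnames = list(NULL, c("cost_trastuzumab",
                                        "qaly_trastuzumab",
                                        "cost_control", "qaly_control")))
  for (i in seq_len(n_iterations)) {
    draw <- sample_parameters(config, se_scale = se_scale)
    out <- tryCatch({
      arms <- lapply(c("trastuzumab", "control"), function(a) {
        p <- build_scenario_parameters(config, a, draw = draw,
                                       life_table = life_table)
        accumulate(run_cohort(p), p)
      })
      c(arms[[1L]]$total_cost, arms[[1L]]$total_qaly,
        arms[[2L]]$total_cost, arms[[2L]]$total_qaly)
    }, error = function(e) {
      stop(sprintf("PSA iteration %d failed: %s\ndraw: %s", i,
                   conditionMessage(e),
                   paste(sprintf("%s=%.4g", names(draw), unlist(draw)),
                         collapse = ", ")), call. = FALSE)
    })
    res[i, ] <- out
  }
  psa <- data.frame(iteration = seq_len(n_iterations), res)
  psa$delta_cost <- psa$cost_trastuzumab - psa$cost_control
  psa$delta_qaly <- psa$qaly_trastuzumab - psa$qaly_control
  structure(psa, seed = seed, wtp = config$wtp, scenario = config$scenario,
            class = c("psa_output", "data.frame"))
}

#' @export
print.psa_output <- function(x, ...) {
  cat(sprintf("<psa_output> %d iterations, scenario %s, seed %d\n",
              nrow(x), attr(x, "scenario") %||% "?", attr(x, "seed")))
  cat(sprintf("  mean incremental cost : %10.0f EUR\n", mean(x$delta_cost)))
  cat(sprintf("  mean incremental QALY : %10.3f\n", mean(x$delta_qaly)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which trastuzumab has positive incremental net monetary benefit
#' (`wtp x dQALY - dCost > 0`).
#'
#' @param psa A `psa_output` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid, euros per QALY (default 0 to
#'   200,000 in steps of 1,000).
#' @return A data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 1000)) {
  stopifnot(length(wtp_grid) >= 1L, nrow(psa) >= 1L)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * psa$delta_qaly - psa$delta_cost > 0)
  }, numeric(1L))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Per-patient expected value of perfect information
#'
#' The expected opportunity loss of deciding under current uncertainty:
#' the mean over PSA iterations of the best achievable net monetary
#' benefit, minus the net monetary benefit of the strategy that is best on
#' average. Always non-negative; zero when there is no decision
#' uncertainty.
#'
#' @param psa A `psa_output`.
#' @param wtp Willingness-to-pay threshold, euros per QALY (default the
#'   config's threshold recorded in the PSA, or 80,000).
#' @return EVPI per patient, in euros.
#' @export
evpi_per_patient <- function(psa, wtp = attr(psa, "wtp") %||% 80000) {
  stopifnot(nrow(psa) >= 1L)
  nmb_tr <- wtp * psa$qaly_trastuzumab - psa$cost_trastuzumab
  nmb_ct <- wtp * psa$qaly_control - psa$cost_control
  mean(pmax(nmb_tr, nmb_ct)) - max(mean(nmb_tr), mean(nmb_ct))
}

#' Effective population for population EVPI
#'
#' @param annual_incidence Eligible patients per year (the base analysis
#'   uses 1,743 = 14,070 incident breast cancers x 17.7\% HER2-positive x
#'   70\% chemotherapy-eligible).
#' @param horizon Expected life span of the technology in years (default
#'   10).
#' @param discount Annual discount rate for future cohorts (default 4\%).
#' @return An object of class `effective_population`.
#' @export
effective_population <- function(annual_incidence = 1743, horizon = 10,
                                 discount = 0.04) {
  stopifnot(annual_incidence >= 0, horizon >= 0, discount >= 0)
  structure(list(annual_incidence = annual_incidence, horizon = horizon,
                 discount = discount),
            class = "effective_population")
}

#' Population expected value of perfect information
#'
#' Multiplies the per-patient EVPI by the discounted number of patients
#' affected by the decision over the technology's life span:
#' `sum_{t=1..horizon} incidence / (1 + discount)^(t-1)` (first-year cohort
#' undiscounted by default; `first_year_discounted = TRUE` uses exponent
#' `t`).
#'
#' @param evpi_pp Per-patient EVPI in euros (>= 0).
#' @param pop An [effective_population()].
#' @param first_year_discounted Whether the first annual cohort is already
#'   discounted one year.
#' @return Population EVPI in euros.
#' @export
population_evpi <- function(evpi_pp, pop = effective_population(),
                            first_year_discounted = FALSE) {
  stopifnot(evpi_pp >= 0, inherits(pop, "effective_population"))
  if (pop$horizon == 0) return(0)
  expo <- if (first_year_discounted) seq_len(pop$horizon) else
    seq_len(pop$horizon) - 1
  evpi_pp * pop$annual_incidence * sum((1 + pop$discount)^(-expo))
}
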