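#' Discount factor for a model cycle
#'
#' Cycle 1 is undiscounted; cycle `t` is discounted by
#' `(1 + rate)^-(t - 1)`.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle_index Cycle number(s), 1-based.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(rate, cycle_index) {
  stopifnot(rate >= 0, all(cycle_index >= 1))
  (1 + rate)^(-(cycle_index - 1))
}

#' Half-cycle-corrected occupancy
#'
#' Events are assumed to happen on average mid-cycle, so person-time in a
#' state during a cycle is approximated by the mean of the occupancies at
#' the cycle's start and end boundaries (the trapezoid rule applied to the
#' trace).
#'
#' @param value_at_start,value_at_end Occupancy at the two boundaries.
#' @return The corrected occupancy, `(start + end) / 2`.
#' @export
half_cycle_value <- function(value_at_start, value_at_end) {
  (value_at_start + value_at_end) / 2
}

#' First-year trastuzumab acquisition cost
#'
#' One year of adjuvant trastuzumab costs
#' `n_administrations x (vials_per_cycle x vial_price + admin_price) +
#' her2_testing`, reflecting drug cost per administration (with spill, via
#' the observed vial count), day-care administration cost and the one-off
#' HER2 determination (IHC/FISH).
#'
#' @param inputs List with `vials_per_cycle`, `n_administrations`,
#'   `vial_price`, `admin_price` and optionally `her2_testing` (default 0).
#' @return Total acquisition cost in euros.
#' @examples
#' trastuzumab_acquisition_cost(list(vials_per_cycle = 3,
#'   n_administrations = 15, vial_price = 605, admin_price = 257))
#' @export
trastuzumab_acquisition_cost <- function(inputs) {
  her2 <- if (is.null(inputs$her2_testing)) 0 else inputs$her2_testing
  with(inputs, {
    stopifnot(vials_per_cycle >= 0, n_administrations >= 0,
              vial_price >= 0, admin_price >= 0, her2 >= 0)
    n_administrations * (vials_per_cycle * vial_price + admin_price) + her2
  })
}

#' Assemble an economic outcome from its components
#'
#' Container for discounted totals by category; the grand totals are always
#' the exact sums of the categories, so a table of per-category results
#' reproduces its own totals by summation.
#'
#' @param costs Named numeric: `trastuzumab`, `cardiac`, `dfs`, `lr`, `dm`
#'   (euros, discounted).
#' @param ly Named numeric life years by state: `dfs`, `lr`, `dm`
#'   (discounted).
#' @param qaly Named numeric QALYs: `cardiac` (the disutility contribution,
#'   <= 0), `dfs`, `lr`, `dm` (discounted).
#' @return An object of class `economic_outcome` with elements `costs`,
#'   `ly`, `qaly`, `total_cost`, `total_ly`, `total_qaly`.
#' @export
economic_outcome <- function(costs, ly, qaly) {
  need <- function(x, nm, what) {
    if (!all(nm %in% names(x))) {
      stop(sprintf("%s must be named over: %s", what,
                   paste(nm, collapse = ", ")), call. = FALSE)
    }
    x[nm]
  }
  costs <- need(costs, c("trastuzumab", "cardiac", "dfs", "lr", "dm"), "costs")
  ly <- need(ly, c("dfs", "lr", "dm"), "ly")
  qaly <- need(qaly, c("cardiac", "dfs", "lr", "dm"), "qaly")
  structure(list(costs = costs, ly = ly, qaly = qaly,
                 total_cost = sum(costs), total_ly = sum(ly),
                 total_qaly = sum(qaly)),
            class = "economic_outcome")
}

#' @export
print.economic_outcome <- function(x, ...) {
  cat("<economic_outcome> (discounted)\n")
  comp <- data.frame(
    category = c("trastuzumab", "cardiac", "dfs", "lr", "dm", "total"),
    cost = round(unname(c(x$costs, x$total_cost))),
    ly = round(c(NA, NA, unname(x$ly), x$total_ly), 3),
    qaly = round(c(NA, unname(x$qaly), x$total_qaly), 3))
  print(comp, row.names = FALSE)
  invisible(x)
}

#' Discounted, half-cycle-corrected costs, life years and QALYs
#'
#' Converts a cohort trace into an [economic_outcome()]. Per cycle, state
#' occupancies are half-cycle corrected ([half_cycle_value()] of successive
#' boundaries) and weighted by the per-state annual cost and utility.
#' First-year rates apply to the year of entry into a state (the tunnel
#' compartments `lr1`/`dm1`; for DFS, cycle 1, since the whole cohort
#' enters DFS at model start) and subsequent-year rates thereafter. Costs
#' are discounted at the cost rate, life years and QALYs at the effect
#' rate, with cycle 1 undiscounted.
#'
#' Cycle-1 additions: the trastuzumab acquisition cost (trastuzumab arm),
#' the cardiac monitoring cost (whole trastuzumab arm by default, or the
#' cardiac-event fraction when the monitoring scope is `"events"`), and the
#' one-cycle cardiac disutility applied to the cardiac-event fraction of
#' the arm.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params The [model_parameters()] the trace was generated from.
#' @return An [economic_outcome()].
#' @export
accumulate <- function(trace, params) {
  stopifnot(is.data.frame(trace), inherits(params, "model_parameters"))
  n_cycles <- nrow(trace) - 1L
  zero <- economic_outcome(
    costs = c(trastuzumab = 0, cardiac = 0, dfs = 0, lr = 0, dm = 0),
    ly = c(dfs = 0, lr = 0, dm = 0),
    qaly = c(cardiac = 0, dfs = 0, lr = 0, dm = 0))
  if (n_cycles < 1L) return(zero)

  t <- seq_len(n_cycles)
  df_cost <- discount_factor(params$discount_costs, t)
  df_eff <- discount_factor(params$discount_effects, t)
  hcc <- function(col) half_cycle_value(col[t], col[t + 1L])
  h <- lapply(trace[occupancy_states[1:5]], hcc)

  sc <- params$state_costs
  ut <- params$utilities
  first_cycle <- t == 1L
  c_dfs <- ifelse(first_cycle, sc$dfs[["first"]], sc$dfs[["subsequent"]])
  u_dfs <- ifelse(first_cycle, ut$dfs[["first"]], ut$dfs[["subsequent"]])

  cost_dfs <- sum(h$dfs * c_dfs * df_cost)
  cost_lr <- sum((h$lr1 * sc$lr[["first"]] + h$lr2 * sc$lr[["subsequent"]]) *
                   df_cost)
  cost_dm <- sum((h$dm1 * sc$dm[["first"]] + h$dm2 * sc$dm[["subsequent"]]) *
                   df_cost)
  qaly_dfs <- sum(h$dfs * u_dfs * df_eff)
  qaly_lr <- sum((h$lr1 * ut$lr[["first"]] + h$lr2 * ut$lr[["subsequent"]]) *
                   df_eff)
  qaly_dm <- sum((h$dm1 * ut$dm[["first"]] + h$dm2 * ut$dm[["subsequent"]]) *
                   df_eff)
  ly_dfs <- sum(h$dfs * df_eff)
  ly_lr <- sum((h$lr1 + h$lr2) * df_eff)
  ly_dm <- sum((h$dm1 + h$dm2) * df_eff)

  cardiac_fraction <- attr(trace, "cardiac_fraction")
  if (is.null(cardiac_fraction)) cardiac_fraction <- params$p_cardiac
  cost_cardiac <- if (params$cardiac_monitoring_scope == "events") {
    params$cardiac_monitoring_cost * cardiac_fraction
  } else {
    params$cardiac_monitoring_cost
  }
  qaly_cardiac <- -params$cardiac_disutility * cardiac_fraction * df_eff[1L]
  cost_trastuzumab <- if (is.null(params$trastuzumab_cost)) 0 else {
    trastuzumab_acquisition_cost(params$trastuzumab_cost) * df_cost[1L]
  }

  economic_outcome(
    costs = c(trastuzumab = cost_trastuzumab, cardiac = cost_cardiac,
              dfs = cost_dfs, lr = cost_lr, dm = cost_dm),
    ly = c(dfs = ly_dfs, lr = ly_lr, dm = ly_dm),
    qaly = c(cardiac = qaly_cardiac, dfs = qaly_dfs, lr = qaly_lr,
             dm = qaly_dm))
}
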