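#' Generate a synthetic patient-level cohort
#'
#' Emulates the statistical structure the estimation stage assumes for a
#' routine-care breast-cancer cohort: piecewise-exponential event times
#' (one rate for the first year, one thereafter) for three latent
#' processes — locoregional/contralateral recurrence, distant metastases
#' and death — with uniform administrative right-censoring, a first-year
#' cardiac-event Bernoulli indicator, and per-state annual cost draws with
#' Gamma-like skew. The observed recurrence-free (DFS-event) time is the
#' earlier of the LR and DM times; distant metastases occurring after
#' death are unobserved. Control-arm hazards are the trastuzumab hazards
#' divided by the trial hazard ratios (HR < 1 means higher control
#' hazards).
#'
#' This generator emulates the design of a real-world cohort; it does not
#' reproduce any real patient data.
#'
#' @param true_probs List of annual probabilities defining the truth, with
#'   elements `p_os`, `p_dfs`, `p_dm`, each `c(first =, subsequent =)`,
#'   and `p_cardiac`. Defaults are the real-world trastuzumab-arm
#'   magnitudes of the model's input table.
#' @param n Number of patients.
#' @param arm `"trastuzumab"` or `"control"`.
#' @param hr Hazard ratios `c(dfs =, os =, dm =)` used to derive control
#'   hazards; `rr_cardiac` likewise for the cardiac probability.
#' @param rr_cardiac Relative risk of a first-year cardiac event.
#' @param censor_range Administrative censoring window in years (uniform;
#'   default `c(3.8, 6.8)`, matching staggered accrual over ~3 years with
#'   a fixed follow-up cut-off).
#' @param cost_model Optional list of [param_dist()]-style lists per state
#'   and period (defaults to the real-world cost table) from which each
#'   patient's annual cost record per (state, period) is drawn.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A data frame of class `synthetic_cohort` with one row per
#'   patient: `id`, `arm`, observed `time_dfs_event` / `event_dfs`,
#'   `time_dm` / `event_dm`, `time_death` / `event_death` (times censored
#'   at the administrative cut-off and, for DFS/DM endpoints, at death),
#'   `censor_time`, `cardiac_event_year1`, and per-(state, period) cost
#'   columns `cost_<state>_<period>`.
#' @export
generate_cohort <- function(true_probs = list(
                              p_os = c(first = 0.000, subsequent = 0.026),
                              p_dfs = c(first = 0.016, subsequent = 0.054),
                              p_dm = c(first = 0.003, subsequent = 0.041),
                              p_cardiac = 0.125),
                            n = 1000,
                            arm = c("trastuzumab", "control"),
                            hr = c(dfs = 1, os = 1, dm = 1),
                            rr_cardiac = 1,
                            censor_range = c(3.8, 6.8),
                            cost_model = default_cost_model(),
                            seed = 1) {
  arm <- match.arg(arm)
  stopifnot(n >= 1, all(hr > 0), rr_cardiac > 0,
            censor_range[1L] >= 0, censor_range[2L] >= censor_range[1L])
  set.seed(seed)

  rate_pair <- function(p) c(first = rate_from_prob(p[["first"]]),
                             subsequent = rate_from_prob(p[["subsequent"]]))
  r_os <- rate_pair(true_probs$p_os)
  r_dfs <- rate_pair(true_probs$p_dfs)
  r_dm <- rate_pair(true_probs$p_dm)
  # cause-specific LR rate so that min(LR, DM) has the composite DFS rate
  r_lr <- pmax(r_dfs - r_dm, 0)  # keeps the first/subsequent names
  p_cardiac <- true_probs$p_cardiac
  if (arm == "control") {
    r_os <- r_os / hr[["os"]]
    r_lr <- r_lr / hr[["dfs"]]
    r_dm <- r_dm / hr[["dm"]]
    p_cardiac <- min(1, p_cardiac / rr_cardiac)
  }

  # piecewise-exponential sampler by hazard inversion: rate r1 on [0,1),
  # r2 beyond; a unit-exponential cumulative-hazard target is inverted.
  rpwexp <- function(n, r1, r2) {
    h <- stats::rexp(n)
    within1 <- r1 > 0 & h < r1
    t <- numeric(n)
    t[within1] <- h[within1] / r1
    t[!within1] <- if (r2 > 0) 1 + (h[!within1] - r1) / r2 else Inf
    t
  }
  t_lr <- rpwexp(n, r_lr[["first"]], r_lr[["subsequent"]])
  t_dm <- rpwexp(n, r_dm[["first"]], r_dm[["subsequent"]])
  t_death <- rpwexp(n, r_os[["first"]], r_os[["subsequent"]])
  censor <- stats::runif(n, censor_range[1L], censor_range[2L])
  cardiac <- stats::runif(n) < p_cardiac

  obs <- function(t_event, cutoff) {
    time <- pmin(t_event, cutoff)
    list(time = time, event = t_event <= cutoff)
  }
  fu_death <- obs(t_death, censor)                       # death censored administratively
  cut_dfs <- pmin(censor, t_death)                       # DFS/DM censored at death too
  fu_dfs <- obs(pmin(t_lr, t_dm), cut_dfs)
  fu_dm <- obs(t_dm, cut_dfs)

  out <- data.frame(
    id = seq_len(n), arm = arm,
    time_dfs_event = fu_dfs$time, event_dfs = fu_dfs$event,
    time_dm = fu_dm$time, event_dm = fu_dm$event,
    time_death = fu_death$time, event_death = fu_death$event,
    censor_time = censor,
    cardiac_event_year1 = cardiac)
  # Per-patient cost spread: the cost table's SEs are standard errors of
  # the mean at the source cohort's size (~230 trastuzumab-treated
  # patients), so the per-patient SD is se * sqrt(230).
  n_ref <- 230
  for (state in names(cost_model)) {
    for (period in names(cost_model[[state]])) {
      d <- as_param_dist(cost_model[[state]][[period]],
                         paste(state, period, sep = "_"))
      col <- paste0("cost_", state, "_", period)
      out[[col]] <- if (d$family == "fixed") rep(d$mean, n) else {
        sh <- gamma_moments(d$mean, d$se * sqrt(n_ref))
        stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
      }
    }
  }
  structure(out, true_probs = true_probs,
            class = c("synthetic_cohort", "data.frame"))
}

# Real-world per-state annual cost table (mean, SE of the mean at the
# cohort's scale, Gamma), reused as the generator's default cost model.
default_cost_model <- function() {
  list(
    dfs = list(first = list(mean = 12776, se = 798.14, dist = "gamma"),
               subsequent = list(mean = 1237, se = 107.49, dist = "gamma")),
    lr = list(first = list(mean = 12777, se = 2203.85, dist = "gamma"),
              subsequent = list(mean = 14149, se = 4679.22, dist = "gamma")),
    dm = list(first = list(mean = 30165, se = 2339.46, dist = "gamma"),
              subsequent = list(mean = 47959, se = 13877.79, dist = "gamma")))
}

#' Estimate model inputs from a patient-level cohort
#'
#' The maximum-likelihood estimator for an exponential hazard is events
#' divided by person-time; the first-year and subsequent-year strata are
#' fitted separately by splitting each patient's follow-up at t = 1.
#' Annual probabilities are `1 - exp(-rate)`. State cost means and
#' standard errors of the mean are computed from the per-patient cost
#' records, and the first-year cardiac fraction from the event indicator.
#'
#' @param cohort A data frame from [generate_cohort()] (or any table with
#'   the same columns).
#' @return A list with `transitions` (elements `p_os`, `p_dfs`, `p_dm`,
#'   each `c(first =, subsequent =)`, plus `p_cardiac`), `rates` (the
#'   underlying hazard estimates), `state_costs` (per state/period lists
#'   of `mean`, `se`, `dist = "gamma"`) and `n`. Strata with zero
#'   person-time yield `NA` with a warning naming the endpoint.
#' @export
estimate_inputs <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  fit_endpoint <- function(time, event, label) {
    pt_first <- sum(pmin(time, 1))
    ev_first <- sum(event & time <= 1)
    pt_subs <- sum(pmax(time - 1, 0))
    ev_subs <- sum(event & time > 1)
    rate_of <- function(ev, pt, stratum) {
      if (pt <= 0) {
        warning(sprintf("no person-time for %s (%s year stratum)",
                        label, stratum), call. = FALSE)
        return(NA_real_)
      }
      ev / pt
    }
    c(first = rate_of(ev_first, pt_first, "first"),
      subsequent = rate_of(ev_subs, pt_subs, "subsequent"))
  }
  rates <- list(
    os = fit_endpoint(cohort$time_death, cohort$event_death, "overall survival"),
    dfs = fit_endpoint(cohort$time_dfs_event, cohort$event_dfs,
                       "disease-free survival"),
    dm = fit_endpoint(cohort$time_dm, cohort$event_dm, "distant metastases"))
  probs <- lapply(rates, function(r) {
    out <- r
    ok <- !is.na(r)
    out[ok] <- prob_from_rate(r[ok])
    out
  })
  cost_cols <- grep("^cost_", names(cohort), value = TRUE)
  state_costs <- list()
  for (col in cost_cols) {
    parts <- strsplit(sub("^cost_", "", col), "_")[[1L]]
    state <- parts[1L]
    period <- parts[2L]
    x <- cohort[[col]]
    state_costs[[state]][[period]] <- list(
      mean = mean(x), se = stats::sd(x) / sqrt(length(x)), dist = "gamma")
  }
  list(
    transitions = list(p_os = probs$os, p_dfs = probs$dfs, p_dm = probs$dm,
                       p_cardiac = mean(cohort$cardiac_event_year1)),
    rates = rates,
    state_costs = state_costs,
    n = nrow(cohort))
}

#' Turn cohort estimates into a scenario configuration
#'
#' Closes the loop between the estimation stage and the decision model:
#' replaces the transition, cardiac and state-cost entries of a scenario
#' configuration with the estimates from [estimate_inputs()], leaving the
#' treatment effect, utilities, prices and analysis settings untouched.
#'
#' @param estimates Output of [estimate_inputs()].
#' @param base_config Configuration supplying the non-estimated fields
#'   (default: the bundled real-world config).
#' @param se_probs Standard errors for the estimated probabilities are not
#'   tracked by the rate estimator here; they are set to 0 (fixed) unless
#'   supplied.
#' @return A `her2cea_config`.
#' @export
estimates_to_config <- function(estimates,
                                base_config = her2cea_example_config("real_world"),
                                se_probs = 0) {
  cfg <- unclass(base_config)
  put <- function(path, mean, se, dist) {
    config_set(cfg, path, list(mean = unname(mean), se = se, dist = dist))
  }
  tr <- estimates$transitions
  for (ep in c("p_os", "p_dfs", "p_dm")) {
    for (period in c("first", "subsequent")) {
      cfg <- put(sprintf("transitions.%s.%s", ep, period),
                 tr[[ep]][[period]], se_probs,
                 if (se_probs > 0) "beta" else "fixed")
    }
  }
  cfg <- config_set(cfg, "transitions.p_cardiac",
                    list(mean = tr$p_cardiac, se = 0, dist = "fixed"))
  for (state in names(estimates$state_costs)) {
    for (period in names(estimates$state_costs[[state]])) {
      est <- estimates$state_costs[[state]][[period]]
      cfg <- put(sprintf("state_costs.%s.%s", state, period),
                 est$mean, est$se, "gamma")
    }
  }
  validate_config(cfg)
}
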