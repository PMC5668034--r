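#' @name markov_engine
#' @title Annual-cycle cohort simulation
#'
#' @description
#' The engine moves a closed cohort through four health states — disease
#' free (DFS), local recurrence (LR), distant metastases (DM) and dead — in
#' one-year cycles. To support costs and utilities that differ between the
#' first year in a state and subsequent years, LR and DM are internally
#' split into entry-year tunnel compartments (`lr1`/`dm1`) and
#' beyond-first-year compartments (`lr2`/`dm2`): entrants spend exactly one
#' cycle in the tunnel, then move on if they survive. Flow is forward-only
#' (no recovery from LR or DM) and dead is absorbing.
#'
#' Competing risks within a cycle are resolved on the rate scale: each exit
#' probability is converted to a hazard rate, the rates are summed, the
#' total exit probability is `1 - exp(-sum)` and it is allocated to causes
#' proportionally to their rates, so total exits can never exceed the state
#' occupancy.
#'
#' Deaths among DFS and LR occupants follow the age-specific background
#' life table. Deaths among DM occupants are, by default, derived each
#' cycle so that the cohort's total death flow tracks the overall-survival
#' input: excess deaths = max(0, overall death probability x alive -
#' background deaths), attributed to DM occupants and capped at probability
#' 1 (a fixed DM death probability can be configured instead).
NULL

occupancy_states <- c("dfs", "lr1", "lr2", "dm1", "dm2", "dead")

# Rate-based competing-risk allocation of exit probabilities.
compete_exits <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  if (all(p == 0)) return(p)
  if (any(p == 1)) {          # certain exit: split among the certain causes
    w <- as.numeric(p == 1)
    return(stats::setNames(w / sum(w), names(p)))
  }
  r <- -log1p(-p)
  total <- sum(r)
  (1 - exp(-total)) * r / total
}

# Per-cycle, arm-effective transition probabilities.
cycle_probabilities <- function(params, cycle_index) {
  p_os <- effective_probability(params, "p_os", cycle_index)
  p_dfs <- effective_probability(params, "p_dfs", cycle_index)
  p_dm <- effective_probability(params, "p_dm", cycle_index)
  list(
    p_os = p_os,
    p_dm = p_dm,
    p_lr = derive_lr_probability(p_dfs, p_dm),
    p_dm_after_lr = 1 - (1 - p_dm)^params$hr_dm_after_lr,
    q_bg = background_mortality(params$life_table, params$start_age,
                                cycle_index))
}

#' Advance the cohort occupancy by one cycle
#'
#' @param occupancy Named numeric vector over
#'   `c("dfs","lr1","lr2","dm1","dm2","dead")`, non-negative and summing
#'   to 1.
#' @param params A [model_parameters()] object.
#' @param cycle_index Model cycle being executed (1-based).
#' @return The occupancy after the cycle, with an attribute `flows` holding
#'   the incident fractions `c(new_lr =, new_dm =, deaths =)`.
#' @export
transition_step <- function(occupancy, params, cycle_index) {
  stopifnot(setequal(names(occupancy), occupancy_states))
  occ <- occupancy[occupancy_states]
  if (any(occ < -1e-12) || abs(sum(occ) - 1) > 1e-9) {
    stop("occupancy must be non-negative and sum to 1", call. = FALSE)
  }
  pr <- cycle_probabilities(params, cycle_index)

  f_dfs <- occ[["dfs"]] *
    compete_exits(c(lr = pr$p_lr, dm = pr$p_dm, dead = pr$q_bg))
  lr_tot <- occ[["lr1"]] + occ[["lr2"]]
  f_lr <- lr_tot * compete_exits(c(dm = pr$p_dm_after_lr, dead = pr$q_bg))

  dm_tot <- occ[["dm1"]] + occ[["dm2"]]
  if (identical(params$dm_mortality, "derived")) {
    alive <- occ[["dfs"]] + lr_tot + dm_tot
    target_deaths <- pr$p_os * alive
    bg_deaths <- f_dfs[["dead"]] + f_lr[["dead"]]
    p_dm_death <- if (dm_tot > 0) {
      min(1, max(0, target_deaths - bg_deaths) / dm_tot)
    } else 0
  } else {
    p_dm_death <- params$dm_mortality
  }
  dm_deaths <- dm_tot * p_dm_death

  new_lr <- f_dfs[["lr"]]
  new_dm <- f_dfs[["dm"]] + f_lr[["dm"]]
  deaths <- f_dfs[["dead"]] + f_lr[["dead"]] + dm_deaths
  out <- c(dfs = occ[["dfs"]] - sum(f_dfs),
           lr1 = new_lr,
           lr2 = lr_tot - sum(f_lr),
           dm1 = new_dm,
           dm2 = dm_tot - dm_deaths,
           dead = occ[["dead"]] + deaths)
  if (any(out < -1e-9)) {
    stop(sprintf("cycle %d: competing-risk exits exceed occupancy (%s)",
                 cycle_index,
                 paste(sprintf("%s=%.3g", names(out), out), collapse = ", ")),
         call. = FALSE)
  }
  out <- pmax(out, 0)
  attr(out, "flows") <- c(new_lr = new_lr, new_dm = new_dm, deaths = deaths)
  out
}

#' Run the cohort model to its lifetime horizon
#'
#' Starts with the whole cohort disease free at cycle 0 and iterates
#' [transition_step()] until the dead fraction reaches `1 - 1e-6` or the
#' cohort attains age `max_age` (default 110), whichever comes first. A
#' numeric `horizon` in the parameter set caps the number of cycles
#' instead.
#'
#' @param params A [model_parameters()] object.
#' @param max_age Age cap guarding against non-terminating models.
#' @return A `cohort_trace`: a data frame with one row per cycle boundary
#'   `0..T` and columns `cycle`, the six occupancy compartments, aggregate
#'   `lr`/`dm`/`alive`, and incident fractions `new_lr`/`new_dm` (the flow
#'   during the cycle ending at that boundary). The first-year
#'   cardiac-event fraction is attached as attribute `cardiac_fraction`.
#' @export
run_cohort <- function(params, max_age = 110) {
  stopifnot(inherits(params, "model_parameters"))
  max_cycles <- if (identical(params$horizon, "lifetime")) {
    max(1L, as.integer(ceiling(max_age - params$start_age)))
  } else {
    as.integer(params$horizon)
  }
  occ <- c(dfs = 1, lr1 = 0, lr2 = 0, dm1 = 0, dm2 = 0, dead = 0)
  rows <- matrix(NA_real_, nrow = max_cycles + 1L,
                 ncol = length(occupancy_states),
                 dimnames = list(NULL, occupancy_states))
  new_lr <- new_dm <- numeric(max_cycles + 1L)
  rows[1L, ] <- occ
  t_final <- 0L
  for (t in seq_len(max_cycles)) {
    occ <- transition_step(occ, params, t)
    flows <- attr(occ, "flows")
    rows[t + 1L, ] <- occ
    new_lr[t + 1L] <- flows[["new_lr"]]
    new_dm[t + 1L] <- flows[["new_dm"]]
    t_final <- t
    if (occ[["dead"]] >= 1 - 1e-6) break
  }
  if (occ[["dead"]] < 0.05 && t_final == max_cycles) {
    warning(sprintf(
      "cohort not absorbed at the horizon cap (attained age %g, dead %.3f)",
      params$start_age + t_final, occ[["dead"]]), call. = FALSE)
  }
  keep <- seq_len(t_final + 1L)
  trace <- data.frame(cycle = keep - 1L, rows[keep, , drop = FALSE],
                      new_lr = new_lr[keep], new_dm = new_dm[keep])
  trace$lr <- trace$lr1 + trace$lr2
  trace$dm <- trace$dm1 + trace$dm2
  trace$alive <- 1 - trace$dead
  structure(trace, cardiac_fraction = params$p_cardiac,
            class = c("cohort_trace", "data.frame"))
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d cycles, final dead fraction %.4f, first-year cardiac fraction %.3f\n",
              max(x$cycle), x$dead[nrow(x)], attr(x, "cardiac_fraction")))
  print.data.frame(utils::head(as.data.frame(x)[,
    c("cycle", "dfs", "lr", "dm", "dead", "new_lr", "new_dm")], 10L),
    row.names = FALSE, digits = 4)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
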