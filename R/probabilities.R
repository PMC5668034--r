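#' Convert an annual probability to a hazard rate
#'
#' Under an exponential survival function, an annual event probability
#' \eqn{p} corresponds to a constant hazard rate \eqn{r = -\log(1 - p)}
#' per year. This is the inverse of [prob_from_rate()].
#'
#' @param p Annual event probability, in `[0, 1)`.
#' @return Hazard rate per year (non-negative).
#' @examples
#' rate_from_prob(0.026)
#' prob_from_rate(rate_from_prob(0.026))
#' @export
rate_from_prob <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("annual probability must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 1, na.rm = TRUE)) {
    stop("annual probability of 1 implies a non-finite hazard rate",
         call. = FALSE)
  }
  -log1p(-p)
}

#' Convert a hazard rate to an annual probability
#'
#' @param rate Hazard rate per year (non-negative).
#' @return Annual event probability `1 - exp(-rate)`.
#' @seealso [rate_from_prob()]
#' @export
prob_from_rate <- function(rate) {
  stopifnot(is.numeric(rate))
  if (any(rate < 0, na.rm = TRUE)) {
    stop("hazard rate must be non-negative", call. = FALSE)
  }
  -expm1(-rate)
}

#' Apply a hazard ratio to an annual probability for a bounded duration
#'
#' The treatment effect acts multiplicatively on the hazard scale:
#' \eqn{p' = 1 - (1 - p)^{\mathrm{hr}}}. The effect is assumed to last
#' `benefit_duration` model cycles; beyond that horizon the hazard ratio
#' reverts to 1 and the probability is returned unchanged.
#'
#' @param p Annual probability in `[0, 1)`.
#' @param hr Hazard ratio, strictly positive.
#' @param cycle_index Model cycle (1-based) at which the probability is used.
#' @param benefit_duration Number of cycles during which the hazard ratio
#'   applies (default 8).
#' @return Adjusted annual probability.
#' @examples
#' apply_hazard_ratio(0.2, 0.5, cycle_index = 1)     # 1 - 0.8^0.5
#' apply_hazard_ratio(0.026, 2, cycle_index = 9)     # beyond benefit: 0.026
#' @export
apply_hazard_ratio <- function(p, hr, cycle_index, benefit_duration = 8) {
  stopifnot(length(hr) == 1L, is.finite(hr), hr > 0,
            length(cycle_index) == 1L, cycle_index >= 1)
  if (any(p < 0 | p >= 1)) {
    stop("annual probability must lie in [0, 1)", call. = FALSE)
  }
  if (cycle_index > benefit_duration) {
    return(p)
  }
  1 - (1 - p)^hr
}

#' Annual local-recurrence probability from composite event probabilities
#'
#' The model parameterises recurrence through two survival endpoints: the
#' annual probability of any recurrence event (`1 - DFS`) and the annual
#' probability of distant metastases (`1 - DM`). The locoregional /
#' contralateral / new-primary (LR) probability is their difference,
#' floored at zero (in trial-based inputs the DFS event probability can be
#' smaller than the DM probability, in which case the LR state is unused).
#'
#' @param p_dfs_event Annual probability of any disease-free-survival event.
#' @param p_dm_event Annual probability of distant metastases.
#' @return Annual LR probability, `max(0, p_dfs_event - p_dm_event)`.
#' @examples
#' derive_lr_probability(0.054, 0.041)  # 0.013
#' derive_lr_probability(0.03, 0.05)    # 0: trial-style inputs, LR unused
#' @export
derive_lr_probability <- function(p_dfs_event, p_dm_event) {
  stopifnot(p_dfs_event >= 0, p_dfs_event <= 1,
            p_dm_event >= 0, p_dm_event <= 1)
  pmax(0, p_dfs_event - p_dm_event)
}
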