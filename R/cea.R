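#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes incremental cost, life years and QALYs of a new strategy versus
#' a reference, and classifies the cost-effectiveness plane quadrant:
#' \describe{
#'   \item{NE (dC > 0, dE > 0)}{numeric ICER = dC / dE}
#'   \item{SE (dC < 0, dE > 0)}{`"dominant"` — cheaper and more effective}
#'   \item{NW (dC > 0, dE < 0)}{`"dominated"` — dearer and less effective}
#'   \item{SW (dC < 0, dE < 0)}{numeric ratio with `sw_flag = TRUE`, since a
#'     bare south-west ICER inverts the usual decision rule}
#'   \item{dE = 0}{`"dominated"`, `"dominant"` or `"equivalent"` per the
#'     sign of dC}
#' }
#'
#' @param outcome_new,outcome_ref [economic_outcome()] objects computed
#'   from the same parameter draw.
#' @param wtp Willingness-to-pay threshold (euros per QALY) used for the
#'   reported net monetary benefit; default 80,000.
#' @return A `cea_result` with elements `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer` (numeric or `NA` when labelled), `label` (`"icer"`,
#'   `"dominant"`, `"dominated"`, `"equivalent"`), `sw_flag`, `nmb`, `wtp`.
#' @examples
#' a <- economic_outcome(costs = c(trastuzumab = 31080, cardiac = 467,
#'                                 dfs = 22000, lr = 9000, dm = 180000),
#'                       ly = c(dfs = 11.7, lr = 0.9, dm = 6.6),
#'                       qaly = c(cardiac = -0.016, dfs = 9.3, lr = 0.64,
#'                                dm = 3.96))
#' b <- economic_outcome(costs = c(trastuzumab = 0, cardiac = 0,
#'                                 dfs = 20600, lr = 7500, dm = 211000),
#'                       ly = c(dfs = 10.2, lr = 0.72, dm = 7.4),
#'                       qaly = c(cardiac = -0.003, dfs = 8.1, lr = 0.51,
#'                                dm = 4.48))
#' compute_icer(a, b)
#' @export
compute_icer <- function(outcome_new, outcome_ref, wtp = 80000) {
  stopifnot(inherits(outcome_new, "economic_outcome"),
            inherits(outcome_ref, "economic_outcome"))
  dc <- outcome_new$total_cost - outcome_ref$total_cost
  de <- outcome_new$total_qaly - outcome_ref$total_qaly
  dl <- outcome_new$total_ly - outcome_ref$total_ly
  sw_flag <- FALSE
  if (de == 0) {
    icer <- NA_real_
    label <- if (dc > 0) "dominated" else if (dc < 0) "dominant" else
      "equivalent"
  } else if (dc >= 0 && de > 0) {
    icer <- dc / de
    label <- "icer"
  } else if (dc < 0 && de > 0) {
    icer <- NA_real_
    label <- "dominant"
  } else if (dc > 0 && de < 0) {
    icer <- NA_real_
    label <- "dominated"
  } else {  # dc <= 0, de < 0: south-west quadrant
    icer <- dc / de
    label <- "icer"
    sw_flag <- TRUE
  }
  structure(list(delta_cost = dc, delta_qaly = de, delta_ly = dl,
                 icer = icer, label = label, sw_flag = sw_flag,
                 nmb = nmb_at(wtp, dc, de), wtp = wtp,
                 outcome_new = outcome_new, outcome_ref = outcome_ref),
            class = "cea_result")
}

#' Incremental net monetary benefit at a willingness-to-pay threshold
#'
#' @param wtp Willingness to pay, euros per QALY.
#' @param delta_cost,delta_qaly Incremental cost and QALYs, or a
#'   `cea_result` passed as `delta_cost`.
#' @return `wtp * delta_qaly - delta_cost`.
#' @export
nmb_at <- function(wtp, delta_cost, delta_qaly) {
  if (inherits(delta_cost, "cea_result")) {
    r <- delta_cost
    delta_cost <- r$delta_cost
    delta_qaly <- r$delta_qaly
  }
  wtp * delta_qaly - delta_cost
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  incremental cost : %10.0f EUR\n", x$delta_cost))
  cat(sprintf("  incremental LYs  : %10.3f\n", x$delta_ly))
  cat(sprintf("  incremental QALYs: %10.3f\n", x$delta_qaly))
  if (x$label == "icer") {
    cat(sprintf("  ICER             : %10.0f EUR/QALY%s\n", round(x$icer),
                if (x$sw_flag) "  [south-west quadrant]" else ""))
  } else {
    cat(sprintf("  result           : %s\n", x$label))
  }
  cat(sprintf("  NMB at %.0f EUR/QALY: %.0f EUR\n", x$wtp, x$nmb))
  invisible(x)
}

#' Results table in the canonical reporting layout
#'
#' Lays out per-arm discounted costs, life years and QALYs by category,
#' with the totals obtained by summation of the categories, mirroring the
#' standard base-case reporting table of the analysis.
#'
#' @param outcome_trastuzumab,outcome_control [economic_outcome()] objects.
#' @return A data frame with columns `category`, `cost_trastuzumab`,
#'   `ly_trastuzumab`, `qaly_trastuzumab`, `cost_control`, `ly_control`,
#'   `qaly_control`.
#' @export
cea_table <- function(outcome_trastuzumab, outcome_control) {
  one <- function(o, suffix) {
    d <- data.frame(
      category = c("trastuzumab_treatment", "cardiac_event_monitoring",
                   "disease_free", "local_recurrence", "distant_metastases",
                   "total"),
      cost = unname(c(o$costs, o$total_cost)),
      ly = c(NA, NA, unname(o$ly), o$total_ly),
      qaly = c(NA, unname(o$qaly), o$total_qaly))
    names(d)[-1L] <- paste(names(d)[-1L], suffix, sep = "_")
    d
  }
  merge(one(outcome_trastuzumab, "trastuzumab"),
        one(outcome_control, "control"), by = "category", sort = FALSE)
}
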