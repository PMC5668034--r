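#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_table Data frame from [ceac()] (columns `wtp`,
#'   `prob_cost_effective`), or a named list of such tables to overlay
#'   several scenarios.
#' @param wtp_line Optional vertical reference at a willingness-to-pay
#'   threshold (default 80,000 euros/QALY).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_table, wtp_line = 80000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac() needs the ggplot2 package", call. = FALSE)
  }
  if (is.data.frame(ceac_table)) ceac_table <- list(scenario = ceac_table)
  df <- do.call(rbind, lapply(names(ceac_table), function(nm) {
    cbind(ceac_table[[nm]], scenario = nm)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp,
                                        y = .data$prob_cost_effective,
                                        colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability trastuzumab is cost-effective",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(wtp_line)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_line, linetype = "dashed")
  }
  p
}

#' Scatter the PSA iterations on the cost-effectiveness plane
#'
#' @param psa A `psa_output` from [run_psa()].
#' @param wtp Threshold line drawn through the origin (default 80,000).
#' @return A ggplot object.
#' @export
plot_psa <- function(psa, wtp = 80000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_psa() needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(as.data.frame(psa),
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)") +
    ggplot2::theme_minimal()
}
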