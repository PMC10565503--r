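#' Goodness-of-fit plots
#'
#' Observed-vs-predicted and residual-vs-time panels from a [kpd_gof()]
#' table.
#'
#' @param gof A `kpd_gof` data frame.
#' @param which `"obs_pred"` (observations against population predictions)
#'   or `"wres_time"` (weighted residuals against time).
#' @return A ggplot object.
#' @export
plot_gof <- function(gof, which = c("obs_pred", "wres_time")) {
  which <- match.arg(which)
  stopifnot(inherits(gof, "kpd_gof"))
  if (which == "obs_pred") {
    ggplot2::ggplot(gof, ggplot2::aes(x = .data$pred, y = .data$dv)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "Population prediction (g/cm²)",
                    y = "Observed BMD (g/cm²)")
  } else {
    ggplot2::ggplot(gof, ggplot2::aes(x = .data$time, y = .data$wres)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "Time (months)", y = "Weighted residual")
  }
}

#' Visual-predictive-check plot
#'
#' Observed percentiles (points/lines) over simulated percentile bands.
#'
#' @param vpc A `kpd_vpc` data frame from [kpd_vpc()].
#' @return A ggplot object.
#' @export
plot_vpc <- function(vpc) {
  stopifnot(inherits(vpc, "kpd_vpc"))
  vpc$pct <- factor(vpc$percentile)
  ggplot2::ggplot(vpc, ggplot2::aes(x = .data$time, group = .data$pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_median), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "Time (months)", y = "BMD (g/cm²)",
                  title = sprintf("VPC (%d simulations)", attr(vpc, "n_sims")))
}

#' APR incidence histogram by dose
#'
#' Pooled incidence per dose group with exact confidence intervals.
#'
#' @param table A `kpd_apr` table (see [read_apr_table()]).
#' @param conf Confidence level for the intervals.
#' @return A ggplot object.
#' @export
plot_apr_incidence <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "kpd_apr"))
  doses <- sort(unique(table$dose_mg[table$valid]))
  rows <- do.call(rbind, lapply(doses, function(d)
    as.data.frame(pooled_incidence(table, d, conf))))
  ggplot2::ggplot(rows, ggplot2::aes(x = factor(.data$dose_mg),
                                     y = .data$incidence_pct)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower_pct,
                                        ymax = .data$upper_pct), width = 0.2) +
    ggplot2::labs(x = "Dose (mg)", y = "APR incidence (%)")
}

#' Percent-change band plot for simulated scenarios
#'
#' Median and 2.5th/97.5th percentile bands of percent change from baseline
#' for one or more simulated scenarios.
#'
#' @param summaries A [simulate_scenario()] result or list of them.
#' @param threshold Optional horizontal reference line (percent).
#' @return A ggplot object.
#' @export
plot_scenarios <- function(summaries, threshold = 3) {
  if (inherits(summaries, "kpd_scenario_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, function(s)
    cbind(s$series, label = s$label)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Time (months)", y = "BMD change from baseline (%)")
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  p
}
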