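#' Read an acute-phase-reaction count table
#'
#' Per-study counts of acute-phase reactions (APR) by dose group, columns
#' `dose_mg`, `apr_count`, `total_count`, `study`. Rows where the event
#' count exceeds the denominator are impossible as printed; they are flagged
#' (`valid = FALSE`), excluded from all downstream pooling, and reported via
#' a warning rather than silently dropped. A corrected table can be supplied
#' instead of the packaged one.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `kpd_apr` with an added logical `valid`
#'   column; the flagged rows are also stored in the `"flagged"` attribute.
#' @export
read_apr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("dose_mg", "apr_count", "total_count", "study")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("APR table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$apr_count < 0) || any(df$total_count < 1))
    stop("APR counts must satisfy apr_count >= 0 and total_count >= 1",
         call. = FALSE)
  df$valid <- df$apr_count <= df$total_count
  if (any(!df$valid))
    warning("data-integrity: ", sum(!df$valid), " row(s) with apr_count > ",
            "total_count flagged and excluded from pooling (",
            paste(df$study[!df$valid], collapse = ", "), ")", call. = FALSE)
  structure(df, class = c("kpd_apr", "data.frame"),
            flagged = df[!df$valid, , drop = FALSE])
}

#' Pooled APR incidence at one dose with exact confidence interval
#'
#' Pools events and denominators over the valid studies at a dose and
#' reports the incidence with a Clopper-Pearson (exact binomial) interval --
#' chosen over the normal approximation because some groups are small.
#'
#' @param table A `kpd_apr` table (see [read_apr_table()]).
#' @param dose_mg Dose group (mg).
#' @param conf Confidence level (default 0.95).
#' @return A list: `dose_mg`, `events`, `total`, `incidence_pct`,
#'   `lower_pct`, `upper_pct`.
#' @examples
#' apr <- load_fixtures()$apr
#' pooled_incidence(apr, 4)   # 6/12 -> 50%
#' @export
pooled_incidence <- function(table, dose_mg, conf = 0.95) {
  stopifnot(inherits(table, "kpd_apr"))
  rows <- table[table$valid & table$dose_mg == dose_mg, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no valid rows at dose ", dose_mg, " mg", call. = FALSE)
  x <- sum(rows$apr_count)
  n <- sum(rows$total_count)
  bt <- binom.test(x, n, conf.level = conf)
  list(dose_mg = dose_mg, events = x, total = n,
       incidence_pct = 100 * x / n,
       lower_pct = 100 * bt$conf.int[1],
       upper_pct = 100 * bt$conf.int[2])
}

#' Dose trend in APR incidence
#'
#' Cochran-Armitage test for trend in pooled APR proportions across ordered
#' dose groups, with the direction taken from the denominator-weighted
#' least-squares slope of incidence on dose.
#'
#' @param table A `kpd_apr` table with valid rows in at least 2 dose groups.
#' @return A list: `direction` (`"increasing"`, `"decreasing"` or `"flat"`),
#'   `statistic` (chi-squared), `p_value`, and the pooled per-dose
#'   proportions in `$groups`.
#' @export
dose_trend <- function(table) {
  stopifnot(inherits(table, "kpd_apr"))
  rows <- table[table$valid, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no valid rows", call. = FALSE)
  g <- aggregate(cbind(apr_count, total_count) ~ dose_mg, rows, sum)
  g <- g[order(g$dose_mg), , drop = FALSE]
  if (nrow(g) < 2)
    stop("dose trend requires at least 2 dose groups", call. = FALSE)
  g$incidence <- g$apr_count / g$total_count
  slope <- coef(lm(incidence ~ dose_mg, data = g, weights = total_count))[2]
  tt <- suppressWarnings(
    prop.trend.test(g$apr_count, g$total_count, score = g$dose_mg))
  direction <- if (abs(slope) < 1e-12) "flat"
               else if (slope > 0) "increasing" else "decreasing"
  list(direction = direction,
       statistic = unname(tt$statistic),
       p_value = tt$p.value,
       groups = g)
}
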