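#' Goodness-of-fit table
#'
#' Population predictions (PRED, at eta = 0), individual predictions (IPRED,
#' at the empirical-Bayes eta), and residuals scaled by the residual SD:
#' `WRES = (DV - PRED)/sqrt(sigma2)` and `IWRES = (DV - IPRED)/sqrt(sigma2)`
#' (for the proportional residual model the SD is `pred * sqrt(sigma2)`).
#' Baseline observations, which define the per-arm baseline, are excluded.
#'
#' @param fit A [kpd_fit()] result.
#' @param data The event dataset the model was fitted to.
#' @return A data frame of class `kpd_gof` with one row per post-baseline
#'   observation: `id`, `time`, `dv`, `pred`, `ipred`, `wres`, `iwres`.
#' @export
kpd_gof <- function(fit, data) {
  stopifnot(inherits(fit, "kpd_fit"))
  arms <- .split_arms(data, fit$weighting)
  missing_eta <- setdiff(names(arms), names(fit$etas))
  if (length(missing_eta))
    stop("no empirical-Bayes eta for id(s): ",
         paste(missing_eta, collapse = ", "), call. = FALSE)
  pop <- fit$pop
  sig <- sqrt(fit$estimates["sigma2"])
  out <- lapply(arms, function(arm) {
    pred <- .arm_predict(arm, 0, pop)
    ipred <- .arm_predict(arm, fit$etas[[as.character(arm$id)]], pop)
    sd_p <- if (fit$residual == "proportional") sig * pred else sig
    sd_i <- if (fit$residual == "proportional") sig * ipred else sig
    data.frame(id = arm$id, time = arm$obs_t, dv = arm$dv,
               pred = pred, ipred = ipred,
               wres = (arm$dv - pred) / sd_p,
               iwres = (arm$dv - ipred) / sd_i)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("kpd_gof", "data.frame")
  out
}

# simulate one replicate of a dataset's observations (matrix arms x times is
# ragged, so return a data frame of id/time/dv)
.simulate_replicate <- function(arms, pop) {
  do.call(rbind, lapply(arms, function(arm) {
    eta <- rnorm(1, 0, sqrt(pop$omega2_edk50))
    resp <- .arm_predict(arm, eta, pop)
    dv <- resp + rnorm(length(resp), 0, sqrt(pop$sigma2))
    redo <- which(dv <= 0)
    while (length(redo)) {
      dv[redo] <- resp[redo] + rnorm(length(redo), 0, sqrt(pop$sigma2))
      redo <- which(dv <= 0)
    }
    data.frame(id = arm$id, time = arm$obs_t, dv = dv)
  }))
}

#' Visual predictive check
#'
#' Simulates `n_sims` replicates of the dataset under its own design (same
#' arms, baselines, regimens and observation schedules), and compares
#' observed percentiles per time bin with the simulation-based percentile
#' bands and their confidence intervals. Time bins are the scheduled
#' observation times. Both the 5/50/95 and the 2.5/50/97.5 percentile sets
#' are standard; 5/50/95 is the default.
#'
#' @param pop A [population_model()].
#' @param data An event dataset.
#' @param n_sims Number of simulated replicates (>= 100).
#' @param seed Integer seed.
#' @param percentiles Percentiles to summarise (default `c(5, 50, 95)`).
#' @param ci Confidence level of the band around each simulated percentile.
#' @return A data frame of class `kpd_vpc`: one row per (time bin,
#'   percentile) with `observed`, `sim_median`, `sim_lo`, `sim_hi`, `n_obs`;
#'   `n_sims` in an attribute.
#' @export
kpd_vpc <- function(pop, data, n_sims = 500, seed = 1,
                    percentiles = c(5, 50, 95), ci = 0.95) {
  stopifnot(inherits(pop, "kpd_pop"))
  if (n_sims < 100) stop("n_sims must be >= 100", call. = FALSE)
  arms <- .split_arms(data)
  obs <- do.call(rbind, lapply(arms, function(a)
    data.frame(time = a$obs_t, dv = a$dv)))
  bins <- sort(unique(obs$time))
  empty <- vapply(bins, function(b) sum(obs$time == b) == 0, logical(1))
  if (any(empty)) {
    warning("dropping empty time bin(s): ", paste(bins[empty], collapse = ", "))
    bins <- bins[!empty]
  }
  probs <- percentiles / 100

  set.seed(as.integer(seed))
  # sim_pct[s, b, k]: percentile k in bin b of replicate s
  sim_pct <- array(NA_real_, c(n_sims, length(bins), length(probs)))
  for (s in seq_len(n_sims)) {
    rep_df <- .simulate_replicate(arms, pop)
    for (b in seq_along(bins)) {
      v <- rep_df$dv[rep_df$time == bins[b]]
      sim_pct[s, b, ] <- quantile(v, probs, names = FALSE, type = 7)
    }
  }
  alpha <- (1 - ci) / 2
  out <- do.call(rbind, lapply(seq_along(bins), function(b) {
    v <- obs$dv[obs$time == bins[b]]
    data.frame(
      time = bins[b],
      percentile = percentiles,
      observed = quantile(v, probs, names = FALSE, type = 7),
      sim_median = apply(sim_pct[, b, , drop = FALSE], 3, median),
      sim_lo = apply(sim_pct[, b, , drop = FALSE], 3, quantile, probs = alpha,
                     names = FALSE),
      sim_hi = apply(sim_pct[, b, , drop = FALSE], 3, quantile,
                     probs = 1 - alpha, names = FALSE),
      n_obs = length(v)
    )
  }))
  rownames(out) <- NULL
  structure(out, class = c("kpd_vpc", "data.frame"),
            n_sims = n_sims, ci = ci)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples study arms (ids) with replacement, refits each replicate
#' dataset, and summarises the estimates by their median and percentile
#' interval. Replicates whose fit errors are recorded as failures; results
#' with more than 20% failures are flagged unreliable.
#'
#' @param data An event dataset with at least 2 ids.
#' @param init A [population_model()] of starting values (typically the
#'   point estimates).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param fixed,residual,weighting,control Passed to [kpd_fit()].
#' @return An object of class `kpd_boot`: `$summary` (per parameter: median,
#'   2.5th and 97.5th percentiles), `$draws` (matrix of replicate estimates),
#'   `$n_boot` (successful replicates), `$failures`, `$unreliable`.
#' @export
kpd_bootstrap <- function(data, init, n_boot = 500, seed = 1,
                          fixed = character(),
                          residual = c("additive", "proportional"),
                          weighting = c("none", "n"),
                          control = list()) {
  residual <- match.arg(residual)
  weighting <- match.arg(weighting)
  data <- as_event_dataset(as.data.frame(data))
  ids <- unique(data$ID)
  if (length(ids) < 2)
    stop("bootstrap requires at least 2 ids to resample", call. = FALSE)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, n_boot, length(.PAR_NAMES),
                  dimnames = list(NULL, .PAR_NAMES))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      sub <- data[data$ID == take[k], , drop = FALSE]
      sub$ID <- k
      sub
    })
    boot_data <- as_event_dataset(do.call(rbind, pieces))
    fit <- tryCatch(
      kpd_fit(boot_data, init, fixed = fixed, residual = residual,
              weighting = weighting,
              control = modifyList(list(hessian = FALSE), control)),
      error = function(e) NULL)
    if (is.null(fit)) failures <- failures + 1L
    else draws[b, ] <- fit$estimates
  }
  keep <- stats::complete.cases(draws)
  draws <- draws[keep, , drop = FALSE]
  if (nrow(draws) == 0L)
    stop("all bootstrap replicates failed to fit", call. = FALSE)
  summ <- data.frame(
    parameter = .PAR_NAMES,
    median = apply(draws, 2, median),
    lo = apply(draws, 2, quantile, probs = 0.025, names = FALSE),
    hi = apply(draws, 2, quantile, probs = 0.975, names = FALSE))
  rownames(summ) <- NULL
  unreliable <- failures > 0.2 * n_boot
  if (unreliable)
    warning("more than 20% of bootstrap replicates failed; ",
            "results flagged unreliable")
  structure(list(summary = summ, draws = draws,
                 n_boot = nrow(draws), failures = failures,
                 unreliable = unreliable),
            class = "kpd_boot")
}

#' @export
print.kpd_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d successful replicates, %d failures%s\n",
              x$n_boot, x$failures,
              if (x$unreliable) " (UNRELIABLE)" else ""))
  print(transform(x$summary, median = signif(median, 5),
                  lo = signif(lo, 5), hi = signif(hi, 5)))
  invisible(x)
}
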