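#' Population K-PD model
#'
#' Typical structural values plus the two variance components: a log-normal
#' inter-arm random effect on EDK50 (variance `omega2_edk50`) and additive
#' Gaussian residual error on observed BMD (variance `sigma2`, (g/cm^2)^2).
#' The baseline is supplied per arm, not part of the population vector.
#'
#' @param kde,kd,edk50,k_tol Typical structural values (see [kpd_params()]).
#' @param omega2_edk50 Variance of the random effect eta on log EDK50
#'   (dimensionless); zero means no inter-arm variability.
#' @param sigma2 Additive residual variance on BMD, (g/cm^2)^2; strictly
#'   positive.
#' @return An object of class `kpd_pop`.
#' @examples
#' population_model(0.0815, 0.00474, 41300, 0.00754, 0.4541, 5e-5)
#' @export
population_model <- function(kde, kd, edk50, k_tol, omega2_edk50, sigma2) {
  if (!is.finite(omega2_edk50) || omega2_edk50 < 0)
    stop("omega2_edk50 must be non-negative", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 < 0)
    stop("sigma2 must be non-negative", call. = FALSE)
  # structural validation (base placeholder only)
  kpd_params(kde, kd, edk50, k_tol, base = 1)
  structure(list(kde = unname(kde), kd = unname(kd), edk50 = unname(edk50),
                 k_tol = unname(k_tol), omega2_edk50 = unname(omega2_edk50),
                 sigma2 = unname(sigma2)),
            class = "kpd_pop")
}

#' @export
print.kpd_pop <- function(x, ...) {
  cat("Population K-PD model\n")
  cat(sprintf("  KDE %.5g  KD %.5g  EDK50 %.5g  K %.5g\n",
              x$kde, x$kd, x$edk50, x$k_tol))
  cat(sprintf("  omega^2(EDK50) %.5g   sigma^2 %.5g\n",
              x$omega2_edk50, x$sigma2))
  invisible(x)
}

#' Individual (arm-level) parameters from the population model
#'
#' Applies the random effect to EDK50 on the log scale,
#' `EDK50_i = EDK50 * exp(eta)`, and sets the arm baseline. KDE, KD and the
#' tolerance rate carry the typical values (their random effects are fixed
#' to zero).
#'
#' @param pop A [population_model()].
#' @param eta Random-effect value on log EDK50.
#' @param base Arm baseline BMD (g/cm^2), strictly positive.
#' @return A [kpd_params] object.
#' @export
individual_params <- function(pop, eta, base) {
  stopifnot(inherits(pop, "kpd_pop"))
  if (!is.finite(base) || base <= 0)
    stop("base must be strictly positive", call. = FALSE)
  if (!is.finite(eta)) stop("eta must be finite", call. = FALSE)
  kpd_params(pop$kde, pop$kd, pop$edk50 * exp(eta), pop$k_tol, base)
}

# --- internal: arm extraction -------------------------------------------------

# Split an event dataset into per-id arm lists. The latest observation at or
# before the first dose defines the arm baseline and is removed from the
# likelihood contributions.
.split_arms <- function(data, weighting = c("none", "n")) {
  weighting <- match.arg(weighting)
  validate_event_dataset(data)
  ids <- unique(data$ID)
  arms <- lapply(ids, function(id) {
    rec <- data[data$ID == id, , drop = FALSE]
    doses <- rec[rec$EVID == 1, , drop = FALSE]
    doses <- doses[order(doses$TIME), , drop = FALSE]
    obs <- rec[rec$EVID == 0 & rec$MDV == 0, , drop = FALSE]
    obs <- obs[order(obs$TIME), , drop = FALSE]
    first_dose <- min(doses$TIME)
    bl_candidates <- which(obs$TIME <= first_dose)
    bl <- bl_candidates[which.max(obs$TIME[bl_candidates])]
    base <- obs$DV[bl]
    keep <- obs[-bl, , drop = FALSE]
    w <- 1
    if (weighting == "n" && "N" %in% names(rec)) w <- rec$N[1]
    list(id = id, obs_t = keep$TIME, dv = keep$DV,
         dose_t = doses$TIME, dose_a = doses$AMT,
         base = base, clock_start = first_dose, weight = w)
  })
  names(arms) <- as.character(ids)
  arms
}

.arm_to_cpp <- function(arm) {
  arm[c("obs_t", "dv", "dose_t", "dose_a", "base", "clock_start", "weight")]
}

# predictions of one arm at its observation times given eta (K-PD model)
.arm_predict <- function(arm, eta, pop, rtol = 1e-8, atol = 1e-10) {
  p <- individual_params(pop, eta, arm$base)
  kpd_response_cpp(arm$obs_t,
                   c(p$kde, p$kd, p$edk50, p$k_tol, p$base),
                   arm$dose_t, arm$dose_a, arm$clock_start, rtol, atol)
}

# conditional -2LL from predictions (shared by the R reference path)
.cond_m2ll_from_pred <- function(dv, pred, sigma2, omega2, eta, weight = 1,
                                 residual = "additive") {
  var <- if (residual == "proportional") sigma2 * pred^2 else
    rep(sigma2, length(pred))
  var <- var / weight
  out <- sum(log(2 * pi * var) + (dv - pred)^2 / var)
  if (omega2 > 0) out <- out + eta^2 / omega2 + log(2 * pi * omega2)
  out
}

#' Conditional -2 log-likelihood of one arm
#'
#' Gaussian -2 log-likelihood of one arm's observations around the model
#' predictions at a given random-effect value, plus the Gaussian prior term
#' `eta^2/omega2 + log(2*pi*omega2)`. The arm baseline is taken from the
#' latest observation at or before the first dose and excluded from the
#' residual sum.
#'
#' @param pop A [population_model()].
#' @param records Event records (see [read_event_dataset()]) of a single id.
#' @param eta Random-effect value on log EDK50.
#' @param residual `"additive"` (default) or `"proportional"` residual model.
#' @return The conditional -2 log-likelihood (numeric scalar).
#' @export
conditional_minus2ll <- function(pop, records, eta,
                                 residual = c("additive", "proportional")) {
  residual <- match.arg(residual)
  stopifnot(inherits(pop, "kpd_pop"))
  if (length(unique(records$ID)) != 1L)
    stop("records must belong to a single id", call. = FALSE)
  if (pop$omega2_edk50 == 0 && eta != 0)
    stop("eta must be 0 when omega2_edk50 is 0", call. = FALSE)
  arm <- .split_arms(records)[[1]]
  if (length(arm$obs_t) == 0L)
    stop("arm has no post-baseline observations", call. = FALSE)
  pred <- .arm_predict(arm, eta, pop)
  .cond_m2ll_from_pred(arm$dv, pred, pop$sigma2, pop$omega2_edk50, eta,
                       arm$weight, residual)
}

#' Laplace approximation to the marginal -2 log-likelihood
#'
#' For each id, finds the random-effect value minimising the conditional
#' -2 log-likelihood (the empirical-Bayes mode), adds the Laplace curvature
#' correction `log(H/(2*pi))` with `H` the finite-difference second
#' derivative of the conditional negative log-likelihood at the mode, and
#' sums over ids. With `omega2_edk50 = 0` this reduces exactly to the pooled
#' (eta = 0) residual -2 log-likelihood.
#'
#' @param pop A [population_model()].
#' @param data An event dataset (see [read_event_dataset()]).
#' @param residual `"additive"` or `"proportional"` residual model.
#' @param predict_fun Optional prediction function `function(arm, eta, pop)`
#'   returning predictions at `arm$obs_t`; when supplied, a pure-R reference
#'   path is used instead of the compiled fast path (useful for testing the
#'   approximation against analytically integrable models).
#' @param eta_init Optional warm starts for the per-id mode searches.
#' @param inner_tol Convergence tolerance of the inner mode search.
#' @return The approximate marginal -2 log-likelihood, with the per-id modes
#'   in attribute `"eta"` and curvatures in attribute `"curvature"`.
#' @export
laplace_marginal_minus2ll <- function(pop, data,
                                      residual = c("additive", "proportional"),
                                      predict_fun = NULL, eta_init = NULL,
                                      inner_tol = 1e-9) {
  residual <- match.arg(residual)
  stopifnot(inherits(pop, "kpd_pop"))
  arms <- .split_arms(data)
  if (is.null(eta_init)) eta_init <- rep(0, length(arms))

  if (is.null(predict_fun)) {
    res <- kpd_laplace_cpp(c(pop$kde, pop$kd, pop$edk50, pop$k_tol),
                           pop$omega2_edk50, pop$sigma2,
                           lapply(arms, .arm_to_cpp), eta_init,
                           residual == "proportional",
                           1e-8, 1e-10, inner_tol)
    if (!all(res$ok))
      stop("empirical-Bayes mode search failed for id(s): ",
           paste(names(arms)[!res$ok], collapse = ", "), call. = FALSE)
    return(structure(res$m2ll, eta = setNames(res$eta, names(arms)),
                     curvature = res$curvature))
  }

  # pure-R reference path
  omega2 <- pop$omega2_edk50
  total <- 0
  etas <- curv <- numeric(length(arms))
  for (i in seq_along(arms)) {
    arm <- arms[[i]]
    g <- function(e) {
      pred <- predict_fun(arm, e, pop)
      .cond_m2ll_from_pred(arm$dv, pred, pop$sigma2, omega2, e,
                           arm$weight, residual)
    }
    if (omega2 <= 1e-12) {
      etas[i] <- 0
      total <- total + g(0)
      next
    }
    opt <- optimize(g, interval = c(-10, 10), tol = inner_tol)
    e <- opt$minimum
    h <- 1e-4
    d2 <- (g(e + h) - 2 * opt$objective + g(e - h)) / h^2
    if (!is.finite(d2) || d2 <= 0)
      stop("empirical-Bayes mode search failed for id: ", names(arms)[i],
           call. = FALSE)
    etas[i] <- e
    curv[i] <- d2
    total <- total + opt$objective + log(0.5 * d2 / (2 * pi))
  }
  structure(total, eta = setNames(etas, names(arms)), curvature = curv)
}

# --- fitting ------------------------------------------------------------------

.PAR_NAMES <- c("kde", "kd", "edk50", "k_tol", "sigma2", "omega2")

#' Fit the population K-PD model
#'
#' Maximises the Laplace-approximate marginal likelihood over the
#' log-transformed structural parameters and variance components, using a
#' Nelder-Mead simplex stage followed by a quasi-Newton (`nlminb`) polish.
#' Per-arm baselines are taken from the data (latest observation at or
#' before the first dose) and are not estimated.
#'
#' @param data An event dataset (see [read_event_dataset()]).
#' @param init A [population_model()] of starting values.
#' @param fixed Character vector of parameters held at their `init` values;
#'   any of `"kde"`, `"kd"`, `"edk50"`, `"k_tol"`, `"sigma2"`, `"omega2"`.
#' @param residual `"additive"` or `"proportional"` residual model.
#' @param weighting `"none"` (default, arms unweighted) or `"n"` (residual
#'   variance scaled by 1/N using the dataset's arm-size column).
#' @param control List overriding numerical controls: `nm_maxit`,
#'   `nm_reltol` (simplex), `qn_iter`, `qn_reltol` (quasi-Newton),
#'   `inner_tol` (eta mode search), `hessian` (logical, compute standard
#'   errors).
#' @return An object of class `kpd_fit`: estimates (as a `kpd_pop` in `$pop`
#'   and a named vector in `$estimates`), standard errors and CV%, the final
#'   -2 log-likelihood, per-id empirical-Bayes eta values, the covariance and
#'   correlation matrices of the (log-scale) estimates and their condition
#'   number, optimizer convergence codes and a non-positive-definite-Hessian
#'   flag.
#' @export
kpd_fit <- function(data, init, fixed = character(),
                    residual = c("additive", "proportional"),
                    weighting = c("none", "n"),
                    control = list()) {
  residual <- match.arg(residual)
  weighting <- match.arg(weighting)
  stopifnot(inherits(init, "kpd_pop"))
  bad <- setdiff(fixed, .PAR_NAMES)
  if (length(bad))
    stop("unknown parameter(s) in fixed: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ctrl <- modifyList(list(nm_maxit = 500, nm_reltol = 1e-7,
                          qn_iter = 300, qn_reltol = 1e-8,
                          inner_tol = 1e-9, hessian = TRUE), control)

  arms <- .split_arms(data, weighting)
  arms_cpp <- lapply(arms, .arm_to_cpp)
  n_obs <- sum(vapply(arms, function(a) length(a$obs_t), integer(1)))

  full0 <- c(init$kde, init$kd, init$edk50, init$k_tol,
             init$sigma2, init$omega2_edk50)
  names(full0) <- .PAR_NAMES
  if (!("omega2" %in% fixed) && full0["omega2"] <= 0)
    stop("init omega2 must be > 0 when omega2 is estimated", call. = FALSE)
  if (!("sigma2" %in% fixed) && full0["sigma2"] <= 0)
    stop("init sigma2 must be > 0 when sigma2 is estimated", call. = FALSE)
  lfull0 <- suppressWarnings(log(full0))  # omega2 = 0 fixed -> -Inf, never used
  free <- setdiff(.PAR_NAMES, fixed)
  free_idx <- match(free, .PAR_NAMES)

  env <- new.env()
  env$eta <- rep(0, length(arms))
  prop <- residual == "proportional"

  objective <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 60)) return(1e10)
    lp <- lfull0
    lp[free_idx] <- par
    v <- exp(lp)
    v[!is.finite(v) & lfull0 == -Inf] <- 0  # fixed omega2 = 0
    res <- kpd_laplace_cpp(v[1:4], v["omega2"], v["sigma2"],
                           arms_cpp, env$eta, prop, 1e-8, 1e-10,
                           ctrl$inner_tol)
    if (!all(res$ok) || !is.finite(res$m2ll)) return(1e10)
    env$eta <- res$eta
    res$m2ll
  }

  if (length(free) == 0L) {
    val <- objective(numeric(0))
    final <- .finalize_fit(full0, NULL, fixed, val, arms, arms_cpp, env,
                           residual, weighting, prop, ctrl, n_obs,
                           convergence = 0L)
    return(final)
  }

  start <- lfull0[free_idx]
  o1 <- optim(start, objective, method = "Nelder-Mead",
              control = list(maxit = ctrl$nm_maxit, reltol = ctrl$nm_reltol))
  o2 <- tryCatch(
    nlminb(o1$par, objective,
           control = list(iter.max = ctrl$qn_iter, eval.max = 4 * ctrl$qn_iter,
                          rel.tol = ctrl$qn_reltol)),
    error = function(e) NULL)
  if (!is.null(o2) && is.finite(o2$objective) && o2$objective <= o1$value) {
    par_best <- o2$par
    val_best <- o2$objective
    convergence <- o2$convergence
  } else {
    par_best <- o1$par
    val_best <- o1$value
    convergence <- o1$convergence
  }
  if (!is.finite(val_best) || val_best >= 1e10)
    stop("population fit failed: objective is not finite at the solution ",
         "(best -2LL = ", format(val_best), ")", call. = FALSE)

  lp <- lfull0
  lp[free_idx] <- par_best
  est <- exp(lp)
  est[!is.finite(est) & lfull0 == -Inf] <- 0

  hess <- NULL
  if (isTRUE(ctrl$hessian)) {
    hess <- tryCatch(optimHess(par_best, objective), error = function(e) NULL)
  }
  .finalize_fit(est, hess, fixed, val_best, arms, arms_cpp, env,
                residual, weighting, prop, ctrl, n_obs, convergence,
                free = free)
}

# assemble the kpd_fit object (shared by the all-fixed short-circuit)
.finalize_fit <- function(est, hess, fixed, minus2ll, arms, arms_cpp, env,
                          residual, weighting, prop, ctrl, n_obs,
                          convergence, free = character()) {
  pop <- population_model(est["kde"], est["kd"], est["edk50"], est["k_tol"],
                          est["omega2"], est["sigma2"])
  # final empirical-Bayes etas at the solution
  res <- kpd_laplace_cpp(est[1:4], est["omega2"], est["sigma2"],
                         arms_cpp, env$eta, prop, 1e-8, 1e-10, ctrl$inner_tol)
  etas <- setNames(res$eta, names(arms))

  se <- cv <- setNames(rep(NA_real_, length(.PAR_NAMES)), .PAR_NAMES)
  vcov_log <- cor_mat <- NULL
  condition_number <- NA_real_
  npd <- FALSE
  if (!is.null(hess) && length(free)) {
    cov_try <- tryCatch(2 * solve(hess), error = function(e) NULL)
    if (is.null(cov_try) || any(!is.finite(diag(cov_try))) ||
        any(diag(cov_try) <= 0)) {
      npd <- TRUE
    } else {
      vcov_log <- cov_try
      dimnames(vcov_log) <- list(free, free)
      se_log <- sqrt(diag(vcov_log))
      se[free] <- est[free] * se_log          # delta method to natural scale
      cv[free] <- 100 * se_log                # = 100 * SE / estimate
      d <- 1 / se_log
      cor_mat <- vcov_log * outer(d, d)
      ev <- eigen(cor_mat, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0) condition_number <- max(ev) / min(ev) else npd <- TRUE
    }
  }

  structure(list(pop = pop,
                 estimates = est,
                 se = se,
                 cv_pct = cv,
                 fixed = fixed,
                 minus2ll = as.numeric(minus2ll),
                 etas = etas,
                 vcov_log = vcov_log,
                 cor = cor_mat,
                 condition_number = condition_number,
                 convergence = convergence,
                 hessian_npd = npd,
                 n_id = length(arms),
                 n_obs = n_obs,
                 residual = residual,
                 weighting = weighting),
            class = "kpd_fit")
}

#' @export
print.kpd_fit <- function(x, ...) {
  cat("Population K-PD fit (Laplace)\n")
  cat(sprintf("  %d arms, %d observations; -2LL = %.4f\n",
              x$n_id, x$n_obs, x$minus2ll))
  tab <- data.frame(estimate = signif(x$estimates, 6),
                    se = signif(x$se, 4),
                    cv_pct = signif(x$cv_pct, 4))
  tab$fixed <- ifelse(names(x$estimates) %in% x$fixed, "yes", "")
  print(tab)
  if (is.finite(x$condition_number))
    cat(sprintf("  condition number: %.4g\n", x$condition_number))
  if (x$hessian_npd)
    cat("  warning: Hessian not positive definite; SEs unavailable\n")
  invisible(x)
}

#' Empirical-Bayes shrinkage diagnostics
#'
#' Eta-shrinkage `100 * (1 - SD(eta_EBE)/sqrt(omega2))` and
#' epsilon-shrinkage `100 * (1 - SD(IWRES))`.
#'
#' @param fit A [kpd_fit()] result with `omega2 > 0` and at least 2 ids.
#' @param data The event dataset the model was fitted to.
#' @return A list with elements `eta_pct` and `eps_pct`.
#' @export
shrinkage <- function(fit, data) {
  stopifnot(inherits(fit, "kpd_fit"))
  omega2 <- fit$estimates["omega2"]
  if (!is.finite(omega2) || omega2 <= 0)
    stop("shrinkage is undefined when omega2 is 0", call. = FALSE)
  if (fit$n_id < 2) stop("shrinkage requires at least 2 ids", call. = FALSE)
  g <- kpd_gof(fit, data)
  list(eta_pct = 100 * (1 - sd(fit$etas) / sqrt(omega2)),
       eps_pct = 100 * (1 - sd(g$iwres)))
}
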