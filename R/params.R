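#' Structural parameters of the K-PD bone-density model
#'
#' Bundles the five structural constants of the dose-driven indirect-response
#' model. The synthesis rate constant `KS` is not a free parameter: the
#' pre-treatment steady state forces `KS = base * kd`.
#'
#' @param kde First-order elimination rate constant from the virtual dose
#'   compartment (1/month).
#' @param kd First-order degradation rate constant of the response (1/month).
#' @param edk50 Virtual infusion rate giving half-maximal stimulation of
#'   synthesis (ng/month).
#' @param k_tol Exponential tolerance decay rate (1/month). May be zero
#'   (no tolerance).
#' @param base Baseline bone mineral density (g/cm^2).
#'
#' @return An object of class `kpd_params`.
#' @examples
#' published_params(base = 0.79)
#' @export
kpd_params <- function(kde, kd, edk50, k_tol, base) {
  v <- c(kde = unname(kde), kd = unname(kd), edk50 = unname(edk50),
         k_tol = unname(k_tol), base = unname(base))
  if (length(v) != 5L || !all(is.finite(v)))
    stop("all K-PD parameters must be finite scalars", call. = FALSE)
  if (any(v[c("kde", "kd", "edk50", "base")] <= 0))
    stop("kde, kd, edk50 and base must be strictly positive", call. = FALSE)
  if (v["k_tol"] < 0)
    stop("k_tol must be non-negative", call. = FALSE)
  structure(as.list(v), class = "kpd_params")
}

#' @export
print.kpd_params <- function(x, ...) {
  cat("K-PD structural parameters\n")
  cat(sprintf("  KDE   %.5g 1/month\n", x$kde))
  cat(sprintf("  KD    %.5g 1/month\n", x$kd))
  cat(sprintf("  EDK50 %.5g ng/month\n", x$edk50))
  cat(sprintf("  K     %.5g 1/month (tolerance)\n", x$k_tol))
  cat(sprintf("  BASE  %.5g g/cm^2 (KS = BASE*KD = %.5g)\n",
              x$base, x$base * x$kd))
  invisible(x)
}

#' Published typical parameter values
#'
#' Convenience constructor returning the packaged population typical values
#' (see [load_fixtures()]) as a [kpd_params] object for a chosen baseline.
#'
#' @param base Baseline bone mineral density (g/cm^2); default 0.79, the
#'   baseline of the largest packaged trial arm.
#' @return A `kpd_params` object.
#' @export
published_params <- function(base = 0.79) {
  pop <- load_fixtures()$pop
  individual_params(pop, eta = 0, base = base)
}

#' Dosing regimen
#'
#' An ordered table of intravenous dose events. Coincident doses (same time)
#' are merged by summing their amounts.
#'
#' @param time Dose times (months since study start), non-negative.
#' @param amount Dose amounts, strictly positive. Interpreted in `units`.
#' @param units `"mg"` (default; converted internally at 1 mg = 1e6 ng) or
#'   `"ng"`.
#' @return A data frame of class `kpd_regimen` with columns `time` (months)
#'   and `amount` (ng), sorted by strictly increasing time. Zero rows are
#'   allowed (no dosing).
#' @examples
#' kpd_regimen(0, 5)                       # single 5 mg dose
#' kpd_regimen(seq(0, 30, 6), rep(1, 6))   # 1 mg every 6 months, 6 doses
#' @export
kpd_regimen <- function(time = numeric(), amount = numeric(),
                        units = c("mg", "ng")) {
  units <- match.arg(units)
  if (length(time) != length(amount))
    stop("time and amount must have equal length", call. = FALSE)
  if (length(time) == 0L)
    return(structure(data.frame(time = numeric(), amount = numeric()),
                     class = c("kpd_regimen", "data.frame")))
  if (any(!is.finite(time)) || any(time < 0))
    stop("dose times must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(amount)) || any(amount <= 0))
    stop("dose amounts must be finite and strictly positive", call. = FALSE)
  ng <- if (units == "mg") amount * .MG_TO_NG else amount
  agg <- aggregate(list(amount = ng), list(time = time), sum)
  agg <- agg[order(agg$time), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("kpd_regimen", "data.frame"))
}

#' Drug amount remaining in the virtual compartment
#'
#' Analytic superposition solution of the linear elimination equation
#' dA/dt = -KDE * A across all administered doses.
#'
#' @param params A [kpd_params] object.
#' @param regimen A [kpd_regimen] object.
#' @param t Time points (months), non-negative; vectorised.
#' @return Amount A(t) in ng, same length as `t`.
#' @export
amount_in_compartment <- function(params, regimen, t) {
  stopifnot(inherits(params, "kpd_params"), inherits(regimen, "kpd_regimen"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative", call. = FALSE)
  if (nrow(regimen) == 0L) return(rep(0, length(t)))
  vapply(t, function(ti) {
    on <- regimen$time <= ti
    sum(regimen$amount[on] * exp(-params$kde * (ti - regimen$time[on])))
  }, numeric(1))
}

#' Virtual infusion rate
#'
#' IR(t) = KDE * A(t): the rate (ng/month) at which drug leaves the virtual
#' compartment and drives the response.
#'
#' @inheritParams amount_in_compartment
#' @return Infusion rate in ng/month, same length as `t`.
#' @export
infusion_rate <- function(params, regimen, t) {
  params$kde * amount_in_compartment(params, regimen, t)
}

#' Emax stimulation of the synthesis rate
#'
#' Multiplier applied to the synthesis rate constant:
#' 1 + IR / (EDK50 + IR). Equals 1 with no drug, 1.5 at IR = EDK50, and
#' approaches (never reaches) 2 as IR grows.
#'
#' @param params A [kpd_params] object.
#' @param ir Virtual infusion rate(s), ng/month, non-negative.
#' @return Dimensionless multiplier in \[1, 2).
#' @export
stimulation_factor <- function(params, ir) {
  stopifnot(inherits(params, "kpd_params"))
  if (any(!is.finite(ir)) || any(ir < 0))
    stop("ir must be finite and non-negative", call. = FALSE)
  1 + ir / (params$edk50 + ir)
}

#' Tolerance factor on synthesis
#'
#' Exponential decay exp(-K * (t - clock_start)) applied to the synthesis
#' rate once the tolerance clock has started (at the first administered
#' dose); 1 beforehand.
#'
#' @param params A [kpd_params] object.
#' @param t Time points (months); vectorised.
#' @param clock_start Start of the tolerance clock (months).
#' @return Dimensionless factor in (0, 1].
#' @export
tolerance_factor <- function(params, t, clock_start = 0) {
  stopifnot(inherits(params, "kpd_params"))
  ifelse(t < clock_start, 1, exp(-params$k_tol * (t - clock_start)))
}
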