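#' Trial-arm design
#'
#' One literature study arm: size, baseline vertebral BMD, dosing regimen
#' and observation schedule.
#'
#' @param label Study tag.
#' @param n_subjects Arm size (>= 1).
#' @param baseline_bmd Baseline vertebral BMD (g/cm^2), within the plausible
#'   0.4-1.4 band.
#' @param regimen A [kpd_regimen()] with at least one dose.
#' @param observation_times Scheduled observation times (months), including
#'   a baseline observation at or before the first dose.
#' @return An object of class `kpd_arm_design`.
#' @export
arm_design <- function(label, n_subjects, baseline_bmd, regimen,
                       observation_times) {
  stopifnot(inherits(regimen, "kpd_regimen"))
  if (nrow(regimen) == 0L)
    stop("arm design needs at least one dose", call. = FALSE)
  if (!is.finite(n_subjects) || n_subjects < 1)
    stop("n_subjects must be >= 1", call. = FALSE)
  if (!is.finite(baseline_bmd) || baseline_bmd < 0.4 || baseline_bmd > 1.4)
    stop("baseline_bmd must lie in the plausible 0.4-1.4 g/cm^2 band",
         call. = FALSE)
  observation_times <- sort(unique(as.numeric(observation_times)))
  if (!any(observation_times <= min(regimen$time)))
    stop("observation schedule lacks a baseline at or before the first dose",
         call. = FALSE)
  structure(list(label = as.character(label),
                 n_subjects = as.integer(round(n_subjects)),
                 baseline_bmd = baseline_bmd,
                 regimen = regimen,
                 observation_times = observation_times),
            class = "kpd_arm_design")
}

#' Default study-arm designs
#'
#' The ten packaged literature trial-arm designs (see [load_fixtures()]):
#' single 1-5 mg doses and annual 5 mg schedules, baselines spanning
#' 0.64-1.06 g/cm^2, observations every 6 months over each arm's follow-up.
#'
#' @return A list of ten [arm_design()] objects.
#' @export
default_designs <- function() {
  load_fixtures()$designs
}

# deterministic per-arm seed stream: adding an arm never perturbs the
# draws of existing arms
.arm_seed <- function(root, i) {
  as.integer((as.numeric(root) + 104729 * i) %% 2147483647)
}

#' Generate a synthetic event dataset
#'
#' Emulates the assumed data-generating process of the population model:
#' per arm, one random effect `eta ~ N(0, omega2)` on log EDK50 (the arm is
#' the exchangeable unit, mirroring arm-level mean data), a deterministic
#' K-PD trajectory at the resulting parameters, and i.i.d. additive
#' `N(0, sigma2)` residual noise on every post-baseline observation.
#' The baseline observation is emitted exactly: it is the arm's published
#' baseline BMD, a design characteristic that downstream fitting treats as
#' the known per-arm baseline, not a digitized curve point. Non-positive
#' observation draws are redrawn (negligible probability at the default
#' noise level, but the contract is total).
#'
#' @param designs A list of [arm_design()] objects.
#' @param pop A [population_model()].
#' @param seed Integer root seed; each arm consumes its own derived stream,
#'   so a fixed seed gives byte-identical output and appending arms leaves
#'   existing arms unchanged.
#' @return A `kpd_dataset` (see [read_event_dataset()]) with one id per arm;
#'   the generating eta values are attached as attribute `"etas"` and the
#'   root seed as `"seed"`.
#' @examples
#' fx <- load_fixtures()
#' d <- generate_dataset(fx$designs[1:2], fx$pop, seed = 1)
#' @export
generate_dataset <- function(designs, pop, seed) {
  stopifnot(inherits(pop, "kpd_pop"), length(designs) >= 1)
  seed <- as.integer(seed)
  rows <- list()
  etas <- numeric(length(designs))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    stopifnot(inherits(d, "kpd_arm_design"))
    set.seed(.arm_seed(seed, i))
    eta <- rnorm(1, 0, sqrt(pop$omega2_edk50))
    etas[i] <- eta
    p <- individual_params(pop, eta, d$baseline_bmd)
    resp <- kpd_simulate(p, d$regimen, d$observation_times)$response
    dv <- resp + rnorm(length(resp), 0, sqrt(pop$sigma2))
    redo <- which(dv <= 0)
    while (length(redo)) {
      dv[redo] <- resp[redo] + rnorm(length(redo), 0, sqrt(pop$sigma2))
      redo <- which(dv <= 0)
    }
    # the latest observation at/before the first dose is the arm baseline,
    # carried exactly (it defines BASE downstream)
    bl_cand <- which(d$observation_times <= min(d$regimen$time))
    bl <- bl_cand[which.max(d$observation_times[bl_cand])]
    dv[bl] <- resp[bl]
    rows[[i]] <- rbind(
      data.frame(ID = i, TIME = d$observation_times, EVID = 0, AMT = NA_real_,
                 DV = dv, MDV = 0, N = d$n_subjects),
      data.frame(ID = i, TIME = d$regimen$time, EVID = 1,
                 AMT = d$regimen$amount, DV = NA_real_, MDV = 1,
                 N = d$n_subjects)
    )
  }
  out <- as_event_dataset(do.call(rbind, rows))
  attr(out, "etas") <- setNames(etas, vapply(designs, `[[`, "", "label"))
  attr(out, "seed") <- seed
  out
}
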