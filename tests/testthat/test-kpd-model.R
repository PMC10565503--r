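# Structural model: virtual compartment, stimulation, tolerance, ODE response

test_that("virtual-compartment amount follows analytic superposition", {
  p <- pub_params()
  reg <- kpd_regimen(0, 5)  # 5 mg
  expect_equal(amount_in_compartment(p, reg, 0), 5e6)
  expect_equal(amount_in_compartment(p, kpd_regimen(), c(0, 10, 50)),
               c(0, 0, 0))
  # half-life identity
  t_half <- log(2) / p$kde
  expect_equal(amount_in_compartment(p, reg, t_half), 2.5e6, tolerance = 1e-12)
  # superposition over two doses
  reg2 <- kpd_regimen(c(0, 6), c(2, 1))
  expect_equal(amount_in_compartment(p, reg2, 10),
               2e6 * exp(-p$kde * 10) + 1e6 * exp(-p$kde * 4))
  expect_error(amount_in_compartment(p, reg, -1), "non-negative")
})

test_that("infusion rate is KDE * A and conserves administered mass", {
  p <- pub_params()
  reg <- kpd_regimen(0, 5)
  expect_equal(infusion_rate(p, reg, 0), 0.08150 * 5e6)
  expect_equal(infusion_rate(p, kpd_regimen(3, 1), 2), 0)  # before first dose
  # integral of IR over a long horizon returns the dose within 0.1%
  tt <- seq(0, 240, by = 0.05)
  ir <- infusion_rate(p, reg, tt)
  total <- sum(diff(tt) * (head(ir, -1) + ir[-1]) / 2)
  expect_lt(abs(total - 5e6) / 5e6, 0.001)
})

test_that("stimulation factor is the bounded Emax form", {
  p <- pub_params()
  expect_equal(stimulation_factor(p, 0), 1)
  expect_equal(stimulation_factor(p, p$edk50), 1.5)
  expect_lt(stimulation_factor(p, 1e12), 2)
  expect_gt(stimulation_factor(p, 1e12), 1.99)
  ir <- seq(0, 1e6, length.out = 50)
  s <- stimulation_factor(p, ir)
  expect_true(all(s >= 1 & s < 2))
  expect_true(all(diff(s) >= 0))
  expect_error(stimulation_factor(p, -1), "non-negative")
})

test_that("tolerance factor decays exponentially from the clock start", {
  p <- pub_params()
  expect_equal(tolerance_factor(p, 0, clock_start = 0), 1)
  expect_equal(tolerance_factor(p, 72, clock_start = 0), exp(-0.00754 * 72))
  expect_equal(tolerance_factor(p, 10, clock_start = 20), 1)  # before start
  p0 <- kpd_params(p$kde, p$kd, p$edk50, k_tol = 0, base = p$base)
  expect_equal(tolerance_factor(p0, c(0, 36, 300), 0), c(1, 1, 1))
})

test_that("coincident doses are merged and regimens validated", {
  r <- kpd_regimen(c(0, 0, 6), c(1, 2, 1))
  expect_equal(nrow(r), 2)
  expect_equal(r$amount, c(3e6, 1e6))
  expect_error(kpd_regimen(-1, 1), "non-negative")
  expect_error(kpd_regimen(0, 0), "positive")
})

test_that("no-dose trajectories match steady state and the closed form", {
  p <- pub_params()
  tt <- 0:72
  p0 <- kpd_params(p$kde, p$kd, p$edk50, k_tol = 0, base = p$base)
  tr0 <- kpd_simulate(p0, kpd_regimen(), tt)
  expect_equal(tr0$response, rep(p$base, length(tt)))
  # k_tol > 0 with the tolerance clock running and no drug: linear ODE with
  # exponentially decaying synthesis has a closed-form solution
  tr <- kpd_simulate(p, kpd_regimen(), tt, clock_start = 0)
  cf <- exp(-p$kd * tt) *
    (p$base + p$base * p$kd * (exp((p$kd - p$k_tol) * tt) - 1) /
       (p$kd - p$k_tol))
  expect_lt(max(abs(tr$response - cf) / cf), 1e-8)
})

test_that("adaptive integration agrees with a fixed-step RK4 reference", {
  p <- pub_params()
  reg <- kpd_regimen(0, 5)
  tt <- seq(0, 72, by = 6)
  tr <- kpd_simulate(p, reg, tt)
  # independent fixed-step classical RK4 at 1e-3-month steps (dose at t=0,
  # so the forcing is smooth over the whole horizon)
  rhs <- function(t, R) {
    ir <- p$kde * 5e6 * exp(-p$kde * t)
    p$base * p$kd * (1 + ir / (p$edk50 + ir)) * exp(-p$k_tol * t) - p$kd * R
  }
  h <- 1e-3
  R <- p$base
  ref <- numeric(length(tt))
  ref[1] <- R
  t <- 0
  for (i in 2:length(tt)) {
    nstep <- round((tt[i] - tt[i - 1]) / h)
    for (s in seq_len(nstep)) {
      k1 <- rhs(t, R)
      k2 <- rhs(t + h / 2, R + h / 2 * k1)
      k3 <- rhs(t + h / 2, R + h / 2 * k2)
      k4 <- rhs(t + h, R + h * k3)
      R <- R + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    ref[i] <- R
  }
  expect_lt(max(abs(tr$response - ref)), 1e-6)
})

test_that("trajectory matches an independent ODE solver on a multi-dose regimen", {
  p <- pub_params(base = 0.93)
  reg <- kpd_regimen(c(0, 6, 12), c(5, 1, 2.5))
  tt <- sort(unique(c(seq(0, 48, by = 3), reg$time)))
  tr <- kpd_simulate(p, reg, tt)
  deriv <- function(t, y, parms) {
    on <- reg$time <= t
    ir <- p$kde * sum(reg$amount[on] * exp(-p$kde * (t - reg$time[on])))
    tol <- if (t > 0) exp(-p$k_tol * t) else 1
    list(p$base * p$kd * (1 + ir / (p$edk50 + ir)) * tol - p$kd * y)
  }
  ref <- deSolve::lsoda(c(R = p$base), tt, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$response - ref[, "R"])), 1e-6)
})

test_that("trajectory invariants hold under the published parameters", {
  p <- pub_params()
  reg <- kpd_regimen(seq(0, 60, 12), rep(5, 6))
  tr <- kpd_simulate(p, reg, 0:72)
  expect_true(all(tr$amount >= 0))
  expect_true(all(tr$tolerance > 0 & tr$tolerance <= 1))
  expect_true(all(tr$response > 0))
  expect_equal(nrow(tr), 73)
})

test_that("percent change is a monotone transform of the response", {
  p <- pub_params(base = 1)
  tr <- kpd_simulate(p, kpd_regimen(0, 2.5), 0:36)
  pc <- percent_change(tr)
  expect_equal(pc[1], 0)
  expect_equal(order(pc), order(tr$response))
  # hand value: response 1.05 against baseline 1 is +5%
  tr$response <- rep(1.05, nrow(tr))
  expect_equal(percent_change(tr), rep(5, nrow(tr)))
})

test_that("single 5 mg dose at the published values exceeds the 3% rule", {
  p <- pub_params(base = 0.79)
  tr <- kpd_simulate(p, kpd_regimen(0, 5), 0:72)
  expect_gt(max(percent_change(tr)), 3)
})

test_that("peak percent change is nondecreasing in single-dose amount", {
  p <- pub_params()
  doses <- c(0.5, 1, 2.5, 4, 5)
  peaks <- vapply(doses, function(d)
    max(percent_change(kpd_simulate(p, kpd_regimen(0, d), 0:72))),
    numeric(1))
  expect_true(all(diff(peaks) >= 0))
})
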