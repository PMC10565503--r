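# Population layer: IIV mapping, conditional likelihood, Laplace marginal, fit

test_that("individual parameters apply a log-normal effect on EDK50 only", {
  pop <- pub_pop()
  p0 <- individual_params(pop, 0, base = 0.79)
  expect_equal(p0$edk50, pop$edk50)
  expect_equal(individual_params(pop, log(2), 0.79)$edk50, 2 * pop$edk50)
  expect_equal(individual_params(pop, -0.5, 0.79)$edk50,
               41300 * exp(-0.5), tolerance = 1e-12)
  p1 <- individual_params(pop, 1.3, base = 0.93)
  expect_equal(p1$kde, pop$kde)
  expect_equal(p1$kd, pop$kd)
  expect_equal(p1$k_tol, pop$k_tol)
  expect_equal(p1$base, 0.93)
  expect_error(individual_params(pop, 0, base = -1), "positive")
})

test_that("conditional -2LL equals a direct Gaussian density product", {
  pop <- pub_pop()
  # toy arm: baseline + 3 post-dose observations
  rec <- data.frame(
    ID = 1,
    TIME = c(0, 0, 6, 12, 18),
    EVID = c(0, 1, 0, 0, 0),
    AMT = c(NA, 5e6, NA, NA, NA),
    DV = c(0.79, NA, 0.80, 0.82, 0.81),
    MDV = c(0, 1, 0, 0, 0),
    N = 100)
  eta <- 0.3
  got <- conditional_minus2ll(pop, rec, eta)
  p <- individual_params(pop, eta, base = 0.79)
  pred <- kpd_simulate(p, kpd_regimen(0, 5e6, units = "ng"),
                       c(6, 12, 18))$response
  by_hand <- -2 * sum(dnorm(c(0.80, 0.82, 0.81), pred,
                            sqrt(pop$sigma2), log = TRUE)) +
    eta^2 / pop$omega2_edk50 + log(2 * pi * pop$omega2_edk50)
  expect_equal(got, by_hand, tolerance = 1e-10)
  # doubling squared residuals doubles the residual sum term
  rec2 <- rec
  rec2$DV[3:5] <- pred + sqrt(2) * (c(0.80, 0.82, 0.81) - pred)
  resid_term <- function(m2ll) m2ll - 3 * log(2 * pi * pop$sigma2) -
    eta^2 / pop$omega2_edk50 - log(2 * pi * pop$omega2_edk50)
  expect_equal(resid_term(conditional_minus2ll(pop, rec2, eta)),
               2 * resid_term(got), tolerance = 1e-8)
})

test_that("eta must be zero when there is no inter-arm variability", {
  pop <- pub_pop()
  pop0 <- population_model(pop$kde, pop$kd, pop$edk50, pop$k_tol, 0,
                           pop$sigma2)
  d <- toy_dataset()
  expect_error(conditional_minus2ll(pop0, d[d$ID == 1, ], eta = 0.5),
               "eta must be 0")
})

test_that("Laplace marginal is exact for a model linear in eta", {
  # predictions linear in eta make the marginal a conjugate Gaussian
  # integral with a closed form; the Laplace approximation must be exact
  pop <- population_model(0.1, 0.01, 1e4, 0.001,
                          omega2_edk50 = 0.25, sigma2 = 4e-4)
  a <- c(0.80, 0.83, 0.85)
  b <- c(0.02, 0.05, 0.03)
  y <- c(0.81, 0.84, 0.83)
  rec <- as_event_dataset(data.frame(
    ID = 1, TIME = c(0, 0, 6, 12, 18), EVID = c(0, 1, 0, 0, 0),
    AMT = c(NA, 1e6, NA, NA, NA), DV = c(0.79, NA, y), MDV = c(0, 1, 0, 0, 0),
    N = 1))
  lin_pred <- function(arm, eta, pop) a + b * eta
  got <- laplace_marginal_minus2ll(pop, rec, predict_fun = lin_pred)
  # exact: y ~ N(a, sigma2 I + omega2 b b^T)
  S <- pop$sigma2 * diag(3) + pop$omega2_edk50 * tcrossprod(b)
  r <- y - a
  exact <- log(det(2 * pi * S)) + drop(t(r) %*% solve(S, r))
  expect_equal(as.numeric(got), exact, tolerance = 1e-8)
})

test_that("zero inter-arm variance reduces the marginal to the pooled -2LL", {
  pop <- pub_pop()
  pop0 <- population_model(pop$kde, pop$kd, pop$edk50, pop$k_tol, 0,
                           pop$sigma2)
  d <- toy_dataset()
  got <- as.numeric(laplace_marginal_minus2ll(pop0, d))
  pooled <- sum(vapply(unique(d$ID), function(id)
    conditional_minus2ll(pop0, d[d$ID == id, ], eta = 0), numeric(1)))
  expect_equal(got, pooled, tolerance = 1e-8)
})

test_that("the marginal -2LL is additive over independent arms", {
  pop <- pub_pop()
  d <- toy_dataset()
  both <- as.numeric(laplace_marginal_minus2ll(pop, d))
  one <- as.numeric(laplace_marginal_minus2ll(pop, d[d$ID == 1, ]))
  two <- as.numeric(laplace_marginal_minus2ll(pop, d[d$ID == 2, ]))
  expect_equal(both, one + two, tolerance = 1e-6)
})

test_that("compiled fast path agrees with the pure-R reference path", {
  pop <- pub_pop()
  d <- toy_dataset()
  kpd_pred <- function(arm, eta, pop) {
    p <- individual_params(pop, eta, arm$base)
    kpd_simulate(p, kpd_regimen(arm$dose_t, arm$dose_a, units = "ng"),
                 arm$obs_t, clock_start = arm$clock_start)$response
  }
  fast <- as.numeric(laplace_marginal_minus2ll(pop, d))
  ref <- as.numeric(laplace_marginal_minus2ll(pop, d, predict_fun = kpd_pred))
  expect_equal(fast, ref, tolerance = 1e-6)
})

test_that("the objective is invariant to shifting the whole time axis", {
  pop <- pub_pop()
  d <- toy_dataset()
  d2 <- d
  d2$TIME <- d2$TIME + 7
  for (mult in c(1, 1.5)) {
    popm <- population_model(pop$kde * mult, pop$kd, pop$edk50, pop$k_tol,
                             pop$omega2_edk50, pop$sigma2)
    expect_equal(as.numeric(laplace_marginal_minus2ll(popm, d)),
                 as.numeric(laplace_marginal_minus2ll(popm, d2)),
                 tolerance = 1e-6)
  }
})

test_that("fit with every parameter fixed returns the initial values", {
  d <- toy_dataset()
  init <- pub_pop()
  f <- kpd_fit(d, init, fixed = c("kde", "kd", "edk50", "k_tol",
                                  "sigma2", "omega2"))
  expect_equal(f$estimates[["kde"]], init$kde)
  expect_equal(f$estimates[["omega2"]], init$omega2_edk50)
  expect_equal(f$minus2ll, as.numeric(laplace_marginal_minus2ll(init, d)),
               tolerance = 1e-6)
})

test_that("fitted objective improves on the start and beats perturbed truth", {
  fx <- quiet_fixtures()
  d <- generate_dataset(rep(fx$designs, 2), fx$pop, seed = 11)
  init <- population_model(0.1, 0.005, 30000, 0.005, 0.3, 1e-4)
  f <- kpd_fit(d, init, control = fast_ctrl)
  expect_lte(f$minus2ll, as.numeric(laplace_marginal_minus2ll(init, d)))
  # at the optimum, the objective is no worse than at 2x-perturbed truth
  pert <- population_model(fx$pop$kde * 2, fx$pop$kd * 2, fx$pop$edk50 * 2,
                           fx$pop$k_tol * 2, fx$pop$omega2_edk50,
                           fx$pop$sigma2)
  expect_lte(f$minus2ll, as.numeric(laplace_marginal_minus2ll(pert, d)))
  # CV% definition: 100 * SE / estimate
  f2 <- kpd_fit(d, f$pop, control = modifyList(fast_ctrl,
                                               list(hessian = TRUE)))
  ok <- !is.na(f2$se)
  expect_true(any(ok))
  expect_equal(f2$cv_pct[ok], 100 * f2$se[ok] / f2$estimates[ok],
               tolerance = 1e-8)
  if (is.finite(f2$condition_number)) expect_gte(f2$condition_number, 1)
})

test_that("shrinkage diagnostics behave at their extremes", {
  d <- toy_dataset()
  init <- pub_pop()
  f <- kpd_fit(d, init, fixed = c("kde", "kd", "edk50", "k_tol",
                                  "sigma2", "omega2"))
  s <- shrinkage(f, d)
  expect_true(is.finite(s$eta_pct) && s$eta_pct <= 100)
  expect_true(is.finite(s$eps_pct))
  # EBEs all zero would give exactly 100%
  f0 <- f
  f0$etas[] <- 0
  expect_equal(100 * (1 - sd(f0$etas) / sqrt(f0$estimates[["omega2"]])), 100)
})
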