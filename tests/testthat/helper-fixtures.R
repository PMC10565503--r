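# shared fixtures: the packaged tables (APR warning silenced) and the
# published typical values, plus loosened optimizer controls for tests that
# only exercise machinery, not estimation quality
quiet_fixtures <- function() suppressWarnings(load_fixtures())

pub_pop <- function() quiet_fixtures()$pop

pub_params <- function(base = 0.79) {
  pop <- pub_pop()
  individual_params(pop, eta = 0, base = base)
}

fast_ctrl <- list(nm_maxit = 200, nm_reltol = 1e-5, qn_iter = 100,
                  qn_reltol = 1e-7, hessian = FALSE)

# small two-arm event dataset used by several machinery tests
toy_dataset <- function(seed = 7, omega2 = 0.4541, sigma2 = 5e-5) {
  fx <- quiet_fixtures()
  pop <- population_model(fx$pop$kde, fx$pop$kd, fx$pop$edk50, fx$pop$k_tol,
                          omega2, sigma2)
  generate_dataset(fx$designs[c(4, 7)], pop, seed = seed)
}
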