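test_that("chi squared is an exact variance-weighted residual sum", {
  truth <- toy_chain6_truth(seed = 2, noise_cv = 0)
  data <- generate_dataset(truth)
  traj <- attr(data, "trajectory")
  # zero residual on the generating trajectory
  expect_identical(chi_squared(traj, data), 0)
  # single-record arithmetic: residual 2, sd 2 -> 1
  one <- measurement_set(
    data.frame(time_min = 0, species_id = "A", compartment = "intracellular",
               replicate = 1L, value_normalized = 3, sd_normalized = 2),
    sd_floor_rel = 0, sd_floor_abs = 0)
  expect_equal(chi_squared(traj, one),
               unname(((traj$values[1, "A"] - 3) / 2)^2))
  # doubling all SDs quarters the objective
  noisy <- generate_dataset(toy_chain6_truth(seed = 2, noise_cv = 0.1))
  doubled <- noisy
  doubled$records$sd_normalized <- 2 * doubled$records$sd_normalized
  traj2 <- attr(noisy, "trajectory")
  expect_equal(chi_squared(traj2, doubled), chi_squared(traj2, noisy) / 4,
               tolerance = 1e-12)
  # times must match exactly; no interpolation
  off <- noisy
  off$records$time_min[1] <- 1.5
  expect_error(chi_squared(traj2, off), "not in trajectory")
})

test_that("the evolution strategy is deterministic given the seed", {
  truth <- toy_chain6_truth(seed = 2, noise_cv = 0.05)
  data <- generate_dataset(truth)
  m <- toy_chain6()
  opts <- es_options(budget = 300L, mu = 4L, lambda = 12L)
  f1 <- fit_linlog(m, data, truth$design, J0 = toy_chain6_J0(),
                   c0_basis = truth$parameterization$c0, options = opts,
                   seed = 11)
  f2 <- fit_linlog(m, data, truth$design, J0 = toy_chain6_J0(),
                   c0_basis = truth$parameterization$c0, options = opts,
                   seed = 11)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$theta, f2$theta)
  f3 <- fit_linlog(m, data, truth$design, J0 = toy_chain6_J0(),
                   c0_basis = truth$parameterization$c0, options = opts,
                   seed = 12)
  expect_false(identical(f1$trace, f3$trace))
})

test_that("best-so-far objective is monotone and consistent", {
  truth <- toy_chain6_truth(seed = 3, noise_cv = 0.05)
  data <- generate_dataset(truth)
  m <- toy_chain6()
  fit <- fit_linlog(m, data, truth$design, J0 = toy_chain6_J0(),
                    c0_basis = truth$parameterization$c0,
                    options = es_options(budget = 1500L, restart_every = 500L),
                    seed = 7)
  expect_true(all(diff(fit$trace) <= 0))
  expect_gte(fit$restarts, 1L)
  # reported chi2 equals a from-scratch recomputation on the best parameters
  design <- truth$design
  init <- linlog_initial_state(design, fit$parameterization)
  sim <- suppressMessages(
    linlog_simulate(fit$parameterization, init, design$time_grid,
                    rtol = 1e-6, atol = 1e-8))
  chi2 <- chi_squared(sim, data, rescale = fit$rescale)
  is_r <- fit$space$kind == "reference"
  i <- match(fit$space$species[is_r], data$reference$species_id)
  chi2 <- chi2 + sum(((fit$theta[is_r] - data$reference$mean_normalized[i]) /
                        data$reference$sd_normalized[i])^2)
  expect_equal(fit$chi2, chi2, tolerance = 1e-12)
})

test_that("a search started at the truth stays at the optimum", {
  truth <- toy_chain6_truth(seed = 2, noise_cv = 0)
  p <- truth$parameterization
  # generate with the same integrator tolerances the fit uses, so that the
  # optimum is exactly zero
  data <- generate_dataset(truth, rtol = 1e-6, atol = 1e-8)
  m <- toy_chain6()
  space_start <- c(p$E[cbind(elasticity_pattern(m)$reaction,
                             elasticity_pattern(m)$species)],
                   rep(1, 5))
  fit <- fit_linlog(m, data, truth$design, J0 = toy_chain6_J0(),
                    c0_basis = p$c0,
                    options = es_options(budget = 200L, mu = 4L, lambda = 12L,
                                         sigma0 = 1e-9),
                    seed = 3, start = space_start)
  expect_lt(fit$chi2, 1e-10)
  te <- p$E[p$E != 0]
  fe <- fit$parameterization$E[p$E != 0]
  expect_lt(max(abs(fe - te)), 1e-6)
})

test_that("parameter error shrinks as the noise vanishes", {
  # paired over fixture truths: CV 1 percent beats CV 10 percent on average
  m <- toy_chain6()
  err <- function(cv, ts) {
    truth <- toy_chain6_truth(seed = ts, noise_cv = cv)
    p <- truth$parameterization
    data <- generate_dataset(truth)
    fit <- fit_linlog(m, data, truth$design, J0 = toy_chain6_J0(),
                      c0_basis = p$c0,
                      options = recovery_es_options(4000L), seed = 21)
    median(abs(fit$parameterization$E[p$E != 0] - p$E[p$E != 0]))
  }
  seeds <- c(2, 5)
  lo <- vapply(seeds, function(s) err(0.01, s), 0)
  hi <- vapply(seeds, function(s) err(0.10, s), 0)
  expect_lt(mean(lo), mean(hi))
})

test_that("all-failing objectives raise a diagnostic error", {
  truth <- toy_chain6_truth(seed = 2, noise_cv = 0.05)
  data <- generate_dataset(truth)
  m <- toy_chain6()
  # an infeasible time grid guarantees failure of every candidate
  bad_design <- truth$design
  bad_design$time_grid <- c(0, 1e7)
  expect_error(
    fit_linlog(m, data, bad_design, J0 = toy_chain6_J0(),
               options = es_options(budget = 150L, mu = 2L, lambda = 6L),
               seed = 1),
    "failed|penalty")
})
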