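test_that("linlog rates reduce to the reference flux and scale with enzymes", {
  p <- toy_three_param()
  ones <- setNames(rep(1, 3), names(p$c0))
  expect_identical(unname(linlog_rates(p, ones)), unname(p$J0))
  # single-reaction arithmetic: J0 = 2, eps = 0.5, chat = e -> 2 * 1.5 = 3
  m <- toy_supply_demand()
  p1 <- parameterization(
    m, data.frame(reaction = "demand", species = "X", value = 0.5),
    J0 = c(supply = 2, demand = 2), c0 = c(X = 1))
  expect_equal(unname(linlog_rates(p1, c(X = exp(1)))["demand"]), 3)
  # zero enzyme level kills the rate regardless of concentrations
  e <- c(supply = 1, demand = 0)
  expect_identical(unname(linlog_rates(p1, c(X = 42), enzyme_levels = e)["demand"]), 0)
  expect_error(linlog_rates(p1, c(X = NaN)), "non-finite")
})

test_that("initial state resets the medium and clamps zero concentrations", {
  p <- hepg2_synthetic_param(3)
  design <- glucose_deprivation_design(p$c0)
  init <- linlog_initial_state(design, p)
  intra <- setdiff(names(p$c0), hepg2_extracellular())
  expect_true(all(init[intra] == 1))
  expect_identical(unname(init["GLC_ex"]), p$clamp)
  expect_equal(unname(init["LAC_ex"]), 0.1)
  # no perturbation reproduces the all-ones state
  same <- perturbation_design(p$c0[hepg2_extracellular()])
  expect_true(all(linlog_initial_state(same, p) == 1))
  # invalid input
  expect_error(
    linlog_initial_state(perturbation_design(c(GLC_ex = 0)), p), "LAC_ex")
  expect_error(
    linlog_initial_state(
      perturbation_design(replace(p$c0[hepg2_extracellular()], 1, -1)), p),
    "negative")
})

test_that("the reference state is stationary for the frozen-medium system", {
  p <- hepg2_synthetic_param(3)
  ones <- setNames(rep(1, length(p$c0)), names(p$c0))
  tr <- linlog_simulate(p, ones, c(0, 1, 10, 60, 180),
                        frozen = hepg2_extracellular())
  expect_lt(max(abs(tr$values - 1)), 1e-6)
})

test_that("moiety totals are conserved along perturbed trajectories", {
  p <- hepg2_synthetic_param(3)
  design <- glucose_deprivation_design(p$c0)
  init <- linlog_initial_state(design, p)
  tr <- suppressMessages(linlog_simulate(p, init, design$time_grid))
  expect_true(all(is.finite(tr$values)))
  for (g in p$system$moieties) {
    tot <- tr$values[, names(g)] %*% (g * p$c0[names(g)])
    expect_lt(max(abs(tot / tot[1] - 1)), 1e-6)
  }
})

test_that("adaptive integrator agrees with a brute-force fixed-step oracle", {
  p <- toy_three_param()
  init <- c(A = 1.7, B = 0.6, C = 1.4)
  times <- c(0, 0.25, 0.5, 1, 2)
  ros <- linlog_simulate(p, init, times, rtol = 1e-8, atol = 1e-10)
  rk4 <- rk4_oracle(p, init, times, dt = 1e-4)
  expect_lt(max(abs(ros$values - rk4$values) / abs(rk4$values)), 1e-4)
})

test_that("compiled and reference integrator engines agree", {
  p <- hepg2_synthetic_param(3)
  design <- glucose_deprivation_design(p$c0)
  init <- linlog_initial_state(design, p)
  times <- c(0, 1, 5, 30)
  a <- suppressMessages(linlog_simulate(p, init, times, engine = "cpp"))
  b <- suppressMessages(linlog_simulate(p, init, times, engine = "r"))
  expect_lt(max(abs(a$values - b$values)), 1e-6)
})

test_that("halving the tolerances barely changes the trajectory", {
  p <- hepg2_synthetic_param(3)
  design <- glucose_deprivation_design(p$c0)
  init <- linlog_initial_state(design, p)
  times <- c(0, 1, 5, 10, 30)
  a <- suppressMessages(linlog_simulate(p, init, times, rtol = 1e-8, atol = 1e-10))
  b <- suppressMessages(linlog_simulate(p, init, times, rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(a$values - b$values) / pmax(abs(b$values), 1e-3)), 1e-5)
})

test_that("steady state solves supply/demand in closed form", {
  # reference state is a fixed point
  p0 <- toy_supply_demand_param()
  expect_equal(unname(linlog_steady_state(p0)["X"]), 1, tolerance = 1e-12)
  # supply enzyme up-modulated: (1+d)(1+eps_s u) = 1+eps_d u with u = ln xhat
  d <- 0.05; eps_s <- -0.5; eps_d <- 1
  u <- d / (eps_d - (1 + d) * eps_s)
  e <- c(supply = 1 + d, demand = 1)
  ss <- linlog_steady_state(p0, enzyme_levels = e)
  expect_equal(unname(log(ss["X"])), u, tolerance = 1e-10)
  # long-time integration converges to the same state
  p0$enzyme_levels <- e[names(p0$J0)]
  tr <- linlog_simulate(p0, c(X = 1), times = c(0, 1e4),
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(tr$values[2, "X"]), unname(ss["X"]), tolerance = 1e-6)
})

test_that("unstable parameterizations are reported, not silently solved", {
  # positive feedback: supply accelerates with X, demand insensitive
  m <- toy_supply_demand()
  p <- parameterization(
    m, data.frame(reaction = "supply", species = "X", value = 2),
    J0 = c(supply = 1, demand = 1), c0 = c(X = 1))
  expect_false(linlog_jacobian(p)$stable)
  expect_error(linlog_steady_state(p), "stable")
})

test_that("packaged steady state matches long-time integration", {
  p <- hepg2_synthetic_param(3)
  e <- setNames(rep(1, 49), names(p$J0))
  e["r22"] <- 1.02
  ss <- linlog_steady_state(p, enzyme_levels = e)
  p2 <- p; p2$enzyme_levels <- e
  ones <- setNames(rep(1, length(p$c0)), names(p$c0))
  tr <- suppressMessages(
    linlog_simulate(p2, ones, times = c(0, 1e4),
                    frozen = hepg2_extracellular(),
                    rtol = 1e-10, atol = 1e-12))
  expect_lt(max(abs(tr$values[2, ] - ss)), 1e-6)
})
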