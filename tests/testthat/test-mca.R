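test_that("jacobian matches hand evaluation and flags stability", {
  # one species: supply eps 0, demand eps +0.5, J0 = 1, c0 = 2
  m <- toy_supply_demand()
  p <- parameterization(
    m, data.frame(reaction = "demand", species = "X", value = 0.5),
    J0 = c(supply = 1, demand = 1), c0 = c(X = 2))
  jac <- linlog_jacobian(p)
  expect_equal(unname(jac$jacobian[1, 1]), -0.25)
  expect_true(jac$stable)
  expect_identical(jac$conjugate_pairs, 0L)
  # damped oscillator: exactly one conjugate pair, negative real parts
  po <- toy_oscillator_param()
  jo <- linlog_jacobian(po)
  expect_identical(jo$conjugate_pairs, 1L)
  expect_true(jo$stable)
  # decoupled diagonal-negative system is stable (three independent pools)
  p3 <- toy_three_param()
  expect_true(linlog_jacobian(p3)$stable)
})

test_that("supply/demand control follows the closed form", {
  # C_J(supply wrt supply enzyme) = eps_d / (eps_d - eps_s)
  p <- toy_supply_demand_param(eps_supply = -1, eps_demand = 1)
  cc <- control_coefficients(p)
  expect_equal(unname(cc$C_J["supply", "supply"]), 0.5, tolerance = 1e-12)
  p2 <- toy_supply_demand_param(eps_supply = -0.5, eps_demand = 1)
  cc2 <- control_coefficients(p2)
  expect_equal(unname(cc2$C_J["supply", "supply"]), 1 / 1.5, tolerance = 1e-12)
})

test_that("summation theorems hold on toys and the packaged network", {
  for (p in list(toy_three_param(), toy_oscillator_param(),
                 hepg2_synthetic_param(3))) {
    cc <- control_coefficients(p)
    expect_lt(max(abs(rowSums(cc$C_J) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(cc$C_S))), 1e-8)
  }
})

test_that("control coefficients match the finite-perturbation oracle", {
  h <- 1e-5
  check_oracle <- function(p, enzymes, frozen = character()) {
    cc <- control_coefficients(p, frozen = frozen)
    for (j in enzymes) {
      eu <- setNames(rep(1, length(p$J0)), names(p$J0)); eu[j] <- 1 + h
      ed <- setNames(rep(1, length(p$J0)), names(p$J0)); ed[j] <- 1 - h
      su <- linlog_steady_state(p, enzyme_levels = eu, frozen = frozen)
      sd <- linlog_steady_state(p, enzyme_levels = ed, frozen = frozen)
      ru <- suppressMessages(linlog_rates(p, su, enzyme_levels = eu))
      rd <- suppressMessages(linlog_rates(p, sd, enzyme_levels = ed))
      cj_fd <- (log(ru) - log(rd)) / (2 * h)
      cs_fd <- (log(su) - log(sd))[rownames(cc$C_S)] / (2 * h)
      big_j <- abs(cc$C_J[, j]) > 1e-3
      expect_lt(max(abs((cj_fd[big_j] - cc$C_J[big_j, j]) / cc$C_J[big_j, j])),
                1e-3)
      big_s <- abs(cc$C_S[, j]) > 1e-3
      if (any(big_s))
        expect_lt(max(abs((cs_fd[big_s] - cc$C_S[big_s, j]) / cc$C_S[big_s, j])),
                  1e-3)
    }
  }
  check_oracle(toy_three_param(), c("r1", "r3"))
  check_oracle(toy_oscillator_param(), c("rin", "r2"))
  check_oracle(toy_supply_demand_param(), c("supply", "demand"))
  check_oracle(hepg2_synthetic_param(3), c("r10", "r22", "r41"),
               frozen = hepg2_extracellular())
})

test_that("partial flux control decomposes the control coefficients exactly", {
  p <- hepg2_synthetic_param(3)
  cc <- control_coefficients(p)
  pfc <- partial_flux_control(p, cc)
  # rebuild C_J from the partials: delta_ij + sum over mediators
  cj <- tapply(pfc$value, list(pfc$flux, pfc$enzyme), sum)
  cj[is.na(cj)] <- 0
  cj <- cj[rownames(cc$C_J), colnames(cc$C_J)] + diag(nrow(cc$C_J))
  expect_lt(max(abs(cj - cc$C_J)), 1e-8)
  # a reaction with a single mediator: partial equals total minus delta
  p1 <- toy_supply_demand_param()
  pfc1 <- partial_flux_control(p1)
  cc1 <- control_coefficients(p1)
  one <- pfc1[pfc1$flux == "demand" & pfc1$enzyme == "supply", ]
  expect_identical(nrow(one), 1L)
  expect_equal(one$value, unname(cc1$C_J["demand", "supply"]), tolerance = 1e-12)
  self <- pfc1[pfc1$flux == "demand" & pfc1$enzyme == "demand", ]
  expect_equal(fcc_from_partials(self$value, "demand", "demand"),
               unname(cc1$C_J["demand", "demand"]), tolerance = 1e-12)
})

test_that("internal response coefficients satisfy the connectivity theorem", {
  p <- hepg2_synthetic_param(3)
  pfc <- partial_flux_control(p)
  irc <- internal_response(p, pfc)
  # moiety members and extracellular pools are excluded
  expect_false(any(c("ATP_in", "ADP_in", "AMP_in", "NAD_in", "NADH_in",
                     "NADP_in", "NADPH_in", hepg2_extracellular())
                   %in% rownames(irc)))
  expect_identical(nrow(irc), 33L)
  # per-species sums equal -1
  expect_lt(max(abs(rowSums(irc) + 1)), 1e-8)
  # irc equals the self partial flux control, via an independent recomputation
  cc <- control_coefficients(p)
  for (x in c("PYR_in", "G6P_in", "SUC_in")) {
    direct <- sapply(colnames(irc), function(j) p$E[j, x] * cc$C_S[x, j])
    expect_equal(unname(irc[x, ]), unname(direct), tolerance = 1e-14)
  }
  # sign pattern: a single-consumer species with positive substrate elasticity
  # is counteracted by that consumer
  p1 <- toy_supply_demand_param()
  irc1 <- internal_response(p1)
  expect_lt(irc1["X", "demand"], 0)
})

test_that("mca_report writes labelled tables that round-trip", {
  p <- hepg2_synthetic_param(3)
  cc <- control_coefficients(p)
  cc$partial_fcc <- partial_flux_control(p, cc)
  cc$irc <- internal_response(p, cc$partial_fcc)
  dir <- tempfile()
  paths <- mca_report(cc, p$model, dir)
  expect_true(all(file.exists(paths)))
  fcc <- read_matrix_tsv(paths[["fcc"]])
  expect_identical(colnames(fcc), paste0("r", 1:49))
  expect_identical(rownames(fcc), paste0("r", 1:49))
  expect_equal(fcc, cc$C_J, tolerance = 0)
  ccc <- read_matrix_tsv(paths[["ccc"]])
  expect_equal(ccc, cc$C_S, tolerance = 0)
  expect_error(mca_report(list(), p$model, dir), "empty")
})

test_that("structurally singular control problems raise an error", {
  # two parallel identical reactions between the same pools make M singular
  m <- load_network(write_toy_model(
    list(toy_species("A"),
         toy_species("X", "boundary", FALSE), toy_species("Y", "boundary", FALSE)),
    list(toy_reaction("rin", list(X = -1, A = 1)),
         toy_reaction("rout", list(A = -1, Y = 1)))))
  p <- parameterization(
    m, data.frame(reaction = "rin", species = "A", value = 0),
    J0 = c(rin = 1, rout = 1), c0 = c(A = 1))
  # demand insensitive to A as well: M = 0
  expect_error(control_coefficients(p), "singular")
})
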