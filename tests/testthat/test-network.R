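test_that("packaged model loads with the published structural counts", {
  m <- load_network(hepg2_model_file())
  expect_s3_class(m, "ccm_model")
  expect_length(m$reactions, 49L)
  expect_identical(sum(m$species$balanced), 45L)
  rep <- structural_report(m)
  expect_identical(rep$balanced_intracellular, 40L)
  expect_identical(rep$balanced_extracellular, 5L)
  expect_identical(rep$transport_steps, 5L)
  expect_identical(rep$rank, 42L)
  expect_identical(rep$moieties, 3L)
  expect_identical(rep$inhibitions, 21L)
  expect_identical(rep$activations, 10L)
  expect_identical(rep$elasticities, 174L)
  expect_length(rep$dead_ends, 0L)
})

test_that("loader rejects malformed models and demotes dead ends", {
  expect_error(
    load_network(write_toy_model(list(toy_species("A")), list())),
    "zero reactions")
  expect_error(
    load_network(write_toy_model(
      list(toy_species("A")),
      list(toy_reaction("r1", list(A = -1, GHOST = 1))))),
    "unknown species")
  expect_error(
    load_network(write_toy_model(
      list(toy_species("A"), toy_species("B")),
      list(toy_reaction("r1", list(A = -1, B = 1)),
           toy_reaction("r1", list(B = -1, A = 1))))),
    "duplicate reaction ids")
  # produced-only species declared balanced gets demoted with a warning,
  # shrinking N by one row
  mk <- function(balanced_c) write_toy_model(
    list(toy_species("A"), toy_species("B"),
         toy_species("C", balanced = balanced_c),
         toy_species("X", "boundary", FALSE)),
    list(toy_reaction("r1", list(X = -1, A = 1)),
         toy_reaction("r2", list(A = -1, B = 1, C = 1)),
         toy_reaction("r3", list(B = -1, X = 1))))
  expect_warning(m_demoted <- load_network(mk(TRUE)), "dead-end")
  m_plain <- load_network(mk(FALSE))
  expect_false(m_demoted$species$balanced[m_demoted$species$id == "C"])
  expect_identical(nrow(stoichiometric_matrix(m_demoted)$N),
                   nrow(stoichiometric_matrix(m_plain)$N))
  expect_identical(nrow(stoichiometric_matrix(m_demoted)$N), 2L)
})

test_that("stoichiometric matrix preserves order, sparsity and fractions", {
  m <- load_network(hepg2_model_file())
  N <- stoichiometric_matrix(m)$N
  expect_identical(dim(N), c(45L, 49L))
  expect_identical(colnames(N), paste0("r", 1:49))
  # NADPH consumption touches only the NADP/NADPH pair (acceptor is boundary)
  r22 <- N[, "r22"]
  expect_identical(names(r22[r22 != 0]), c("NADP_in", "NADPH_in"))
  expect_equal(unname(r22[c("NADPH_in", "NADP_in")]), c(-1, 1))
  # fractional coefficients survive exactly
  expect_identical(unname(N["NAD_in", "r40"]), -0.6)
  expect_identical(unname(N["ATP_in", "r41"]), 2.5)
  # single reaction toy
  m2 <- toy_cycle()
  expect_identical(unname(stoichiometric_matrix(m2)$N[, "rf"]), c(-1, 1))
})

test_that("conserved moieties are exact, canonical and complete", {
  m <- load_network(hepg2_model_file())
  sys <- stoichiometric_matrix(m)
  mo <- conserved_moieties(sys)
  expect_length(mo, 3L)
  expect_identical(lapply(mo, names),
                   list(c("ATP_in", "ADP_in", "AMP_in"),
                        c("NAD_in", "NADH_in"),
                        c("NADP_in", "NADPH_in")))
  # unit coefficients, and g N == 0 exactly in integer arithmetic
  for (g in mo) {
    expect_true(all(g == 1))
    gv <- setNames(numeric(nrow(sys$N)), rownames(sys$N))
    gv[names(g)] <- g
    # scale columns to integers (coefficients are decimals in tenths)
    expect_identical(max(abs(gv %*% (sys$N * 10))), 0)
  }
  # rank + moieties = balanced species
  expect_identical(linlogmca:::rational_rank(sys$N) + length(mo), 45L)
  # closed 2-cycle has one moiety, open chain none
  expect_length(conserved_moieties(toy_cycle()), 1L)
  expect_identical(names(conserved_moieties(toy_cycle())[[1]]), c("A", "B"))
  expect_length(conserved_moieties(toy_chain()), 0L)
})

test_that("reduce_system builds a consistent link matrix", {
  m <- load_network(hepg2_model_file())
  sys <- stoichiometric_matrix(m)
  set.seed(7)
  c0 <- setNames(runif(45, 0.2, 5), rownames(sys$N))
  red <- reduce_system(sys, c0)
  expect_length(red$independent_ids, 42L)
  expect_identical(sort(red$dependent_ids),
                   sort(c("AMP_in", "NADH_in", "NADPH_in")))
  # N = L N_R
  expect_lt(max(abs(red$L %*% red$N_R - sys$N)), 1e-12)
  # reconstruction at the reference is the identity
  rec <- drop(red$L %*% c0[red$independent_ids]) + red$offset
  expect_equal(rec, c0[rownames(sys$N)], tolerance = 1e-12)
  # random perturbations of independent species keep moiety totals invariant
  for (i in 1:10) {
    ci <- c0[red$independent_ids] * exp(rnorm(42, 0, 0.3))
    call <- drop(red$L %*% ci) + red$offset
    for (k in seq_along(red$moieties)) {
      g <- red$moieties[[k]]
      expect_equal(sum(g * call[names(g)]), unname(red$totals[k]),
                   tolerance = 1e-10)
    }
  }
  # missing c0 for a moiety member is an informative error
  expect_error(reduce_system(sys, c0[setdiff(names(c0), "AMP_in")]),
               "AMP_in")
})

test_that("model serialization round-trips", {
  m <- load_network(hepg2_model_file())
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(name = m$name,
         species = lapply(seq_len(nrow(m$species)), function(i)
           as.list(m$species[i, c("id", "name", "compartment", "balanced",
                                  "measured")])),
         reactions = lapply(m$reactions, function(r)
           list(id = r$id, name = r$name,
                stoichiometry = as.list(r$stoichiometry),
                activators = r$activators, inhibitors = r$inhibitors))),
    path, auto_unbox = TRUE, digits = NA)
  m2 <- load_network(path)
  expect_identical(m2$species[names(m2$species) != "reference_concentration"],
                   m$species[names(m$species) != "reference_concentration"])
  expect_equal(m2$reactions, m$reactions)
})

test_that("elasticity pattern counts substrates, products and modifiers", {
  m <- load_network(hepg2_model_file())
  pat <- elasticity_pattern(m)
  expect_identical(nrow(pat), 174L)
  expect_identical(sum(pat$role %in% c("activator", "inhibitor")), 31L)
  # stripping all regulation leaves the 143 substrate/product dependencies
  m2 <- m
  m2$reactions <- lapply(m2$reactions, function(r) {
    r$activators <- character(); r$inhibitors <- character(); r
  })
  expect_identical(nrow(elasticity_pattern(m2)), 143L)
  expect_identical(count_unknowns(m2)$elasticities, 143L)
})

test_that("parameter census matches the estimation problem", {
  m <- load_network(hepg2_model_file())
  cu <- count_unknowns(m)
  expect_identical(cu$elasticities, 174L)
  expect_identical(cu$reference_levels, 42L)
  expect_identical(cu$total, 216L)
  expect_identical(cu$measured_reference, 30L)
})
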