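#' Assemble a linlog parameterization
#'
#' Binds a network model to a reference state (steady-state flux distribution
#' `J0` and reference concentrations `c0`), a sparse scaled-elasticity matrix
#' and relative enzyme levels.  The linlog rate law anchors every reaction at
#' its reference flux and adds logarithmic deviations of the normalized
#' concentrations, weighted by the scaled elasticities.
#'
#' The reference state must be a steady state: `N J0 = 0` is enforced to a
#' relative tolerance of 1e-8.
#'
#' @param model A `ccm_model`.
#' @param elasticities Either a data frame with columns
#'   `reaction`, `species`, `value`, or a full reactions-by-balanced-species
#'   matrix.  Entries outside the model's sparsity pattern must be zero.
#' @param J0 Named per-reaction reference fluxes (concentration units/min,
#'   nonnegative in the shipped reference-direction convention).
#' @param c0 Named positive reference concentrations for all balanced species
#'   (mmol/l of the species' compartment).
#' @param enzyme_levels Named or unnamed per-reaction relative enzyme
#'   activities e/e0 (default all 1).
#' @param clamp Floor applied to normalized concentrations inside the
#'   logarithm (the rate law diverges as concentrations approach zero, e.g.
#'   intracellular glucose under glucose deprivation).
#' @return A `ccm_parameterization`.
#' @export
parameterization <- function(model, elasticities, J0, c0,
                             enzyme_levels = NULL, clamp = 1e-6) {
  stopifnot(inherits(model, "ccm_model"))
  bal <- balanced_ids(model)
  rid <- reaction_ids(model)

  if (is.null(names(J0)) && length(J0) == length(rid)) names(J0) <- rid
  if (!all(rid %in% names(J0))) stop("J0 must cover every reaction")
  J0 <- J0[rid]
  if (!all(bal %in% names(c0)))
    stop("c0 missing for balanced species: ",
         paste(setdiff(bal, names(c0)), collapse = ", "))
  c0 <- c0[bal]
  if (any(!is.finite(c0)) || any(c0 <= 0)) stop("all c0 must be positive")

  E <- matrix(0, length(rid), length(bal), dimnames = list(rid, bal))
  if (is.data.frame(elasticities)) {
    stopifnot(all(c("reaction", "species", "value") %in% names(elasticities)))
    bad <- !(elasticities$reaction %in% rid) | !(elasticities$species %in% bal)
    if (any(bad))
      stop("elasticity entries reference unknown reaction/species: ",
           paste(elasticities$reaction[bad], elasticities$species[bad],
                 collapse = ", "))
    E[cbind(elasticities$reaction, elasticities$species)] <- elasticities$value
  } else {
    E[rownames(elasticities), colnames(elasticities)] <-
      as.matrix(elasticities)
  }
  pat <- elasticity_pattern(model)
  allowed <- matrix(FALSE, length(rid), length(bal), dimnames = dimnames(E))
  allowed[cbind(pat$reaction, pat$species)] <- TRUE
  if (any(E[!allowed] != 0))
    stop("nonzero elasticities outside the structural sparsity pattern")

  if (is.null(enzyme_levels)) enzyme_levels <- setNames(rep(1, length(rid)), rid)
  if (is.null(names(enzyme_levels))) names(enzyme_levels) <- rid
  enzyme_levels <- enzyme_levels[rid]
  if (any(enzyme_levels < 0)) stop("enzyme levels must be nonnegative")

  system <- reduce_system(stoichiometric_matrix(model), c0)
  # the reference steady state is a property of the cellular metabolism: it is
  # imposed on the intracellular balances (extracellular medium pools of a
  # batch culture accumulate/deplete and have no steady state of their own)
  intra <- setdiff(rownames(system$N), extracellular_ids(model))
  res <- max(abs(system$N[intra, , drop = FALSE] %*% J0)) /
    max(abs(J0), 1e-300)
  if (res > 1e-8)
    stop("J0 is not an intracellular steady state (relative residual ",
         format(res, digits = 3), ")")

  structure(list(model = model, system = system, E = E, pattern = pat,
                 J0 = J0, c0 = c0, enzyme_levels = enzyme_levels,
                 clamp = clamp),
            class = "ccm_parameterization")
}

#' @export
print.ccm_parameterization <- function(x, ...) {
  cat("<ccm_parameterization> ", length(x$J0), " reactions, ",
      length(x$c0), " balanced species, ",
      sum(x$E != 0), " nonzero elasticities\n", sep = "")
  invisible(x)
}

#' Evaluate linlog reaction rates
#'
#' `r_i = (e_i/e0_i) J0_i (1 + sum_x eps_ix log chat_x)`, with normalized
#' concentrations floored at the clamp value inside the logarithm.  At the
#' reference state (all normalized concentrations 1, enzyme levels 1) the
#' rates equal `J0` exactly.
#'
#' @param p A `ccm_parameterization`.
#' @param c_hat Named (or model-ordered) vector of normalized concentrations
#'   over the balanced species.
#' @param enzyme_levels Optional override of the stored relative enzyme
#'   levels.
#' @return Named per-reaction flux vector (concentration units/min).
#' @export
linlog_rates <- function(p, c_hat, enzyme_levels = NULL) {
  stopifnot(inherits(p, "ccm_parameterization"))
  bal <- names(p$c0)
  if (!is.null(names(c_hat))) c_hat <- c_hat[bal]
  if (any(!is.finite(c_hat)))
    stop("non-finite normalized concentration in rate evaluation")
  e <- if (is.null(enzyme_levels)) p$enzyme_levels else enzyme_levels[names(p$J0)]
  .clamp_warn(p, c_hat)
  drop(e * p$J0 * (1 + p$E %*% log(pmax(c_hat, p$clamp))))
}

# clamping notice for direct rate evaluations
.clamp_warn <- function(p, c_hat) {
  low <- names(p$c0)[c_hat < p$clamp]
  if (length(low))
    message("linlog rates: clamping normalized concentration at ",
            format(p$clamp), " for: ", paste(low, collapse = ", "))
  invisible()
}

#' Describe a stimulus-response perturbation design
#'
#' The default emulates the glucose-deprivation experiment: at t = 0 the
#' culture medium is exchanged instantaneously, resetting the extracellular
#' concentrations (glucose to zero), while intracellular pools are untouched.
#' Samples are drawn in triplicate at 1, 2, 5, 10, 30, 60, 120 and 180 min
#' (plus the 0+ sample) for 25 observed metabolites.
#'
#' @param post_extracellular Named vector: extracellular species to
#'   post-perturbation concentration (same units as `c0`).
#' @param time_grid Sampling times in minutes, strictly increasing from 0
#'   (0 = immediately after the medium exchange).
#' @param observed Character vector of observed species ids.
#' @param replicates Number of replicates per time point.
#' @return A `ccm_design`.
#' @export
perturbation_design <- function(post_extracellular,
                                time_grid = c(0, 1, 2, 5, 10, 30, 60, 120, 180),
                                observed = character(),
                                replicates = 3L) {
  stopifnot(is.numeric(post_extracellular), !is.null(names(post_extracellular)))
  if (time_grid[1] != 0 || is.unsorted(time_grid, strictly = TRUE))
    stop("time_grid must be strictly increasing and start at 0")
  structure(list(post_extracellular = post_extracellular,
                 time_grid = time_grid, observed = observed,
                 replicates = as.integer(replicates)),
            class = "ccm_design")
}

# observed set of the glucose-deprivation experiment: 5 extracellular +
# 20 intracellular species quantified by GC-MS / LC-MS-MS / HPLC
default_observed <- function() {
  c("GLC_ex", "LAC_ex", "PYR_ex", "ALA_ex", "SER_ex",
    "GLC_in", "PEP_in", "G3P_in", "DHAP_in", "F16P_in", "G6P_in", "6PG_in",
    "S7P_in", "RIBO5P_in", "RIBU5P_in", "FUM_in", "MAL_in", "CISAC_in",
    "ISOCIT_in", "CIT_in", "LAC_in", "PYR_in", "ATP_in", "NAD_in", "NADP_in")
}

#' Glucose-deprivation design for the packaged HepG2 model
#'
#' Medium exchange at t = 0: extracellular glucose drops to zero, residual
#' lactate and pyruvate in the fresh medium are 10 percent of their reference
#' levels, alanine and serine are replenished to their reference levels.
#'
#' @param c0 Named reference concentrations (used to express the medium
#'   composition in absolute units).
#' @inheritParams perturbation_design
#' @return A `ccm_design`.
#' @export
glucose_deprivation_design <- function(c0,
                                       time_grid = c(0, 1, 2, 5, 10, 30, 60, 120, 180),
                                       replicates = 3L) {
  post <- c(GLC_ex = 0,
            LAC_ex = unname(0.1 * c0["LAC_ex"]),
            PYR_ex = unname(0.1 * c0["PYR_ex"]),
            ALA_ex = unname(c0["ALA_ex"]),
            SER_ex = unname(c0["SER_ex"]))
  perturbation_design(post, time_grid = time_grid,
                      observed = default_observed(), replicates = replicates)
}

#' Initial normalized state of a stimulus-response simulation
#'
#' Intracellular pools start at their reference levels (normalized value 1);
#' extracellular pools are reset to the post-perturbation medium composition.
#' Zero medium concentrations are floored at the clamp value so that the
#' logarithmic rate terms stay finite.
#'
#' @param design A `ccm_design`.
#' @param p A `ccm_parameterization` (supplies `c0` and the clamp floor).
#' @return Named normalized concentration vector over the balanced species.
#' @export
linlog_initial_state <- function(design, p) {
  stopifnot(inherits(design, "ccm_design"), inherits(p, "ccm_parameterization"))
  sp <- p$model$species
  ex <- sp$id[sp$balanced & sp$compartment == "extracellular"]
  missing_ex <- setdiff(ex, names(design$post_extracellular))
  if (length(missing_ex))
    stop("post-perturbation concentration missing for extracellular ",
         "species: ", paste(missing_ex, collapse = ", "))
  post <- design$post_extracellular[ex]
  if (any(post < 0))
    stop("negative post-perturbation concentration for: ",
         paste(ex[post < 0], collapse = ", "))
  c_hat <- setNames(rep(1, length(p$c0)), names(p$c0))
  c_hat[ex] <- pmax(post / p$c0[ex], p$clamp)
  c_hat
}

# --- reduced-system plumbing -------------------------------------------------

# Map a full normalized state to independent coordinates and back.  Species in
# `frozen` are held constant (treated as external parameters); their values
# are folded into the affine offset via .freeze_state().  Freezing is used for
# steady-state continuation and control analysis, where the extracellular
# medium pools are external to the intracellular steady state.
.reduced_ops <- function(p, frozen = character()) {
  sys <- p$system
  ind <- sys$independent_ids
  bad <- intersect(frozen, sys$dependent_ids)
  if (length(bad))
    stop("cannot freeze moiety-dependent species: ", paste(bad, collapse = ", "))
  act <- setdiff(ind, frozen)
  bal <- names(p$c0)
  D <- p$c0
  # chat_all = Lhat_act chat_act + Lhat_frz chat_frz + ohat
  Lhat <- sys$L * (rep(D[ind], each = length(bal)) / D)
  ohat <- sys$offset / D
  list(ind = act, frozen = intersect(frozen, ind), bal = bal,
       Lhat = Lhat[, act, drop = FALSE],
       Lfrz = Lhat[, intersect(frozen, ind), drop = FALSE],
       ohat = ohat, NR = sys$N_R[act, , drop = FALSE],
       Dind_inv = 1 / D[act])
}

# bind the frozen species' values from a full state into the offset
.freeze_state <- function(ops, init) {
  if (length(ops$frozen))
    ops$ohat <- ops$ohat + drop(ops$Lfrz %*% init[ops$frozen])
  ops
}

.expand_state <- function(ops, x_ind)
  drop(ops$Lhat %*% x_ind) + ops$ohat

# RHS and Jacobian of the reduced normalized system
.reduced_rhs <- function(p, ops, x_ind, eJ0) {
  chat <- .expand_state(ops, x_ind)
  if (any(!is.finite(chat))) return(NULL)
  r <- eJ0 * (1 + drop(p$E %*% log(pmax(chat, p$clamp))))
  list(dx = ops$Dind_inv * drop(ops$NR %*% r), chat = chat, rates = r)
}

.reduced_jac <- function(p, ops, chat, eJ0) {
  w <- ifelse(chat > p$clamp, 1 / chat, 0)
  Ew <- p$E * rep(w, each = nrow(p$E))
  (ops$Dind_inv * ops$NR) %*% (eJ0 * (Ew %*% ops$Lhat))
}

#' Integrate the normalized linlog mass balances
#'
#' Integrates `d chat_ind/dt = diag(c0_ind)^-1 N_R r(chat)` over the
#' independent species, reconstructing the moiety-dependent species
#' algebraically from the conservation totals at every step (the ODE-to-DAE
#' reformulation).  A 4th-order L-stable Rosenbrock method with embedded
#' error control and analytic Jacobian handles the stiffness of the
#' metabolic time scales.
#'
#' @param p A `ccm_parameterization`.
#' @param init Named normalized initial state over all balanced species (see
#'   [linlog_initial_state()]).
#' @param times Output time grid in minutes (first entry = initial time).
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param max_steps Step budget before giving up.
#' @param frozen Species ids held constant at their initial value (external
#'   parameters); empty by default, i.e. all balanced species are dynamic.
#' @param engine `"cpp"` (compiled integrator, default) or `"r"` (reference
#'   implementation); both implement the identical method and are
#'   cross-checked in the test suite.
#' @return A `ccm_trajectory`: list with `times` and a times-by-species
#'   matrix `values` of normalized concentrations.
#' @export
linlog_simulate <- function(p, init, times, rtol = 1e-8, atol = 1e-10,
                            max_steps = 100000L, frozen = character(),
                            engine = c("cpp", "r")) {
  stopifnot(inherits(p, "ccm_parameterization"))
  engine <- match.arg(engine)
  ops <- .reduced_ops(p, frozen)
  if (!is.null(names(init))) init <- init[ops$bal]
  names(init) <- ops$bal
  ops <- .freeze_state(ops, init)
  eJ0 <- p$enzyme_levels * p$J0
  x <- init[ops$ind]
  if (engine == "cpp") {
    vals <- .cpp_rosenbrock(ops$Lhat, ops$ohat, ops$NR, ops$Dind_inv,
                            p$E, eJ0, p$clamp, x, as.numeric(times),
                            rtol, atol, as.integer(max_steps))
    colnames(vals) <- ops$bal
    clamped <- ops$bal[apply(vals < p$clamp, 2, any)]
    if (length(clamped))
      message("linlog simulate: clamp floor ", format(p$clamp),
              " active for: ", paste(clamped, collapse = ", "))
    return(structure(list(times = times, values = vals, species = ops$bal),
                     class = "ccm_trajectory"))
  }
  out <- matrix(NA_real_, length(times), length(ops$bal),
                dimnames = list(NULL, ops$bal))
  out[1, ] <- .expand_state(ops, x)
  t <- times[1]
  h <- min(diff(times)[1] / 10, 1)
  n_steps <- 0L
  for (k in seq_along(times)[-1]) {
    tend <- times[k]
    while (t < tend - 1e-12 * max(1, abs(tend))) {
      h <- min(h, tend - t)
      step <- .rosenbrock_step(p, ops, x, h, eJ0, rtol, atol)
      n_steps <- n_steps + 1L
      if (n_steps > max_steps)
        stop("integration failure: step budget exhausted at t = ",
             format(t, digits = 6), " min")
      if (is.null(step)) { # rejected hard (non-finite)
        h <- h / 10
        if (h < 1e-12)
          stop("integration failure: step size underflow at t = ",
               format(t, digits = 6), " min")
        next
      }
      if (step$errmax <= 1) {
        t <- t + h
        x <- step$x
        h <- h * min(5, max(0.2, 0.9 * step$errmax^(-0.25)))
      } else {
        h <- h * max(0.1, 0.9 * step$errmax^(-0.25))
        if (h < 1e-12)
          stop("integration failure: step size underflow at t = ",
               format(t, digits = 6), " min")
      }
    }
    out[k, ] <- .expand_state(ops, x)
  }
  clamped <- ops$bal[apply(out < p$clamp, 2, any)]
  if (length(clamped))
    message("linlog simulate: clamp floor ", format(p$clamp),
            " active for: ", paste(clamped, collapse = ", "))
  structure(list(times = times, values = out, species = ops$bal),
            class = "ccm_trajectory")
}

# one adaptive step of the 4-stage Rosenbrock method (Shampine coefficients)
.rosenbrock_step <- function(p, ops, x, h, eJ0, rtol, atol) {
  GAM <- 0.5
  A21 <- 2; A31 <- 48 / 25; A32 <- 6 / 25
  C21 <- -8; C31 <- 372 / 25; C32 <- 12 / 5
  C41 <- -112 / 125; C42 <- -54 / 125; C43 <- -2 / 5
  B1 <- 19 / 9; B2 <- 1 / 2; B3 <- 25 / 108; B4 <- 125 / 108
  E1 <- 17 / 54; E2 <- 7 / 36; E3 <- 0; E4 <- 125 / 108

  f0 <- .reduced_rhs(p, ops, x, eJ0)
  if (is.null(f0)) return(NULL)
  J <- .reduced_jac(p, ops, f0$chat, eJ0)
  n <- length(x)
  W <- diag(1 / (GAM * h), n) - J
  lu <- tryCatch(.lu_factor(W), error = function(e) NULL)
  if (is.null(lu)) return(NULL)

  g1 <- .lu_solve(lu, f0$dx)
  f1 <- .reduced_rhs(p, ops, x + A21 * g1, eJ0)
  if (is.null(f1)) return(NULL)
  g2 <- .lu_solve(lu, f1$dx + C21 * g1 / h)
  x3 <- x + A31 * g1 + A32 * g2
  f2 <- .reduced_rhs(p, ops, x3, eJ0)
  if (is.null(f2)) return(NULL)
  g3 <- .lu_solve(lu, f2$dx + (C31 * g1 + C32 * g2) / h)
  g4 <- .lu_solve(lu, f2$dx + (C41 * g1 + C42 * g2 + C43 * g3) / h)

  xn <- x + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4
  if (any(!is.finite(xn))) return(NULL)
  err <- E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4
  sc <- atol + rtol * pmax(abs(x), abs(xn))
  list(x = xn, errmax = max(abs(err) / sc))
}

.lu_factor <- function(W) {
  qr(W, LAPACK = TRUE)
}

.lu_solve <- function(lu, b) {
  solve.qr(lu, b)
}

#' @export
print.ccm_trajectory <- function(x, ...) {
  cat("<ccm_trajectory> ", length(x$times), " time points (",
      min(x$times), "-", max(x$times), " min), ",
      ncol(x$values), " species\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ccm_trajectory <- function(x, ...) {
  data.frame(
    time_min = rep(x$times, times = ncol(x$values)),
    species_id = rep(colnames(x$values), each = length(x$times)),
    value_normalized = as.vector(x$values),
    stringsAsFactors = FALSE)
}

#' Solve for the normalized linlog steady state
#'
#' Solves `N_R r(chat) = 0` subject to the moiety totals by a damped Newton
#' iteration started from the reference state, falling back to long-time
#' integration when Newton stalls.  Intended for finite-perturbation analyses
#' (enzyme-level modulations around a stable reference).
#'
#' @param p A `ccm_parameterization`.
#' @param enzyme_levels Optional per-reaction relative enzyme levels
#'   overriding those stored in `p`.
#' @param tol Residual tolerance, relative to the flux scale.
#' @param max_iter Newton iteration budget.
#' @param frozen Species held at their reference value.  Defaults to the
#'   extracellular balanced species: the intracellular steady state is
#'   defined with the medium composition as an external parameter (the
#'   medium pools of a batch culture have no steady state of their own).
#' @return Named normalized steady-state concentration vector (frozen species
#'   reported at 1).
#' @export
linlog_steady_state <- function(p, enzyme_levels = NULL, tol = 1e-10,
                                max_iter = 200L, frozen = NULL) {
  stopifnot(inherits(p, "ccm_parameterization"))
  if (is.null(frozen)) frozen <- extracellular_ids(p$model)
  jac <- linlog_jacobian(p, frozen = frozen)
  if (!jac$stable)
    stop("reference parameterization is not asymptotically stable; ",
         "steady-state continuation is not meaningful")
  ops <- .reduced_ops(p, frozen)
  ops <- .freeze_state(ops, setNames(rep(1, length(ops$bal)), ops$bal))
  eJ0 <- if (is.null(enzyme_levels)) p$enzyme_levels * p$J0
         else enzyme_levels[names(p$J0)] * p$J0
  scale <- max(abs(eJ0), 1e-300)
  x <- setNames(rep(1, length(ops$ind)), ops$ind)

  resid <- function(x) {
    f <- .reduced_rhs(p, ops, x, eJ0)
    if (is.null(f)) return(NULL)
    list(F = drop(ops$NR %*% f$rates), chat = f$chat)
  }
  r <- resid(x)
  for (it in seq_len(max_iter)) {
    nrm <- max(abs(r$F)) / scale
    if (nrm < tol)
      return(.expand_state(ops, x))
    w <- ifelse(r$chat > p$clamp, 1 / r$chat, 0)
    Jn <- ops$NR %*% (eJ0 * ((p$E * rep(w, each = nrow(p$E))) %*% ops$Lhat))
    dx <- tryCatch(solve(Jn, -r$F), error = function(e) NULL)
    if (is.null(dx))
      stop("steady-state solve failed: singular Jacobian")
    lambda <- 1
    repeat {
      xn <- x + lambda * dx
      rn <- if (all(is.finite(xn))) resid(xn) else NULL
      if (!is.null(rn) && max(abs(rn$F)) < max(abs(r$F)) * (1 - 0.25 * lambda)) {
        x <- xn; r <- rn
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        # fall back to integrating towards the attractor
        chat0 <- setNames(rep(1, length(ops$bal)), ops$bal)
        traj <- tryCatch(
          linlog_simulate(.with_enzymes(p, eJ0 / p$J0), chat0,
                          times = c(0, 10^(1:4)), rtol = 1e-10, atol = 1e-12,
                          frozen = ops$frozen),
          error = function(e) NULL)
        if (is.null(traj) || any(!is.finite(traj$values)) ||
            max(abs(traj$values[nrow(traj$values), ])) > 1e6)
          stop("steady-state solve failed: runaway trajectory ",
               "(system appears unstable under these enzyme levels)")
        x <- traj$values[nrow(traj$values), ops$ind]
        r <- resid(x)
        break
      }
    }
  }
  nrm <- max(abs(r$F)) / scale
  if (nrm < tol) return(.expand_state(ops, x))
  stop("steady-state solve did not converge (residual ",
       format(nrm, digits = 3), ")")
}

.with_enzymes <- function(p, enzyme_levels) {
  p$enzyme_levels <- setNames(as.numeric(enzyme_levels), names(p$J0))
  p
}
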