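#' Sample a feasible reference flux distribution
#'
#' Draws a strictly positive flux vector in the null space of the balanced
#' stoichiometric matrix (all fluxes run in their reference direction), with
#' an optional branch-point constraint fixing the split between two
#' competing reactions.  For the packaged model, the default pins the
#' glycolysis : pentose-phosphate split at the glucose-6-phosphate branch to
#' 57 : 43.
#'
#' Positivity is found by minimizing a convex hinge penalty over null-space
#' coordinates (the penalty is zero exactly on the positive cone), after
#' which a seeded random null-space perturbation is applied with
#' backtracking, so that different seeds give different feasible flux maps.
#'
#' @param model A `ccm_model`.
#' @param seed Integer seed.
#' @param split Branch split as a named length-2 vector of fractions summing
#'   to 1 (names = reaction ids), e.g. `c(r2 = 0.57, r10 = 0.43)`; `NULL`
#'   disables the constraint.  Reactions absent from the model are an error.
#' @param scale_reaction,scale The returned vector is scaled so that this
#'   reaction carries flux `scale` (defaults: glucose transport at
#'   1 mmol/l/min; if absent, the largest flux is set to `scale`).
#' @return Named positive flux vector `J0` with `N J0 = 0`.
#' @export
sample_reference_flux <- function(model, seed = 1L,
                                  split = c(r2 = 0.57, r10 = 0.43),
                                  scale_reaction = "r47", scale = 1) {
  stopifnot(inherits(model, "ccm_model"))
  sys <- stoichiometric_matrix(model)
  # steady state constrains the intracellular balances; extracellular medium
  # pools accumulate/deplete at the transport rates (batch culture)
  intra <- setdiff(rownames(sys$N), extracellular_ids(model))
  N <- sys$N[intra, , drop = FALSE]
  rid <- colnames(N)
  A <- N
  if (!is.null(split)) {
    stopifnot(length(split) == 2L, abs(sum(split) - 1) < 1e-12)
    miss <- setdiff(names(split), rid)
    if (length(miss))
      stop("split constraint references unknown reaction(s): ",
           paste(miss, collapse = ", "))
    # v_a/(v_a+v_b) = s_a  <=>  (1-s_a) v_a - s_a v_b = 0
    row <- setNames(numeric(length(rid)), rid)
    row[names(split)[1]] <- split[2]
    row[names(split)[2]] <- -split[1]
    A <- rbind(A, row)
  }
  sv <- svd(A, nu = 0, nv = ncol(A))
  d <- c(sv$d, rep(0, ncol(A) - length(sv$d)))
  tolr <- max(dim(A)) * max(sv$d) * 64 * .Machine$double.eps
  B <- sv$v[, d < tolr, drop = FALSE]
  if (!ncol(B))
    stop("constraint set infeasible: null space is empty after adding the ",
         "split constraint")
  hinge <- function(alpha) {
    v <- drop(B %*% alpha)
    sum(pmax(1 - v, 0)^2)
  }
  hinge_grad <- function(alpha) {
    v <- drop(B %*% alpha)
    drop(-2 * crossprod(B, pmax(1 - v, 0)))
  }
  set.seed(seed)
  v <- NULL
  for (try in 1:20) {
    a0 <- stats::rnorm(ncol(B))
    opt <- stats::optim(a0, hinge, hinge_grad, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    cand <- drop(B %*% opt$par)
    if (all(cand > 0)) { v <- cand; break }
  }
  if (is.null(v)) {
    viol <- rid[drop(B %*% opt$par) <= 0]
    stop("no strictly positive flux vector found; violated reactions: ",
         paste(viol, collapse = ", "))
  }
  # randomize within the positive cone
  delta <- stats::rnorm(ncol(B), 0, 0.2 * stats::median(abs(v)))
  repeat {
    cand <- v + drop(B %*% delta)
    if (all(cand > 0)) { v <- cand; break }
    delta <- delta / 2
    if (max(abs(delta)) < 1e-12) break
  }
  names(v) <- rid
  sref <- if (!is.na(match(scale_reaction, rid))) v[scale_reaction] else max(v)
  v <- v * (scale / unname(sref))
  v
}

#' Sample a stable synthetic parameterization
#'
#' Draws scaled elasticities on the model's sparsity pattern with the
#' conventional signs (substrate +, product -, inhibitor -, activator +) and
#' magnitudes uniform in `mag_range`, and reference concentrations
#' log-uniform in `c0_range` (mmol/l), rejecting draws until the linlog
#' Jacobian is asymptotically stable.
#'
#' @param model A `ccm_model`.
#' @param J0 Named reference flux vector (see [sample_reference_flux()]).
#' @param seed Integer seed.
#' @param mag_range Range of absolute elasticity values.
#' @param c0_range Range of reference concentrations.
#' @param max_tries Rejection cap.
#' @return A stable `ccm_parameterization`.
#' @export
sample_parameters <- function(model, J0, seed = 1L, mag_range = c(0.1, 2),
                              c0_range = c(0.1, 10), max_tries = 1000L) {
  stopifnot(inherits(model, "ccm_model"))
  pat <- elasticity_pattern(model)
  bal <- balanced_ids(model)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    eps <- pat$sign * stats::runif(nrow(pat), mag_range[1], mag_range[2])
    c0 <- setNames(exp(stats::runif(length(bal), log(c0_range[1]),
                                    log(c0_range[2]))), bal)
    p <- parameterization(model,
                          data.frame(reaction = pat$reaction,
                                     species = pat$species, value = eps),
                          J0, c0)
    # the simulated system and the intracellular control subsystem must both
    # be asymptotically stable
    if (linlog_jacobian(p)$stable &&
        linlog_jacobian(p, frozen = extracellular_ids(model))$stable)
      return(p)
  }
  stop("no asymptotically stable parameterization found in ", max_tries,
       " draws; consider narrower elasticity magnitudes")
}

#' Bundle a synthetic ground truth
#'
#' @param parameterization A stable `ccm_parameterization`.
#' @param design A `ccm_design`.
#' @param noise_cv Per-replicate coefficient of variation of the
#'   multiplicative measurement noise (default 0.15, typical of MS-based
#'   metabolite quantification).
#' @param seed Integer seed driving the noise draws.
#' @return A `ccm_truth`.
#' @export
synthetic_truth <- function(parameterization, design, noise_cv = 0.15,
                            seed = 1L) {
  stopifnot(inherits(parameterization, "ccm_parameterization"),
            inherits(design, "ccm_design"))
  structure(list(parameterization = parameterization, design = design,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "ccm_truth")
}

#' Generate a noisy stimulus-response dataset from a synthetic truth
#'
#' Simulates the perturbation experiment, samples the observed species at the
#' design's time grid in replicate, applies multiplicative Gaussian noise
#' (truncated at zero) with the stated per-species CV, and emits the
#' records normalized by the per-species 0- reference estimate -- exactly the
#' normalization an experimenter applies.  The 0- reference block (noisy
#' replicates of the reference state) is included.
#'
#' @param truth A `ccm_truth`.
#' @param rtol,atol Integrator tolerances for the ground-truth trajectory.
#' @return A `ccm_measurements`; the underlying noise-free trajectory is
#'   attached as attribute `"trajectory"` and the normalization basis as
#'   attribute `"reference_estimate"` (absolute units).
#' @export
generate_dataset <- function(truth, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(truth, "ccm_truth"))
  p <- truth$parameterization
  design <- truth$design
  obs <- design$observed
  if (!length(obs)) stop("design has no observed species")
  init <- linlog_initial_state(design, p)
  traj <- suppressMessages(
    linlog_simulate(p, init, design$time_grid, rtol = rtol, atol = atol))
  cv <- truth$noise_cv
  set.seed(truth$seed)
  nrep <- design$replicates
  # 0- reference replicates (normalized truth = 1)
  ref_draws <- matrix(pmax(1 + cv * stats::rnorm(length(obs) * nrep), 0),
                      length(obs), nrep, dimnames = list(obs, NULL))
  ref_mean <- rowMeans(ref_draws)
  ref_sd <- apply(ref_draws, 1, stats::sd)
  if (cv == 0) ref_mean[] <- 1

  comp <- setNames(p$model$species$compartment, p$model$species$id)
  rows <- vector("list", length(obs))
  for (k in seq_along(obs)) {
    s <- obs[k]
    true_vals <- traj$values[, s]
    draws <- matrix(pmax(true_vals * (1 + cv * stats::rnorm(length(true_vals) * nrep)), 0),
                    length(true_vals), nrep)
    norm <- draws / ref_mean[s]
    sds <- apply(norm, 1, stats::sd)
    if (cv == 0) { norm <- matrix(true_vals, length(true_vals), nrep); sds[] <- 0 }
    rows[[k]] <- data.frame(
      time_min = rep(design$time_grid, nrep),
      species_id = s,
      compartment = unname(comp[s]),
      replicate = rep(seq_len(nrep), each = length(true_vals)),
      value_normalized = as.vector(norm),
      sd_normalized = rep(sds, nrep),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  reference <- data.frame(species_id = obs,
                          mean_normalized = unname(ref_mean),
                          sd_normalized = unname(ref_sd),
                          stringsAsFactors = FALSE)
  if (cv == 0) reference$sd_normalized <- 0
  out <- measurement_set(records, reference)
  attr(out, "trajectory") <- traj
  attr(out, "reference_estimate") <- p$c0[obs] * ref_mean
  out
}
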