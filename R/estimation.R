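#' Build a measurement set
#'
#' @param records Data frame with columns `time_min`, `species_id`,
#'   `compartment`, `replicate`, `value_normalized`, `sd_normalized`.
#' @param reference Data frame with columns `species_id`, `mean_normalized`,
#'   `sd_normalized`: the 0- sample, i.e. per-species reference estimates on
#'   the normalized scale (approximately 1).
#' @param sd_floor_rel,sd_floor_abs Variance floor: standard deviations are
#'   floored at `sd_floor_rel` times the replicate mean (and at
#'   `sd_floor_abs` absolutely) to keep the weighted residuals finite when
#'   triplicate spread is spuriously tiny.
#' @return A `ccm_measurements`.
#' @export
measurement_set <- function(records, reference = NULL,
                            sd_floor_rel = 0.05, sd_floor_abs = 1e-6) {
  need <- c("time_min", "species_id", "replicate", "value_normalized",
            "sd_normalized")
  stopifnot(all(need %in% names(records)))
  # floor at a fraction of the replicate mean of the same (species, time) point
  grp <- interaction(records$species_id, records$time_min, drop = TRUE)
  rep_mean <- tapply(abs(records$value_normalized), grp, mean)
  records$sd_normalized <- pmax(records$sd_normalized,
                                sd_floor_rel * rep_mean[grp],
                                sd_floor_abs)
  if (!is.null(reference))
    reference$sd_normalized <- pmax(reference$sd_normalized,
                                    sd_floor_rel * abs(reference$mean_normalized),
                                    sd_floor_abs)
  structure(list(records = records, reference = reference),
            class = "ccm_measurements")
}

#' @export
print.ccm_measurements <- function(x, ...) {
  cat("<ccm_measurements> ", nrow(x$records), " records, ",
      length(unique(x$records$species_id)), " species, ",
      length(unique(x$records$time_min)), " time points\n", sep = "")
  invisible(x)
}

#' Variance-weighted sum of squared residuals
#'
#' `chi2 = sum_k ((c_sim - c_meas)_k / sd_k)^2` over all measurement records,
#' replicates entering individually.  The simulation must cover every
#' measurement time exactly; interpolation is deliberately not supported.
#'
#' @param sim A `ccm_trajectory` of normalized concentrations.
#' @param data A `ccm_measurements`.
#' @param rescale Optional named per-species factors applied to the simulated
#'   values before comparison (used when fitted reference levels differ from
#'   the normalization basis of the data).
#' @return Nonnegative scalar.
#' @export
chi_squared <- function(sim, data, rescale = NULL) {
  stopifnot(inherits(sim, "ccm_trajectory"), inherits(data, "ccm_measurements"))
  rec <- data$records
  ti <- match(rec$time_min, sim$times)
  if (anyNA(ti))
    stop("measurement time(s) not in trajectory: ",
         paste(unique(rec$time_min[is.na(ti)]), collapse = ", "))
  si <- match(rec$species_id, colnames(sim$values))
  if (anyNA(si))
    stop("measured species not simulated: ",
         paste(unique(rec$species_id[is.na(si)]), collapse = ", "))
  pred <- sim$values[cbind(ti, si)]
  if (!is.null(rescale)) pred <- pred * rescale[rec$species_id]
  sum(((pred - rec$value_normalized) / rec$sd_normalized)^2)
}

#' Parameter census of the estimation problem
#'
#' The unknowns of the fitting problem are all in-pattern scaled elasticities
#' plus the independent reference concentration levels (one per balanced
#' species outside the designated moiety-dependent set; the three moiety
#' totals are fixed by those levels).  For the packaged model this gives
#' 174 + 42 = 216 parameters, of which 30 reference levels have direct
#' measurements.
#'
#' @param model A `ccm_model`.
#' @return List with `elasticities`, `reference_levels`, `total`,
#'   `measured_reference`.
#' @export
count_unknowns <- function(model) {
  stopifnot(inherits(model, "ccm_model"))
  pat <- elasticity_pattern(model)
  sys <- stoichiometric_matrix(model)
  moieties <- conserved_moieties(sys)
  bal <- balanced_ids(model)
  dep <- vapply(moieties, function(m) {
    members <- names(m)
    members[which.max(match(members, bal))]
  }, "")
  n_ref <- length(bal) - length(dep)
  list(elasticities = nrow(pat),
       reference_levels = n_ref,
       total = nrow(pat) + n_ref,
       measured_reference = sum(model$species$measured[model$species$balanced]))
}

#' Evolution-strategy options
#'
#' A (mu, lambda) evolution strategy with per-parameter log-normal step-size
#' self-adaptation (learning rates `tau_global = 1/sqrt(2 n)`,
#' `tau_coord = 1/sqrt(2 sqrt(n))`), comma selection, reflection at the box
#' constraints, a large finite penalty for failed simulations, and restart
#' cycles reseeded from the incumbent best.
#'
#' @param budget Total number of objective evaluations.
#' @param mu,lambda Parent/offspring population sizes.
#' @param sigma0 Initial per-parameter mutation step (on the internal scale).
#' @param restart_every Evaluations per restart cycle.
#' @param elasticity_bounds Box constraints for elasticities.
#' @param sign_priors If `TRUE`, elasticities are confined to their
#'   conventional sign (substrate +, product -, inhibitor -, activator +).
#' @param reference_mode `"fit"` (measured reference levels move within
#'   +/- 3 SD of their 0- estimates, unmeasured ones log-uniformly in
#'   `10^unknown_ref_log10_bounds`) or `"fix"`.
#' @param unknown_ref_log10_bounds log10 bounds for unmeasured reference
#'   levels, relative to the scale guess.
#' @param n_starts Independent multi-starts (best result reported); the
#'   budget is spent per start.
#' @param recombine Use pairwise intermediate recombination before mutation.
#' @param rtol,atol Integrator tolerances used during fitting.
#' @param penalty Objective value assigned to failed simulations.
#' @return List of options for [fit_linlog()].
#' @export
es_options <- function(budget = 20000L, mu = 10L, lambda = 70L,
                       sigma0 = 0.3, restart_every = 100000L,
                       elasticity_bounds = c(-20, 20), sign_priors = FALSE,
                       reference_mode = c("fit", "fix"),
                       unknown_ref_log10_bounds = c(-3, 3),
                       n_starts = 1L, recombine = FALSE,
                       rtol = 1e-6, atol = 1e-8,
                       penalty = 1e12) {
  list(budget = as.integer(budget), mu = as.integer(mu),
       lambda = as.integer(lambda), sigma0 = sigma0,
       restart_every = as.integer(restart_every),
       elasticity_bounds = elasticity_bounds, sign_priors = sign_priors,
       reference_mode = match.arg(reference_mode),
       unknown_ref_log10_bounds = unknown_ref_log10_bounds,
       n_starts = as.integer(n_starts), recombine = isTRUE(recombine),
       rtol = rtol, atol = atol, penalty = penalty)
}

# parameter-space description: elasticities + reference-level factors
.fit_space <- function(model, data, options) {
  pat <- elasticity_pattern(model)
  lo_e <- rep(options$elasticity_bounds[1], nrow(pat))
  hi_e <- rep(options$elasticity_bounds[2], nrow(pat))
  if (options$sign_priors) {
    lo_e <- ifelse(pat$sign > 0, 0, lo_e)
    hi_e <- ifelse(pat$sign > 0, hi_e, 0)
  }
  space <- data.frame(kind = rep("elasticity", nrow(pat)),
                      reaction = pat$reaction, species = pat$species,
                      lower = lo_e, upper = hi_e,
                      start = 0.5 * pat$sign,
                      stringsAsFactors = FALSE)
  if (options$reference_mode == "fit") {
    bal <- balanced_ids(model)
    sys <- stoichiometric_matrix(model)
    moieties <- conserved_moieties(sys)
    dep <- vapply(moieties, function(m) names(m)[which.max(match(names(m), bal))], "")
    ind <- setdiff(bal, dep)
    ref <- data$reference
    for (s in ind) {
      i <- if (!is.null(ref)) match(s, ref$species_id) else NA_integer_
      if (!is.na(i)) {
        m <- ref$mean_normalized[i]
        sd <- max(ref$sd_normalized[i], 1e-6)
        space <- rbind(space, data.frame(
          kind = "reference", reaction = NA, species = s,
          lower = max(m - 3 * sd, 1e-6), upper = m + 3 * sd, start = m))
      } else {
        b <- options$unknown_ref_log10_bounds
        # searched in log10 units around the scale guess
        space <- rbind(space, data.frame(
          kind = "reference_log10", reaction = NA, species = s,
          lower = b[1], upper = b[2], start = 0))
      }
    }
  }
  rownames(space) <- NULL
  space
}

# translate a parameter vector into a parameterization + comparison rescaling
.fit_instantiate <- function(theta, space, model, J0, c0_basis, clamp) {
  is_e <- space$kind == "elasticity"
  ela <- data.frame(reaction = space$reaction[is_e],
                    species = space$species[is_e],
                    value = theta[is_e])
  c0 <- c0_basis
  f <- setNames(rep(1, length(c0_basis)), names(c0_basis))
  is_r <- space$kind == "reference"
  f[space$species[is_r]] <- theta[is_r]
  is_l <- space$kind == "reference_log10"
  f[space$species[is_l]] <- 10^theta[is_l]
  c0 <- c0_basis * f
  p <- tryCatch(
    parameterization(model, ela, J0, c0, clamp = clamp),
    error = function(e) NULL)
  list(p = p, rescale = f)
}

#' Fit elasticities and reference levels to time-series data
#'
#' Minimizes the variance-weighted residual between simulated and measured
#' normalized metabolite time courses with a self-adaptive (mu, lambda)
#' evolution strategy.  The reference flux distribution `J0` is a fixed input
#' (two-step identification: fluxes from an isotopic-tracer study, kinetics
#' from the stimulus-response data).  Deterministic given `seed`.
#'
#' @param model A `ccm_model`.
#' @param data A `ccm_measurements` (its reference block supplies the
#'   normalization basis and the constraints of measured reference levels).
#' @param design A `ccm_design` describing the perturbation.
#' @param J0 Named reference flux vector.
#' @param c0_basis Named reference-concentration basis in absolute units
#'   (measured species: the 0- estimate; unmeasured: a scale guess, default
#'   1).  Fitted reference levels are multiplicative factors on this basis.
#' @param options See [es_options()].
#' @param seed Integer seed controlling all randomness.
#' @param start Optional named start vector overriding the default start.
#' @param clamp Clamp floor passed to the parameterization.
#' @return A `ccm_fit`: list with the best `parameterization`, `chi2`,
#'   `theta`, the search `space`, `trace` (best-so-far per generation),
#'   `evaluations`, `restarts` and `seed`.
#' @export
fit_linlog <- function(model, data, design, J0, c0_basis = NULL,
                       options = es_options(), seed = 1L, start = NULL,
                       clamp = 1e-6) {
  stopifnot(inherits(model, "ccm_model"), inherits(data, "ccm_measurements"),
            inherits(design, "ccm_design"))
  bal <- balanced_ids(model)
  if (is.null(c0_basis)) c0_basis <- setNames(rep(1, length(bal)), bal)
  c0_basis <- c0_basis[bal]

  space <- .fit_space(model, data, options)
  n <- nrow(space)
  lower <- space$lower; upper <- space$upper

  objective <- function(theta) {
    inst <- .fit_instantiate(theta, space, model, J0, c0_basis, clamp)
    if (is.null(inst$p)) return(options$penalty)
    init <- tryCatch(linlog_initial_state(design, inst$p),
                     error = function(e) NULL)
    if (is.null(init)) return(options$penalty)
    sim <- tryCatch(
      suppressMessages(
        linlog_simulate(inst$p, init, design$time_grid,
                        rtol = options$rtol, atol = options$atol)),
      error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim$values))) return(options$penalty)
    chi2 <- tryCatch(chi_squared(sim, data, rescale = inst$rescale),
                     error = function(e) NA_real_)
    if (!is.finite(chi2)) return(options$penalty)
    # stationary (0-) information on fitted reference levels
    is_r <- space$kind == "reference"
    if (any(is_r)) {
      ref <- data$reference
      i <- match(space$species[is_r], ref$species_id)
      chi2 <- chi2 + sum(((theta[is_r] - ref$mean_normalized[i]) /
                            pmax(ref$sd_normalized[i], 1e-6))^2)
    }
    chi2
  }

  best <- NULL
  for (k in seq_len(options$n_starts)) {
    res <- .run_es(objective, space, options,
                   seed = seed + (k - 1L) * 1000L, start = start)
    if (is.null(best) || res$chi2 < best$chi2) best <- res
  }
  inst <- .fit_instantiate(best$theta, space, model, J0, c0_basis, clamp)
  best$parameterization <- inst$p
  best$rescale <- inst$rescale
  best$space <- space
  best$seed <- seed
  class(best) <- "ccm_fit"
  best
}

# self-adaptive (mu, lambda)-ES with restarts; returns best-ever solution
.run_es <- function(objective, space, options, seed, start = NULL) {
  set.seed(seed)
  n <- nrow(space)
  lower <- space$lower; upper <- space$upper
  tau_g <- 1 / sqrt(2 * n)
  tau_c <- 1 / sqrt(2 * sqrt(n))
  mu <- options$mu; lambda <- options$lambda

  reflect <- function(x) {
    span <- upper - lower
    # reflect into the box (twice handles far overshoots; then clip)
    for (dummy in 1:2) {
      x <- ifelse(x < lower, 2 * lower - x, x)
      x <- ifelse(x > upper, 2 * upper - x, x)
    }
    pmin(pmax(x, lower), upper)
  }

  start0 <- if (is.null(start)) reflect(space$start) else reflect(start)
  init_pop <- function(center, sigma_scale) {
    pop <- vector("list", mu)
    for (i in seq_len(mu)) {
      x <- if (i == 1L) center
           else reflect(center + stats::rnorm(n, 0, sigma_scale * (upper - lower) / 10))
      pop[[i]] <- list(x = x, sigma = rep(options$sigma0, n),
                       fit = objective(x))
    }
    pop
  }

  evals <- 0L
  restarts <- 0L
  trace <- numeric(0)
  pop <- init_pop(start0, 1)
  evals <- evals + mu
  best <- pop[[which.min(vapply(pop, `[[`, 0, "fit"))]]
  cycle_end <- min(options$budget, options$restart_every)

  while (evals < options$budget) {
    offspring <- vector("list", lambda)
    for (o in seq_len(lambda)) {
      if (isTRUE(options$recombine)) {
        # pairwise intermediate recombination before self-adaptive mutation
        pick <- sample.int(mu, 2, replace = TRUE)
        xr <- (pop[[pick[1]]]$x + pop[[pick[2]]]$x) / 2
        sr <- sqrt(pop[[pick[1]]]$sigma * pop[[pick[2]]]$sigma)
      } else {
        par <- pop[[sample.int(mu, 1)]]
        xr <- par$x; sr <- par$sigma
      }
      g <- stats::rnorm(1)
      sigma <- sr * exp(tau_g * g + tau_c * stats::rnorm(n))
      sigma <- pmin(pmax(sigma, 1e-8), (upper - lower) / 2)
      x <- reflect(xr + sigma * stats::rnorm(n))
      offspring[[o]] <- list(x = x, sigma = sigma, fit = objective(x))
    }
    evals <- evals + lambda
    fits <- vapply(offspring, `[[`, 0, "fit")
    sel <- order(fits)[seq_len(mu)]
    pop <- offspring[sel]
    if (fits[sel[1]] < best$fit) best <- offspring[[sel[1]]]
    trace <- c(trace, best$fit)
    if (evals >= cycle_end && evals < options$budget) {
      # restart cycle boundary: reseed the population from the incumbent
      restarts <- restarts + 1L
      pop <- init_pop(best$x, 1)
      evals <- evals + mu
      cycle_end <- min(options$budget, cycle_end + options$restart_every)
    }
  }
  if (best$fit >= options$penalty)
    stop("all candidate simulations failed during the evolution strategy (",
         evals, " evaluations, penalty objective everywhere)")
  list(theta = best$x, chi2 = best$fit, trace = trace,
       evaluations = evals, restarts = restarts)
}

#' @export
print.ccm_fit <- function(x, ...) {
  cat("<ccm_fit> chi2 = ", format(x$chi2, digits = 6), " after ",
      x$evaluations, " evaluations (", x$restarts, " restarts)\n", sep = "")
  invisible(x)
}
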