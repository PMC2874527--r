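#' Jacobian and local stability of a linlog parameterization
#'
#' Evaluates the reduced Jacobian `M = N_R diag(e J0) E diag(c0)^-1 L` at the
#' reference state.  The reference steady state is asymptotically stable iff
#' all eigenvalue real parts are negative; the number of complex-conjugate
#' eigenvalue pairs indicates a capacity for damped oscillations.
#'
#' @param p A `ccm_parameterization`.
#' @param frozen Species treated as external parameters (their dynamics are
#'   excluded).  Default none: the Jacobian of the full simulated system.
#'   Control analysis uses the intracellular subsystem (extracellular pools
#'   frozen), see [control_coefficients()].
#' @return List with `jacobian` (independent-species square matrix, 1/min),
#'   `eigenvalues` (complex), `stable` (logical) and `conjugate_pairs`.
#' @export
linlog_jacobian <- function(p, frozen = character()) {
  stopifnot(inherits(p, "ccm_parameterization"))
  sys <- p$system
  act <- setdiff(sys$independent_ids, frozen)
  M <- sys$N_R[act, , drop = FALSE] %*%
    ((p$enzyme_levels * p$J0) * p$E) %*%
    ((1 / p$c0) * sys$L)[, act, drop = FALSE]
  dimnames(M) <- list(act, act)
  ev <- eigen(M, only.values = TRUE)$values
  pairs <- sum(Im(ev) > 1e-9 * max(abs(ev), 1e-300))
  list(jacobian = M, eigenvalues = ev,
       stable = all(Re(ev) < 0), conjugate_pairs = pairs)
}

#' Scaled flux and concentration control coefficients
#'
#' Computes the scaled concentration control coefficients
#' `C_S = -diag(c0)^-1 L M^-1 N_R diag(J0)` and the flux control
#' coefficients `C_J = I + E C_S` (reactions x reactions) with respect to
#' relative enzyme-activity changes, where `M = N_R diag(J0) E diag(c0)^-1 L`
#' is the Jacobian of the subsystem whose steady state is analyzed.
#'
#' Control analysis is carried out on the intracellular steady state: the
#' extracellular medium pools are external parameters (they belong to a batch
#' culture and have no steady state), so `C_S` covers the intracellular
#' balanced species.  With that convention the summation theorems (rows of
#' `C_J` sum to 1, rows of `C_S` to 0) hold by construction whenever `M` is
#' well conditioned.
#'
#' @param p A `ccm_parameterization` (must be asymptotically stable).
#' @param frozen Species treated as external parameters; defaults to the
#'   extracellular balanced species.
#' @return List with matrices `C_S`, `C_J`, plus the `jacobian` result of the
#'   analyzed subsystem.
#' @export
control_coefficients <- function(p, frozen = NULL) {
  stopifnot(inherits(p, "ccm_parameterization"))
  if (is.null(frozen)) frozen <- extracellular_ids(p$model)
  jac <- linlog_jacobian(p, frozen = frozen)
  M <- jac$jacobian
  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stop("structurally singular control problem: Jacobian condition number ",
         format(kap, digits = 3), ", rank ", qr(M)$rank, " of ", nrow(M))
  sys <- p$system
  act <- rownames(M)
  rows <- setdiff(names(p$c0), frozen)
  J <- p$enzyme_levels * p$J0
  NRJ <- sys$N_R[act, , drop = FALSE] * rep(J, each = length(act))
  C_S <- -(1 / p$c0[rows]) *
    (sys$L[rows, act, drop = FALSE] %*% solve(M, NRJ))
  dimnames(C_S) <- list(rows, names(p$J0))
  C_J <- diag(length(J)) + p$E[, rows, drop = FALSE] %*% C_S
  dimnames(C_J) <- list(names(p$J0), names(p$J0))
  list(C_S = C_S, C_J = C_J, jacobian = jac, frozen = frozen)
}

#' Partial flux control coefficients
#'
#' Splits every flux control coefficient into its single-mediator summands
#' `pFCC[i, j, x] = eps_ix * C_S[x, j]`: the fraction of the control of
#' enzyme j over flux i that is transmitted through metabolite x.  Only
#' in-pattern (reaction, mediator) pairs carry entries.  The decomposition
#' identity `C_J[i, j] = delta_ij + sum_x pFCC[i, j, x]` is exact.  Values
#' are unscaled (not divided by the total flux control coefficient).
#'
#' @param p A `ccm_parameterization`.
#' @param cc Optional result of [control_coefficients()] to reuse.
#' @return Data frame with columns `flux`, `enzyme`, `mediator`, `value`.
#' @export
partial_flux_control <- function(p, cc = NULL) {
  stopifnot(inherits(p, "ccm_parameterization"))
  if (is.null(cc)) cc <- control_coefficients(p)
  nz <- which(p$E != 0, arr.ind = TRUE)
  # frozen (external) mediators transmit no systemic control
  nz <- nz[colnames(p$E)[nz[, 2]] %in% rownames(cc$C_S), , drop = FALSE]
  fluxes <- rownames(p$E)[nz[, 1]]
  mediators <- colnames(p$E)[nz[, 2]]
  eps <- p$E[nz]
  enzymes <- colnames(cc$C_J)
  out <- data.frame(
    flux = rep(fluxes, times = length(enzymes)),
    enzyme = rep(enzymes, each = length(fluxes)),
    mediator = rep(mediators, times = length(enzymes)),
    value = as.vector(outer(seq_along(eps), seq_along(enzymes),
                            function(i, j) eps[i] * cc$C_S[cbind(mediators[i], enzymes[j])])),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compose a flux control coefficient from its partial summands
#'
#' `C_J[i, j] = delta_ij + sum_x pFCC[i, j, x]`; the `+1` direct term applies
#' on the diagonal (an enzyme's proportional effect on its own rate).
#'
#' @param partials Numeric vector of partial flux control coefficients of one
#'   (flux, enzyme) pair.
#' @param flux,enzyme Reaction ids of the controlled flux and of the perturbed
#'   enzyme (the direct term enters iff they coincide).
#' @return The composed total flux control coefficient.
#' @export
fcc_from_partials <- function(partials, flux, enzyme) {
  sum(partials) + as.numeric(identical(flux, enzyme))
}

#' Partial internal response coefficients
#'
#' For metabolite x and enzyme j, `IRC[x, j] = pFCC[j, j, x]` quantifies how
#' much reaction j contributes to counteracting a perturbation in x; by the
#' connectivity theorem the coefficients of every metabolite outside a
#' conserved moiety sum to -1.  Moiety members (ATP/ADP/AMP, NAD/NADH,
#' NADP/NADPH in the packaged model) are excluded: a perturbation of a
#' conserved pool cannot be relaxed back to the previous steady state.
#'
#' @param p A `ccm_parameterization`.
#' @param pfc Optional result of [partial_flux_control()] to reuse.
#' @return Matrix (non-moiety balanced species x reactions); entries outside
#'   the elasticity pattern are zero.
#' @export
internal_response <- function(p, pfc = NULL) {
  stopifnot(inherits(p, "ccm_parameterization"))
  if (is.null(pfc)) pfc <- partial_flux_control(p)
  moiety_members <- unique(unlist(lapply(p$system$moieties, names)))
  keep <- setdiff(intersect(names(p$c0), unique(pfc$mediator)),
                  moiety_members)
  irc <- matrix(0, length(keep), length(p$J0),
                dimnames = list(keep, names(p$J0)))
  self <- pfc[pfc$flux == pfc$enzyme & pfc$mediator %in% keep, ]
  irc[cbind(self$mediator, self$enzyme)] <- self$value
  irc
}

#' Write control-analysis tables
#'
#' Serializes flux control coefficients (`fcc.tsv`), concentration control
#' coefficients (`ccc.tsv`), partial flux control coefficients in long format
#' (`partial_fcc.tsv`), internal response coefficients (`irc.tsv`) and the
#' Jacobian eigenvalues (`eigenvalues.tsv`) with reaction/species id headers.
#' Floating point values are written with 17 significant digits so that a
#' read-back round-trips exactly.
#'
#' @param result List as returned by [control_coefficients()], optionally
#'   with elements `partial_fcc` and `irc`.
#' @param model The `ccm_model` the result belongs to.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
mca_report <- function(result, model, dir) {
  if (is.null(result$C_J) || !nrow(result$C_J)) stop("empty control-analysis result")
  stopifnot(inherits(model, "ccm_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fcc = file.path(dir, "fcc.tsv"),
    ccc = file.path(dir, "ccc.tsv"),
    partial_fcc = file.path(dir, "partial_fcc.tsv"),
    irc = file.path(dir, "irc.tsv"),
    eigenvalues = file.path(dir, "eigenvalues.tsv"))
  .write_matrix_tsv(result$C_J, "flux_id", paths["fcc"])
  .write_matrix_tsv(result$C_S, "species_id", paths["ccc"])
  if (!is.null(result$partial_fcc)) {
    pf <- result$partial_fcc
    pf$value <- .num17(pf$value)
    utils::write.table(pf, paths["partial_fcc"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$irc))
    .write_matrix_tsv(result$irc, "species_id", paths["irc"])
  ev <- result$jacobian$eigenvalues
  utils::write.table(
    data.frame(re = .num17(Re(ev)), im = .num17(Im(ev))),
    paths["eigenvalues"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.num17 <- function(x) formatC(x, digits = 17, format = "g")

.write_matrix_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m), apply(m, 2, .num17),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read back a matrix written by [mca_report()]
#'
#' @param path Path to a TSV with an id column followed by numeric columns.
#' @return Numeric matrix with row names from the id column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
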