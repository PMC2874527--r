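#' Path to the packaged HepG2 central carbon metabolism model
#'
#' The packaged model transcribes the 49-reaction stoichiometry (glycolysis,
#' pentose-phosphate pathway, TCA cycle, cofactor turnover, 5 transport steps)
#' and the 31 literature-curated activator/inhibitor influences of the HepG2
#' central carbon metabolism, with 45 balanced species (40 intracellular,
#' 5 extracellular) and 3 conserved moieties (adenylates, NAD(H), NADP(H)).
#'
#' @return Path to the model JSON file shipped with the package.
#' @export
hepg2_model_file <- function() {
  system.file("extdata", "hepg2_ccm.model.json", package = "linlogmca",
              mustWork = TRUE)
}

#' Load and validate a metabolic network model
#'
#' Reads a model definition (species with compartment/balanced/measured flags,
#' reactions with signed stoichiometry and modifier lists) from a JSON file and
#' validates it.  Intracellular species declared balanced but only ever
#' produced or only ever consumed are dead ends; they are demoted to boundary
#' status with a warning.  Extracellular species are exempt from the dead-end
#' scan: each one legitimately appears in a single transport step and its mass
#' balance is the accumulation/depletion of the medium pool.
#'
#' @param model_file Path to a model JSON file, see [hepg2_model_file()] for
#'   the packaged schema example.
#' @return A `ccm_model`: list with a `species` data frame and a `reactions`
#'   list (id, name, named `stoichiometry` vector with negative entries for
#'   substrates, `activators`, `inhibitors`).
#' @export
load_network <- function(model_file) {
  raw <- jsonlite::fromJSON(model_file, simplifyVector = FALSE)
  if (is.null(raw$species) || is.null(raw$reactions))
    stop("model schema error: need 'species' and 'reactions' blocks")
  if (length(raw$reactions) == 0L)
    stop("model schema error: zero reactions")

  species <- do.call(rbind, lapply(raw$species, function(s) {
    data.frame(
      id = s$id, name = s$name %||% s$id,
      compartment = s$compartment, balanced = isTRUE(s$balanced),
      measured = isTRUE(s$measured),
      reference_concentration = as.numeric(s$reference_concentration %||% NA),
      stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(species$id))
    stop("model schema error: duplicate species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  bad_comp <- setdiff(species$compartment,
                      c("intracellular", "extracellular", "boundary"))
  if (length(bad_comp))
    stop("model schema error: unknown compartment: ",
         paste(bad_comp, collapse = ", "))
  if (any(species$balanced & species$compartment == "boundary"))
    stop("model schema error: boundary species cannot be balanced")

  reactions <- lapply(raw$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    if (is.null(st) || !length(st))
      stop("model schema error: reaction ", r$id, " has empty stoichiometry")
    if (any(st == 0))
      stop("model schema error: zero coefficient in reaction ", r$id)
    mods <- c(unlist(r$activators), unlist(r$inhibitors))
    unknown <- setdiff(c(names(st), mods), species$id)
    if (length(unknown))
      stop("model schema error: reaction ", r$id,
           " references unknown species: ", paste(unknown, collapse = ", "))
    list(id = r$id, name = r$name %||% r$id, stoichiometry = st,
         activators = as.character(unlist(r$activators)),
         inhibitors = as.character(unlist(r$inhibitors)))
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("model schema error: duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids

  model <- structure(list(species = species, reactions = reactions,
                          name = raw$name %||% "metabolic network"),
                     class = "ccm_model")

  # dead-end scan (intracellular only, see above)
  scan <- .dead_end_scan(model)
  if (length(scan)) {
    warning("demoting dead-end species to boundary: ",
            paste(scan, collapse = ", "), call. = FALSE)
    model$species$balanced[model$species$id %in% scan] <- FALSE
    model$species$compartment[model$species$id %in% scan] <- "boundary"
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced intracellular species that are produced-only or consumed-only
.dead_end_scan <- function(model) {
  sp <- model$species
  cand <- sp$id[sp$balanced & sp$compartment == "intracellular"]
  prod <- cons <- setNames(logical(length(cand)), cand)
  for (r in model$reactions) {
    st <- r$stoichiometry[names(r$stoichiometry) %in% cand]
    prod[names(st)[st > 0]] <- TRUE
    cons[names(st)[st < 0]] <- TRUE
  }
  cand[!(prod & cons)]
}

balanced_ids <- function(model)
  model$species$id[model$species$balanced]

extracellular_ids <- function(model)
  model$species$id[model$species$balanced &
                     model$species$compartment == "extracellular"]

reaction_ids <- function(model)
  unname(vapply(model$reactions, `[[`, "", "id"))

#' @export
print.ccm_model <- function(x, ...) {
  sp <- x$species
  cat("<ccm_model> ", x$name, "\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      ", balanced species: ", sum(sp$balanced),
      " (", sum(sp$balanced & sp$compartment == "intracellular"),
      " intracellular, ",
      sum(sp$balanced & sp$compartment == "extracellular"),
      " extracellular)\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of the balanced species
#'
#' Rows are the balanced species in file order, columns the reactions in file
#' order; boundary species contribute no row.  Fractional coefficients (e.g.
#' the 0.6/0.2 of succinate dehydrogenase or the P/O-ratio 2.5 of oxidative
#' phosphorylation) are preserved exactly.
#'
#' @param model A `ccm_model`.
#' @return A `ccm_stoich` object: list with the matrix `N`, the originating
#'   `model`, and (after [reduce_system()]) the reduced system.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "ccm_model"))
  bal <- balanced_ids(model)
  rid <- reaction_ids(model)
  N <- matrix(0, length(bal), length(rid), dimnames = list(bal, rid))
  for (r in model$reactions) {
    keep <- intersect(names(r$stoichiometry), bal)
    N[keep, r$id] <- r$stoichiometry[keep]
  }
  structure(list(N = N, model = model), class = "ccm_stoich")
}

#' Conserved moieties of a stoichiometric system
#'
#' Computes an integer basis of the left null space of the balanced
#' stoichiometric matrix by exact rational elimination, so that `g %*% N == 0`
#' holds exactly for every returned vector `g`.  Vectors are scaled to the
#' smallest integers and ordered lexicographically by their smallest
#' participating species id.  A warning is raised if any basis vector has
#' mixed signs (not a nonnegative moiety).
#'
#' @param system A `ccm_stoich` (or a `ccm_model`, which is converted).
#' @return List of named integer vectors over the balanced species (nonzero
#'   entries only).
#' @export
conserved_moieties <- function(system) {
  if (inherits(system, "ccm_model")) system <- stoichiometric_matrix(system)
  stopifnot(inherits(system, "ccm_stoich"))
  N <- system$N
  G <- rational_left_null(N)
  if (!ncol(G)) return(list())
  vecs <- lapply(seq_len(ncol(G)), function(k) {
    v <- G[, k]
    names(v) <- rownames(N)
    v[v != 0]
  })
  mixed <- vapply(vecs, function(v) any(v < 0) && any(v > 0), TRUE)
  if (any(mixed))
    warning("left null space basis contains mixed-sign vectors; ",
            "returning raw basis", call. = FALSE)
  ord <- order(vapply(vecs, function(v) min(names(v)), ""))
  vecs[ord]
}

#' Reduce a stoichiometric system along its conserved moieties
#'
#' Splits the balanced species into independent and dependent sets (one
#' dependent species per conserved moiety: its last member in species-file
#' order), and builds the reduced matrix `N_R`, the link matrix `L` with
#' `N = L N_R`, and the affine offsets such that
#' `c = L c_independent + offset`, where the offsets carry the moiety totals
#' computed from the reference concentrations `c0`.
#'
#' @param system A `ccm_stoich`.
#' @param c0 Named vector of reference concentrations for all balanced
#'   species (needed for the moiety totals).
#' @return The `ccm_stoich` augmented with `moieties`, `independent_ids`,
#'   `dependent_ids`, `N_R`, `L`, `offset` and `totals`.
#' @export
reduce_system <- function(system, c0) {
  stopifnot(inherits(system, "ccm_stoich"))
  N <- system$N
  bal <- rownames(N)
  moieties <- conserved_moieties(system)
  dep <- vapply(moieties, function(m) {
    members <- names(m)
    members[which.max(match(members, bal))]
  }, "")
  ind <- setdiff(bal, dep)

  totals <- NULL
  offset <- setNames(numeric(length(bal)), bal)
  if (length(moieties)) {
    missing_c0 <- setdiff(unlist(lapply(moieties, names)), names(c0))
    if (length(missing_c0))
      stop("reference concentration missing for moiety member(s): ",
           paste(missing_c0, collapse = ", "))
    totals <- vapply(moieties, function(m) sum(m * c0[names(m)]), 0)
    names(totals) <- vapply(moieties, function(m)
      paste(names(m), collapse = "+"), "")
  }

  L <- matrix(0, length(bal), length(ind), dimnames = list(bal, ind))
  L[cbind(ind, ind)] <- 1
  for (k in seq_along(moieties)) {
    m <- moieties[[k]]
    d <- dep[k]
    others <- setdiff(names(m), d)
    # g. c = T  =>  c_d = (T - sum_others g_o c_o) / g_d
    L[d, others] <- -m[others] / m[d]
    offset[d] <- totals[k] / m[d]
  }
  system$moieties <- moieties
  system$independent_ids <- ind
  system$dependent_ids <- dep
  system$N_R <- N[ind, , drop = FALSE]
  system$L <- L
  system$offset <- offset
  system$totals <- totals
  system$c0 <- c0[bal]
  system
}

#' Structural validation report
#'
#' Counts reactions, transport steps (reactions touching an extracellular
#' species), balanced species by compartment, conserved moieties, regulatory
#' effects, the size of the scaled-elasticity sparsity pattern, the rank of
#' the stoichiometric matrix, and lists dead-end violations.
#'
#' @param model A `ccm_model`.
#' @return A `ccm_report` list of counts and violations.
#' @export
structural_report <- function(model) {
  stopifnot(inherits(model, "ccm_model"))
  sys <- stoichiometric_matrix(model)
  moieties <- conserved_moieties(sys)
  pat <- elasticity_pattern(model)
  sp <- model$species
  ex_ids <- sp$id[sp$compartment == "extracellular"]
  transport <- vapply(model$reactions, function(r)
    any(names(r$stoichiometry) %in% ex_ids), TRUE)
  report <- list(
    reactions = length(model$reactions),
    transport_steps = sum(transport),
    balanced_species = sum(sp$balanced),
    balanced_intracellular = sum(sp$balanced & sp$compartment == "intracellular"),
    balanced_extracellular = sum(sp$balanced & sp$compartment == "extracellular"),
    moieties = length(moieties),
    rank = rational_rank(sys$N),
    inhibitions = sum(lengths(lapply(model$reactions, `[[`, "inhibitors"))),
    activations = sum(lengths(lapply(model$reactions, `[[`, "activators"))),
    elasticities = nrow(pat),
    dead_ends = .dead_end_scan(model)
  )
  structure(report, class = "ccm_report")
}

#' @export
print.ccm_report <- function(x, ...) {
  cat("<ccm_report>\n")
  cat("  reactions:          ", x$reactions,
      " (", x$transport_steps, " transport steps)\n", sep = "")
  cat("  balanced species:   ", x$balanced_species,
      " (", x$balanced_intracellular, " intracellular, ",
      x$balanced_extracellular, " extracellular)\n", sep = "")
  cat("  rank(N):            ", x$rank, "\n", sep = "")
  cat("  conserved moieties: ", x$moieties, "\n", sep = "")
  cat("  regulatory effects: ", x$inhibitions + x$activations,
      " (", x$inhibitions, " inhibitions, ", x$activations,
      " activations)\n", sep = "")
  cat("  scaled elasticities:", x$elasticities, "\n")
  if (length(x$dead_ends))
    cat("  DEAD ENDS:          ", paste(x$dead_ends, collapse = ", "), "\n")
  else cat("  dead ends:           none\n")
  invisible(x)
}

#' Scaled-elasticity sparsity pattern
#'
#' One elasticity per (reaction, balanced substrate-or-product) pair --
#' counted once per species per reaction regardless of the stoichiometric
#' coefficient, boundary species excluded -- plus one per modifier link.
#' The conventional signs (substrate +, product -, activator +, inhibitor -)
#' are reported for use as sampling/sign priors.
#'
#' @param model A `ccm_model`.
#' @return Data frame with columns `reaction`, `species`, `role`, `sign`.
#' @export
elasticity_pattern <- function(model) {
  stopifnot(inherits(model, "ccm_model"))
  bal <- balanced_ids(model)
  rows <- lapply(model$reactions, function(r) {
    st <- r$stoichiometry[names(r$stoichiometry) %in% bal]
    out <- data.frame(
      reaction = rep(r$id, length(st)),
      species = names(st),
      role = ifelse(st < 0, "substrate", "product"),
      stringsAsFactors = FALSE)
    if (length(r$activators))
      out <- rbind(out, data.frame(reaction = r$id, species = r$activators,
                                   role = "activator"))
    if (length(r$inhibitors))
      out <- rbind(out, data.frame(reaction = r$id, species = r$inhibitors,
                                   role = "inhibitor"))
    out
  })
  pat <- do.call(rbind, rows)
  rownames(pat) <- NULL
  dup <- duplicated(pat[c("reaction", "species")])
  if (any(dup)) pat <- pat[!dup, ]
  pat$sign <- ifelse(pat$role %in% c("substrate", "activator"), 1, -1)
  pat
}
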