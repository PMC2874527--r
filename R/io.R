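# Readers and writers for the pipeline's plain-text artifacts.  All tabular
# output is UTF-8 CSV/TSV with stable id headers; floats carry 17 significant
# digits so that write -> read round-trips exactly.

.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a trajectory as tidy CSV
#'
#' Columns: `time_min`, `species_id`, `compartment`, `value_normalized`.
#'
#' @param traj A `ccm_trajectory`.
#' @param model The `ccm_model` (supplies compartments).
#' @param path Output CSV path.
#' @return `write_trajectory` invisibly returns `path`; `read_trajectory`
#'   returns a `ccm_trajectory`.
#' @export
write_trajectory <- function(traj, model, path) {
  stopifnot(inherits(traj, "ccm_trajectory"))
  df <- as.data.frame(traj)
  comp <- setNames(model$species$compartment, model$species$id)
  df$compartment <- comp[df$species_id]
  df <- df[c("time_min", "species_id", "compartment", "value_normalized")]
  df$value_normalized <- .fmt_num(df$value_normalized)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time_min <- as.numeric(df$time_min)
  times <- sort(unique(df$time_min))
  species <- unique(df$species_id)
  values <- matrix(NA_real_, length(times), length(species),
                   dimnames = list(NULL, species))
  values[cbind(match(df$time_min, times), match(df$species_id, species))] <-
    df$value_normalized
  structure(list(times = times, values = values, species = species),
            class = "ccm_trajectory")
}

#' Write / read a parameterization as structured JSON
#'
#' Stores the sparse elasticity triples, `J0`, `c0`, enzyme levels and the
#' clamp floor with full precision.
#'
#' @param p A `ccm_parameterization`.
#' @param path Output JSON path.
#' @param model A `ccm_model` used to rebuild the object on read.
#' @return `write_parameterization` invisibly returns `path`;
#'   `read_parameterization` returns a `ccm_parameterization`.
#' @export
write_parameterization <- function(p, path) {
  stopifnot(inherits(p, "ccm_parameterization"))
  nz <- which(p$E != 0, arr.ind = TRUE)
  obj <- list(
    elasticities = data.frame(reaction = rownames(p$E)[nz[, 1]],
                              species = colnames(p$E)[nz[, 2]],
                              value = p$E[nz]),
    J0 = as.list(p$J0), c0 = as.list(p$c0),
    enzyme_levels = as.list(p$enzyme_levels), clamp = p$clamp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_parameterization
#' @export
read_parameterization <- function(path, model) {
  obj <- jsonlite::fromJSON(path)
  parameterization(model, obj$elasticities,
                   J0 = unlist(obj$J0), c0 = unlist(obj$c0),
                   enzyme_levels = unlist(obj$enzyme_levels),
                   clamp = obj$clamp)
}

#' Write / read a measurement set as CSV
#'
#' The records go to `path`; the 0- reference block goes to a sibling file
#' with suffix `.reference.csv`.
#'
#' @param data A `ccm_measurements`.
#' @param path Records CSV path.
#' @return `write_measurements` invisibly returns `path`;
#'   `read_measurements` returns a `ccm_measurements`.
#' @export
write_measurements <- function(data, path) {
  stopifnot(inherits(data, "ccm_measurements"))
  rec <- data$records
  rec$value_normalized <- .fmt_num(rec$value_normalized)
  rec$sd_normalized <- .fmt_num(rec$sd_normalized)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  if (!is.null(data$reference)) {
    ref <- data$reference
    ref$mean_normalized <- .fmt_num(ref$mean_normalized)
    ref$sd_normalized <- .fmt_num(ref$sd_normalized)
    utils::write.csv(ref, .reference_path(path), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

.reference_path <- function(path) sub("\\.csv$", ".reference.csv", path)

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$time_min <- as.numeric(rec$time_min)
  rec$replicate <- as.integer(rec$replicate)
  rec$value_normalized <- as.numeric(rec$value_normalized)
  rec$sd_normalized <- as.numeric(rec$sd_normalized)
  refp <- .reference_path(path)
  ref <- if (file.exists(refp)) utils::read.csv(refp, stringsAsFactors = FALSE)
         else NULL
  # data were floored when written; do not floor again
  measurement_set(rec, ref, sd_floor_rel = 0, sd_floor_abs = 0)
}

#' Write / read a perturbation design as JSON
#'
#' @param design A `ccm_design`.
#' @param path Output JSON path.
#' @return `write_design` invisibly returns `path`; `read_design` returns a
#'   `ccm_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ccm_design"))
  jsonlite::write_json(
    list(post_extracellular = as.list(design$post_extracellular),
         time_grid = design$time_grid, observed = design$observed,
         replicates = design$replicates),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::fromJSON(path)
  perturbation_design(unlist(obj$post_extracellular),
                      time_grid = obj$time_grid,
                      observed = as.character(obj$observed),
                      replicates = obj$replicates)
}

# provenance sidecar written next to every CLI artifact set
.write_provenance <- function(dir, command, model_file = NULL, seed = NULL) {
  obj <- list(command = command,
              package = "linlogmca",
              version = as.character(utils::packageVersion("linlogmca")),
              seed = seed)
  if (!is.null(model_file))
    obj$model_md5 <- unname(tools::md5sum(model_file))
  jsonlite::write_json(obj, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null")
  invisible()
}
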