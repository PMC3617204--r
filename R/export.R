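# Text exports: tidy CSVs for trajectories / scans / datasets, JSON for
# models, fit results and sensitivity rankings.

#' Export a trajectory
#'
#' Tidy CSV with columns `time`, `species`, `level`, or a JSON document also
#' carrying the boundary levels and solver metadata.
#'
#' @param trajectory A `cd4_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_trajectory_json <- function(trajectory, path) {
  jsonlite::write_json(list(
    time = trajectory$time,
    state = as.data.frame.matrix(trajectory$state),
    boundary = as.list(trajectory$boundary),
    recipe = trajectory$recipe_label,
    solver = trajectory$solver
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a scan result
#'
#' CSV with the grid-value column first, one row per scanned value, one
#' column per readout (plus the phenotype call when present).
#'
#' @param scan A `cd4_scan`.
#' @param path Output path.
#' @export
write_scan_csv <- function(scan, path) {
  df <- data.frame(grid_value = scan$grid, scan$readouts,
                   check.names = FALSE)
  if (!is.null(scan$calls)) df$call <- scan$calls
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Calibration dataset CSV I/O
#'
#' Long format with columns `experiment_id`, `row_type`
#' (`input` / `observation`), `species`, `level_or_value`, `time_h`,
#' `weight`: input rows give the recipe doses, observation rows the
#' measurements.
#'
#' @param dataset A [calibration_dataset()].
#' @param path File path.
#' @export
write_dataset_csv <- function(dataset, path) {
  rows <- list()
  for (i in seq_along(dataset$experiments)) {
    ex <- dataset$experiments[[i]]
    eid <- ex$recipe$label %||% paste0("exp", i)
    eid <- paste0(eid, "_", i)
    if (length(ex$recipe$doses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = eid, row_type = "input",
        species = names(ex$recipe$doses),
        level_or_value = unname(ex$recipe$doses),
        time_h = NA_real_, weight = NA_real_, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = eid, row_type = "observation",
      species = ex$observations$species,
      level_or_value = ex$observations$value,
      time_h = ex$observations$time,
      weight = ex$observations$weight, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  experiments <- lapply(split(df, df$experiment_id), function(d) {
    inp <- d[d$row_type == "input", ]
    obs <- d[d$row_type == "observation", ]
    list(
      recipe = stimulus_recipe(
        stats::setNames(inp$level_or_value, inp$species),
        label = sub("_[0-9]+$", "", d$experiment_id[1])),
      observations = data.frame(species = obs$species, time = obs$time_h,
                                value = obs$level_or_value,
                                weight = obs$weight,
                                stringsAsFactors = FALSE))
  })
  names(experiments) <- NULL
  calibration_dataset(experiments,
                      provenance = list(source = "csv", path = path))
}

#' Human-auditable model JSON
#'
#' Flat JSON document (species table, reactions with rate-law structure,
#' parameter map) intended for diffing two model versions.
#'
#' @param model A `cd4_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    metadata = model$metadata,
    species = model$species,
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, substrates = as.list(r$substrates),
           products = as.list(r$products), modifiers = r$modifiers,
           rate_law = unclass(r$rate_law))
    }),
    parameters = as.list(model$parameters)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a sensitivity report
#'
#' CSV matrix of control coefficients (readouts x parameters) and a JSON
#' ranking by aggregate influence.
#'
#' @param report A `cd4_sensitivity`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_sensitivity_report <- function(report, csv_path = NULL,
                                     json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$coefficients, csv_path, row.names = TRUE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      ranking = rank_parameters(report),
      settings = report$settings
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

#' Export a fit result
#' @param fit A `cd4_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    par = as.list(fit$par), objective = fit$objective,
    trace = fit$trace, settings = fit$settings[c(
      "swarm_size", "iterations", "seed", "log_space", "solver_failures")]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the fate fixture
#' @param fixture Result of [generate_fate_fixture()].
#' @param path Output path.
#' @export
write_fate_fixture_json <- function(fixture, path) {
  jsonlite::write_json(fixture, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
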