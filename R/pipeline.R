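#' Assemble the analyzed parameter series
#'
#' Binds the twelve analyzed parameters into one long series table: the
#' nine landmark coordinates in the average scapula frame (AA_X ... TS_Z,
#' mm) and the three YXZ Euler orientation angles (e1, e2, e3, degrees).
#'
#' @param coordinates A landmark table in the `average_scapula` space.
#' @param orientations An orientation table from [scapular_orientation()].
#' @return A long tibble with columns `parameter`, `unit`, `scapula_id`,
#'   `observer_id`, `measure_idx`, `value`.
#' @export
parameter_series <- function(coordinates, orientations) {
  assert_landmark_tbl(coordinates, space = "average_scapula")
  coord_long <- coordinates |>
    tidyr::pivot_longer(cols = c("x", "y", "z"), names_to = "axis",
                        values_to = "value") |>
    dplyr::mutate(
      parameter = paste(.data$landmark, toupper(.data$axis), sep = "_"),
      unit = "mm"
    ) |>
    dplyr::select("parameter", "unit", "scapula_id", "observer_id",
                  "measure_idx", "value")
  angle_long <- orientations |>
    tidyr::pivot_longer(cols = c("e1_deg", "e2_deg", "e3_deg"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::mutate(parameter = sub("_deg$", "", .data$parameter),
                  unit = "deg") |>
    dplyr::select("parameter", "unit", "scapula_id", "observer_id",
                  "measure_idx", "value")
  out <- dplyr::bind_rows(coord_long, angle_long)
  dplyr::arrange(out, factor(.data$parameter, levels = PARAMETER_LEVELS),
                 .data$scapula_id, .data$observer_id, .data$measure_idx)
}

#' Run the full reliability analysis pipeline
#'
#' End-to-end chain on a balanced landmark dataset: validation, average
#' scapula coordinate re-expression, thorax rotation, per-measure scapular
#' orientation, and the per-parameter reliability report. Deterministic:
#' running twice on the same input and configuration yields identical
#' results.
#'
#' @param data A landmark table in imaging space (e.g. from
#'   [read_landmark_csv()] or [simulate_landmark_study()]), or a path to a
#'   plain-dialect landmark CSV.
#' @param pose The [thorax_pose()] defining the thorax frame.
#' @param side,area_epsilon,gimbal_tol Geometry options, see
#'   [build_scapula_frame()] and [euler_yxz_extract()].
#' @param method Variance estimation method, see
#'   [estimate_variance_components()].
#' @param output_dir Optional directory; when given, [write_run()] is
#'   called on the result.
#' @return An object of class `scapula_run`: a list with `coordinates`
#'   (average-scapula space), `orientations`, `series`, `reliability`,
#'   `validation` and `meta` (package version, pose, options, config
#'   hash).
#' @examples
#' sim <- simulate_landmark_study(generator_config(n_scapulae = 5, seed = 3))
#' run <- run_pipeline(sim$dataset)
#' run$reliability
#' @export
run_pipeline <- function(data, pose = thorax_pose(), side = "right",
                         area_epsilon = 1, gimbal_tol = 1e-9,
                         method = "anova", output_dir = NULL) {
  if (is.character(data) && length(data) == 1L) {
    data <- read_landmark_csv(data)
  }
  validation <- validate_dataset(data, area_epsilon = area_epsilon)
  if (!validation$usable) {
    msg <- utils::capture.output(print(validation))
    abort(paste(c("Dataset rejected by validation:", msg), collapse = "\n"))
  }
  coordinates <- to_average_cs(data, side = side,
                               area_epsilon = area_epsilon)
  thorax_coords <- apply_thorax_rotation(coordinates, pose)
  orientations <- scapular_orientation(thorax_coords, pose = pose,
                                       side = side,
                                       area_epsilon = area_epsilon,
                                       gimbal_tol = gimbal_tol)
  series <- parameter_series(coordinates, orientations)
  reliability <- reliability_table(series, method = method)
  meta <- list(
    package = "scapulometry",
    version = as.character(packageVersion("scapulometry")),
    pose = unlist(unclass(pose)),
    side = side, area_epsilon = area_epsilon, gimbal_tol = gimbal_tol,
    method = method,
    n = validation$n,
    config_hash = rlang::hash(list(data, unclass(pose), side, area_epsilon,
                                   gimbal_tol, method))
  )
  run <- structure(
    list(coordinates = coordinates, orientations = orientations,
         series = series, reliability = reliability,
         validation = validation, meta = meta),
    class = "scapula_run"
  )
  if (!is.null(output_dir)) {
    write_run(run, output_dir)
  }
  run
}

#' @export
print.scapula_run <- function(x, ...) {
  cat(sprintf("scapulometry run (v%s, config %s)\n",
              x$meta$version, substr(x$meta$config_hash, 1, 8)))
  cat(sprintf("  %d scapulae x %d observers x %d measures; thorax pose (%.1f, %.1f, %.1f) deg\n",
              x$meta$n[["n_scapulae"]], x$meta$n[["n_observers"]],
              x$meta$n[["n_measures"]],
              x$meta$pose[[1L]], x$meta$pose[[2L]], x$meta$pose[[3L]]))
  print(x$reliability)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `coordinates.csv` (average-scapula landmark coordinates),
#' `orientations.csv` (per-measure Euler angles), `reliability.csv`
#' (display-rounded report), `reliability.json` (full-precision report
#' plus metadata) and `run_log.txt`. Every CSV starts with a `#` comment
#' header recording package version and configuration hash for
#' provenance; [read_landmark_csv()] and `readr::read_csv(comment = "#")`
#' skip it transparently.
#'
#' @param run A `scapula_run`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run <- function(run, output_dir) {
  if (!inherits(run, "scapula_run")) {
    abort("`run` must be a `scapula_run` object.")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# scapulometry %s | config %s",
                   run$meta$version, run$meta$config_hash)
  write_stamped_csv <- function(df, file) {
    path <- file.path(output_dir, file)
    writeLines(stamp, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  coords_out <- run$coordinates |>
    dplyr::select("scapula_id", "observer_id", "measure_idx", "landmark",
                  x_acs = "x", y_acs = "y", z_acs = "z")
  write_stamped_csv(coords_out, "coordinates.csv")
  write_stamped_csv(run$orientations, "orientations.csv")
  write_stamped_csv(format_reliability(run$reliability), "reliability.csv")
  jsonlite::write_json(
    list(meta = run$meta,
         reliability = tibble::as_tibble(run$reliability)),
    file.path(output_dir, "reliability.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  writeLines(c(
    stamp,
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("design: %d scapulae x %d observers x %d measures",
            run$meta$n[["n_scapulae"]], run$meta$n[["n_observers"]],
            run$meta$n[["n_measures"]]),
    sprintf("thorax pose (deg): %s",
            paste(run$meta$pose, collapse = ", ")),
    sprintf("variance method: %s", run$meta$method)
  ), file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' Tidy a pipeline run
#'
#' @param x A `scapula_run`.
#' @param ... Unused.
#' @return The full-precision reliability table as a plain tibble.
#' @method tidy scapula_run
#' @export
tidy.scapula_run <- function(x, ...) {
  tibble::as_tibble(x$reliability)
}

#' Glance at a pipeline run
#'
#' @param x A `scapula_run`.
#' @param ... Unused.
#' @return A one-row tibble with design sizes, ICC ranges and SEM ranges.
#' @method glance scapula_run
#' @export
glance.scapula_run <- function(x, ...) {
  r <- x$reliability
  tibble::tibble(
    n_scapulae = x$meta$n[["n_scapulae"]],
    n_observers = x$meta$n[["n_observers"]],
    n_measures = x$meta$n[["n_measures"]],
    icc_intra_min = min(r$icc_intra, na.rm = TRUE),
    icc_intra_max = max(r$icc_intra, na.rm = TRUE),
    icc_inter_min = min(r$icc_inter, na.rm = TRUE),
    icc_inter_max = max(r$icc_inter, na.rm = TRUE),
    sem_intra_max = max(r$sem_intra, na.rm = TRUE),
    sem_inter_max = max(r$sem_inter, na.rm = TRUE)
  )
}
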