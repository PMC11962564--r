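#' Read a landmark digitization file
#'
#' Reads one or more digitizations of the three ISB scapula landmarks
#' (AA, IA, TS) into a long landmark table. Two dialects are supported:
#'
#' * `"plain"` — the package's canonical interchange format: a header row
#'   and columns `scapula_id, observer_id, measure_idx, landmark, x, y, z`,
#'   one row per landmark, comma-separated, `.` decimal separator.
#' * `"slicer_fcsv"` — a 3D Slicer fiducial markup file: `#`-prefixed
#'   header lines, one fiducial per row, with the landmark name in the
#'   `label` column. Coordinates are converted to the package's internal
#'   right-handed LPS millimetre convention according to the file's
#'   declared coordinate system (`RAS` coordinates are negated in x and y);
#'   files without a declaration are assumed to already be LPS. An `.fcsv`
#'   file carries no study keys, so `scapula_id`, `observer_id` and
#'   `measure_idx` must be supplied.
#'
#' @param path Path to the file.
#' @param dialect `"plain"` (default) or `"slicer_fcsv"`.
#' @param scapula_id,observer_id,measure_idx Study keys for the
#'   `"slicer_fcsv"` dialect (ignored for `"plain"`).
#' @return A tibble with columns `scapula_id`, `observer_id`,
#'   `measure_idx`, `landmark`, `x`, `y`, `z`, `space` (`"imaging"`),
#'   one row per landmark. Coordinates are in millimetres, LPS.
#' @seealso [write_landmark_csv()], [validate_dataset()]
#' @examples
#' f <- system.file("extdata", "example_landmarks.csv", package = "scapulometry")
#' read_landmark_csv(f)
#' @export
read_landmark_csv <- function(path, dialect = c("plain", "slicer_fcsv"),
                              scapula_id = "S01", observer_id = "O1",
                              measure_idx = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  if (dialect == "plain") {
    read_plain_landmark_csv(path)
  } else {
    read_slicer_fcsv(path, scapula_id, observer_id, measure_idx)
  }
}

read_plain_landmark_csv <- function(path) {
  # non-numeric coordinates surface as NA here and are reported below
  # with their line number, so readr's own parsing warning is redundant
  data <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      scapula_id = readr::col_character(),
      observer_id = readr::col_character(),
      measure_idx = readr::col_integer(),
      landmark = readr::col_character(),
      x = readr::col_double(), y = readr::col_double(),
      z = readr::col_double()
    ),
    comment = "#", progress = FALSE
  ))
  required <- setdiff(LANDMARK_TBL_COLS, "space")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("'%s' is missing required column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  # line numbers in the file: header is line 1
  line_no <- seq_len(nrow(data)) + 1L
  bad_label <- !(data$landmark %in% LANDMARK_LABELS)
  if (any(bad_label)) {
    abort(sprintf(
      "'%s': unknown landmark label '%s' at line %d (expected AA, IA or TS).",
      path, data$landmark[which(bad_label)[1L]], line_no[which(bad_label)[1L]]
    ))
  }
  bad_num <- !is.finite(data$x) | !is.finite(data$y) | !is.finite(data$z)
  if (any(bad_num)) {
    abort(sprintf("'%s': non-numeric or missing coordinate at line %d.",
                  path, line_no[which(bad_num)[1L]]))
  }
  key <- paste(data$scapula_id, data$observer_id, data$measure_idx,
               data$landmark, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf(
      "'%s': duplicate (scapula, observer, measure, landmark) entry at line %d.",
      path, line_no[which(dup)[1L]]
    ))
  }
  dplyr::mutate(data[required], space = "imaging")
}

read_slicer_fcsv <- function(path, scapula_id, observer_id, measure_idx) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    abort(sprintf("'%s' contains no fiducial rows.", path))
  }

  # coordinate system declaration, e.g. "# CoordinateSystem = RAS" or "= 0"
  cs <- "LPS"
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs_line) > 0L) {
    val <- trimws(sub(".*[=:]", "", cs_line[1L]))
    cs <- switch(toupper(val), "RAS" = "RAS", "0" = "RAS",
                 "LPS" = "LPS", "1" = "LPS",
                 abort(sprintf("'%s': unsupported coordinate system '%s'.",
                               path, val)))
  }

  # column layout: honour a "# columns = ..." line, else Slicer's default
  default_cols <- c("id", "x", "y", "z", "ow", "ox", "oy", "oz",
                    "vis", "sel", "lock", "label", "desc", "associatedNodeID")
  col_line <- grep("columns *=", header, value = TRUE)
  cols <- if (length(col_line) > 0L) {
    trimws(strsplit(sub(".*columns *= *", "", col_line[1L]), ",")[[1L]])
  } else {
    default_cols
  }
  for (required in c("x", "y", "z", "label")) {
    if (!required %in% cols) {
      abort(sprintf("'%s': fcsv column layout lacks '%s'.", path, required))
    }
  }

  fields <- strsplit(body, ",")
  out <- purrr::imap(fields, function(f, i) {
    row_line <- which(lines == body[i])[1L]
    if (length(f) < max(match(c("x", "y", "z", "label"), cols))) {
      abort(sprintf("'%s': malformed fiducial row at line %d.", path, row_line))
    }
    xyz <- suppressWarnings(as.numeric(f[match(c("x", "y", "z"), cols)]))
    if (any(!is.finite(xyz))) {
      abort(sprintf("'%s': non-numeric coordinate at line %d.", path, row_line))
    }
    tibble::tibble(landmark = trimws(f[match("label", cols)]),
                   x = xyz[1L], y = xyz[2L], z = xyz[3L])
  })
  out <- dplyr::bind_rows(out)
  bad <- setdiff(out$landmark, LANDMARK_LABELS)
  if (length(bad) > 0L) {
    abort(sprintf("'%s': fiducial label(s) not in {AA, IA, TS}: %s.",
                  path, paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(out$landmark)) {
    abort(sprintf("'%s': duplicate fiducial label '%s'.",
                  path, out$landmark[duplicated(out$landmark)][1L]))
  }
  if (cs == "RAS") {
    out <- ras_to_lps(out)
  }
  tibble::tibble(
    scapula_id = as.character(scapula_id),
    observer_id = as.character(observer_id),
    measure_idx = as.integer(measure_idx),
    landmark = out$landmark, x = out$x, y = out$y, z = out$z,
    space = "imaging"
  )
}

#' Convert coordinates between the RAS and LPS conventions
#'
#' Negates the x and y columns; applying it twice returns the input
#' (the conversion is an involution).
#'
#' @param data A data frame with numeric `x`, `y`, `z` columns.
#' @return The same data frame with `x` and `y` negated.
#' @export
ras_to_lps <- function(data) {
  dplyr::mutate(data, x = -.data$x, y = -.data$y)
}

#' @rdname ras_to_lps
#' @export
lps_to_ras <- ras_to_lps

#' Write a landmark table to the plain CSV dialect
#'
#' The output is readable by [read_landmark_csv()] with
#' `dialect = "plain"`; a write/read round trip reproduces the dataset to
#' better than 1e-9 mm.
#'
#' @param data A landmark table (see [read_landmark_csv()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(data, path) {
  if (nrow(data) > 0L) assert_landmark_tbl(data)
  cols <- setdiff(LANDMARK_TBL_COLS, "space")
  empty <- tibble::tibble(scapula_id = character(), observer_id = character(),
                          measure_idx = integer(), landmark = character(),
                          x = double(), y = double(), z = double())
  out <- if (nrow(data) > 0L) data[cols] else empty
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a landmark study dataset
#'
#' Checks that a landmark table forms the fully balanced
#' scapula x observer x measure grid the reliability analysis assumes:
#' every cell present exactly once with all three landmarks, no collinear
#' (degenerate) landmark triplets, and (when a `side` column is present) a
#' single consistent side per scapula.
#'
#' @param data A landmark table.
#' @param area_epsilon Minimum AA/IA/TS triangle area in mm^2 below which a
#'   triplet is flagged as degenerate (default 1).
#' @return An object of class `landmark_validation`: a list with elements
#'   `balanced` (logical), `usable` (logical), `n` (named counts),
#'   `missing_cells`, `extra_cells`, `collinear`, `side_conflicts`
#'   (tibbles), printed as a human-readable report.
#' @export
validate_dataset <- function(data, area_epsilon = 1) {
  assert_landmark_tbl(data)
  cells <- dplyr::distinct(data, .data$scapula_id, .data$observer_id,
                           .data$measure_idx)
  grid <- tidyr::expand_grid(
    scapula_id = sort(unique(data$scapula_id)),
    observer_id = sort(unique(data$observer_id)),
    measure_idx = sort(unique(data$measure_idx))
  )
  missing_cells <- dplyr::anti_join(
    grid, cells, by = c("scapula_id", "observer_id", "measure_idx"))

  # cells with missing/duplicated landmarks
  lm_counts <- data |>
    dplyr::count(.data$scapula_id, .data$observer_id, .data$measure_idx,
                 .data$landmark) |>
    tidyr::pivot_wider(names_from = "landmark", values_from = "n",
                       values_fill = 0L)
  for (lab in LANDMARK_LABELS) {
    if (!lab %in% names(lm_counts)) lm_counts[[lab]] <- 0L
  }
  extra_cells <- dplyr::filter(
    lm_counts, .data$AA != 1L | .data$IA != 1L | .data$TS != 1L)

  complete <- dplyr::anti_join(
    cells,
    extra_cells[c("scapula_id", "observer_id", "measure_idx")],
    by = c("scapula_id", "observer_id", "measure_idx"))
  collinear <- data |>
    dplyr::semi_join(complete,
                     by = c("scapula_id", "observer_id", "measure_idx")) |>
    triplet_areas() |>
    dplyr::filter(.data$area_mm2 < .env$area_epsilon)

  side_conflicts <- tibble::tibble(scapula_id = character())
  if ("side" %in% names(data)) {
    side_conflicts <- data |>
      dplyr::distinct(.data$scapula_id, .data$side) |>
      dplyr::count(.data$scapula_id) |>
      dplyr::filter(.data$n > 1L)
  }

  n <- c(n_scapulae = dplyr::n_distinct(data$scapula_id),
         n_observers = dplyr::n_distinct(data$observer_id),
         n_measures = dplyr::n_distinct(data$measure_idx))
  balanced <- nrow(missing_cells) == 0L && nrow(extra_cells) == 0L
  usable <- balanced && nrow(collinear) == 0L &&
    nrow(side_conflicts) == 0L &&
    n[["n_observers"]] >= 2L && n[["n_measures"]] >= 2L

  structure(
    list(balanced = balanced, usable = usable, n = n,
         missing_cells = missing_cells, extra_cells = extra_cells,
         collinear = collinear, side_conflicts = side_conflicts),
    class = "landmark_validation"
  )
}

# area of the AA/IA/TS triangle for every (scapula, observer, measure) cell
triplet_areas <- function(data) {
  data |>
    tidyr::pivot_wider(
      id_cols = c("scapula_id", "observer_id", "measure_idx"),
      names_from = "landmark", values_from = c("x", "y", "z")
    ) |>
    dplyr::mutate(area_mm2 = purrr::pmap_dbl(
      list(.data$x_AA, .data$y_AA, .data$z_AA,
           .data$x_IA, .data$y_IA, .data$z_IA,
           .data$x_TS, .data$y_TS, .data$z_TS),
      function(xa, ya, za, xi, yi, zi, xt, yt, zt) {
        triangle_area(c(xa, ya, za), c(xi, yi, zi), c(xt, yt, zt))
      }
    )) |>
    dplyr::select("scapula_id", "observer_id", "measure_idx", "area_mm2")
}

#' @export
print.landmark_validation <- function(x, ...) {
  cat("Landmark dataset validation\n")
  cat(sprintf("  grid: %d scapulae x %d observers x %d measures\n",
              x$n[["n_scapulae"]], x$n[["n_observers"]], x$n[["n_measures"]]))
  cat(sprintf("  balanced: %s\n", if (x$balanced) "yes" else "no"))
  if (nrow(x$missing_cells) > 0L) {
    cat(sprintf("  missing cells (%d):\n", nrow(x$missing_cells)))
    for (i in seq_len(min(nrow(x$missing_cells), 10L))) {
      cat(sprintf("    (%s, %s, %d)\n",
                  x$missing_cells$scapula_id[i], x$missing_cells$observer_id[i],
                  x$missing_cells$measure_idx[i]))
    }
  }
  if (nrow(x$extra_cells) > 0L) {
    cat(sprintf("  cells with missing/duplicated landmarks: %d\n",
                nrow(x$extra_cells)))
  }
  if (nrow(x$collinear) > 0L) {
    cat(sprintf("  degenerate (collinear) triplets: %d\n", nrow(x$collinear)))
  }
  if (nrow(x$side_conflicts) > 0L) {
    cat(sprintf("  scapulae with conflicting sides: %d\n",
                nrow(x$side_conflicts)))
  }
  cat(sprintf("  usable for reliability analysis: %s\n",
              if (x$usable) "yes" else "no"))
  invisible(x)
}

#' Generate a blinded randomized digitization list
#'
#' Builds the randomized work list used to present scapula models to
#' observers in shuffled order under uninformative identifiers, so that
#' repeated measures of the same scapula cannot be recognized (avoiding
#' learning effects). Every (scapula, measure) pair appears exactly once;
#' blinded ids are opaque zero-padded codes assigned *after* shuffling.
#'
#' @param scapula_ids Character vector of unique scapula identifiers.
#' @param n_measures Number of repeated measures per scapula.
#' @param seed Integer seed making the permutation reproducible.
#' @return A tibble with columns `blinded_id`, `scapula_id`, `measure_idx`;
#'   `length(scapula_ids) * n_measures` rows in randomized order.
#' @examples
#' generate_randomized_list(sprintf("S%02d", 1:81), 3, seed = 7)
#' @export
generate_randomized_list <- function(scapula_ids, n_measures, seed) {
  if (length(scapula_ids) == 0L) {
    abort("`scapula_ids` must be non-empty.")
  }
  if (anyDuplicated(scapula_ids)) {
    abort("`scapula_ids` contains duplicates.")
  }
  if (!is_count(n_measures)) {
    abort("`n_measures` must be a positive integer.")
  }
  grid <- tidyr::expand_grid(scapula_id = as.character(scapula_ids),
                             measure_idx = seq_len(n_measures))
  perm <- with_seed(seed, sample.int(nrow(grid)))
  out <- grid[perm, ]
  width <- max(3L, nchar(as.character(nrow(out))))
  out$blinded_id <- sprintf(paste0("M%0", width, "d"), seq_len(nrow(out)))
  out[c("blinded_id", "scapula_id", "measure_idx")]
}

#' Mirror left-side records into the right-side convention
#'
#' Reflects imaging-space coordinates of left scapulae across the sagittal
#' plane (`x -> -x` in LPS) so that all downstream scapula frames follow a
#' single right-side convention. Right-side records pass through unchanged.
#'
#' @param data A landmark table in imaging space with a `side` column
#'   (`"right"` or `"left"` per record), or `side` supplied separately.
#' @param side Optional side specification overriding the column: a single
#'   value or a vector of length `nrow(data)`.
#' @return The table with left records reflected and their `side` set to
#'   `"right"`.
#' @export
mirror_to_right <- function(data, side = NULL) {
  assert_landmark_tbl(data, space = "imaging")
  if (is.null(side)) {
    if (!"side" %in% names(data)) {
      abort("`data` has no `side` column and `side` was not supplied.")
    }
    side <- data$side
  }
  side <- rep_len(as.character(side), nrow(data))
  bad <- !(side %in% c("right", "left"))
  if (any(bad)) {
    abort(sprintf("Unknown side value(s): %s.",
                  paste(unique(side[bad]), collapse = ", ")))
  }
  left <- side == "left"
  data$x[left] <- -data$x[left]
  data$side <- "right"
  data
}

#' Reflect coordinates across the sagittal plane
#'
#' The raw reflection `x -> -x` (LPS sagittal mirror); an involution used
#' by [mirror_to_right()].
#'
#' @param data A data frame with an `x` column.
#' @return The data frame with `x` negated.
#' @export
reflect_sagittal <- function(data) {
  dplyr::mutate(data, x = -.data$x)
}
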