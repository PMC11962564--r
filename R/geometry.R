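#' Coordinate frames
#'
#' A frame is a proper rotation matrix `R` (columns = the frame's X, Y, Z
#' axis unit vectors expressed in the parent space) plus an origin.
#' Construction enforces orthonormality and `det(R) = +1` to 1e-9.
#'
#' @param R 3x3 numeric rotation matrix.
#' @param origin Length-3 numeric origin (default the parent origin).
#' @return An object of class `scapula_frame`.
#' @export
new_frame <- function(R, origin = c(0, 0, 0)) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    abort("`R` must be a finite 3x3 numeric matrix.")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    abort("`R` has non-orthonormal columns (tolerance 1e-9).")
  }
  if (abs(det(R) - 1) > 1e-9) {
    abort("`R` must be a proper rotation: det(R) = +1 (tolerance 1e-9).")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin))) {
    abort("`origin` must be a finite length-3 numeric vector.")
  }
  structure(list(R = unname(R), origin = origin), class = "scapula_frame")
}

#' @export
print.scapula_frame <- function(x, digits = 4, ...) {
  cat("Coordinate frame\n  R (columns X, Y, Z):\n")
  print(round(x$R, digits))
  cat("  origin:", paste(round(x$origin, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Build the ISB scapula coordinate system from a landmark triplet
#'
#' Constructs the scapula frame from the acromial angle (AA), inferior
#' angle (IA) and trigonum spinae (TS):
#' Z is the unit vector along AA -> TS (pointing medially for a
#' right-convention scapula), X is the unit normal of the AA/IA/TS plane
#' pointing anteriorly, and Y = Z x X (pointing superiorly). The origin is
#' placed at AA (the origin does not affect orientation angles; it makes
#' coordinate re-expression translation-invariant).
#'
#' For `side = "right"` the anterior normal is realized as
#' `unit(cross(TS - AA, IA - AA))`; for `side = "left"` the opposite cross
#' order is used (the mirrored triangle winds the other way). Prefer
#' mirroring left data first with [mirror_to_right()].
#'
#' @param AA,IA,TS Length-3 numeric landmark coordinates (mm).
#' @param side `"right"` (default) or `"left"` convention.
#' @param area_epsilon Minimum triangle area in mm^2 (default 1); smaller
#'   triplets are rejected as degenerate digitizations.
#' @return A `scapula_frame`.
#' @examples
#' build_scapula_frame(AA = c(0, 0, 0), IA = c(0, -120, 60), TS = c(0, 0, 100))
#' @export
build_scapula_frame <- function(AA, IA, TS, side = c("right", "left"),
                                area_epsilon = 1) {
  side <- match.arg(side)
  AA <- as.numeric(AA); IA <- as.numeric(IA); TS <- as.numeric(TS)
  area <- triangle_area(AA, IA, TS)
  if (!is.finite(area) || area < area_epsilon) {
    abort(sprintf(
      "Degenerate landmark triplet: AA/IA/TS triangle area %.3g mm^2 is below %.3g mm^2.",
      area, area_epsilon))
  }
  Z <- unit3(TS - AA)
  X <- if (side == "right") {
    unit3(cross3(TS - AA, IA - AA))
  } else {
    unit3(cross3(IA - AA, TS - AA))
  }
  Y <- cross3(Z, X)
  new_frame(cbind(X, Y, Z), origin = AA)
}

# frame from a one-scapula mean-landmark table (rows AA, IA, TS)
frame_from_landmarks <- function(lm, side = "right", area_epsilon = 1) {
  pick <- function(lab) {
    row <- lm[lm$landmark == lab, , drop = FALSE]
    c(row$x[1L], row$y[1L], row$z[1L])
  }
  build_scapula_frame(pick("AA"), pick("IA"), pick("TS"),
                      side = side, area_epsilon = area_epsilon)
}

#' Mean landmarks of each scapula
#'
#' Per-landmark arithmetic mean of the coordinates across all observers
#' and measures of each scapula (mAA, mIA, mTS) — the triplet defining the
#' average scapula coordinate system.
#'
#' @param data A landmark table; all records must share one coordinate
#'   space.
#' @return A tibble with columns `scapula_id`, `landmark`, `x`, `y`, `z`,
#'   `space`, one row per scapula and landmark.
#' @export
mean_landmarks <- function(data) {
  assert_landmark_tbl(data)
  spaces <- unique(data$space)
  if (length(spaces) != 1L) {
    abort(sprintf("Records mix coordinate spaces: %s.",
                  paste(spaces, collapse = ", ")))
  }
  data |>
    dplyr::group_by(.data$scapula_id, .data$landmark) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop") |>
    dplyr::mutate(space = spaces)
}

#' Express landmark records in the average scapula coordinate system
#'
#' For each scapula: computes the mean landmarks across all its observers
#' and measures, builds the average scapula frame from them (see
#' [build_scapula_frame()]), and re-expresses every landmark `p` of that
#' scapula as `t(R) %*% (p - origin)`. After this step, digitizations of
#' the same scapula are directly comparable regardless of the imaging pose.
#'
#' @param data A landmark table in imaging space.
#' @param side Side convention passed to [build_scapula_frame()].
#' @param area_epsilon Degeneracy threshold in mm^2.
#' @return The table with transformed coordinates and
#'   `space = "average_scapula"`.
#' @export
to_average_cs <- function(data, side = "right", area_epsilon = 1) {
  assert_landmark_tbl(data, space = "imaging")
  out <- data |>
    dplyr::group_by(.data$scapula_id) |>
    dplyr::group_modify(function(sub, key) {
      ml <- sub |>
        dplyr::group_by(.data$landmark) |>
        dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                         z = mean(.data$z), .groups = "drop")
      fr <- tryCatch(
        frame_from_landmarks(ml, side = side, area_epsilon = area_epsilon),
        error = function(e) {
          abort(sprintf("Scapula '%s': %s", key$scapula_id[1L],
                        conditionMessage(e)))
        })
      pts <- as.matrix(sub[c("x", "y", "z")])
      acs <- sweep(pts, 2L, fr$origin) %*% fr$R
      sub$x <- acs[, 1L]; sub$y <- acs[, 2L]; sub$z <- acs[, 3L]
      sub
    }) |>
    dplyr::ungroup()
  out$space <- "average_scapula"
  out[union(LANDMARK_TBL_COLS, names(out))]
}

#' Default thorax resting pose
#'
#' The average scapulothoracic orientation during relaxed standing used as
#' the thorax reference when thorax landmarks are unavailable in CT:
#' 41.1 degrees of protraction, 5.4 degrees of medial rotation and
#' 13.5 degrees of anterior tilt.
#'
#' @param protraction_deg,medial_rotation_deg,anterior_tilt_deg Pose angles
#'   in degrees, each in (-180, 180].
#' @return An object of class `thorax_pose` (a named list of the three
#'   angles).
#' @export
thorax_pose <- function(protraction_deg = 41.1, medial_rotation_deg = 5.4,
                        anterior_tilt_deg = 13.5) {
  angles <- c(protraction_deg, medial_rotation_deg, anterior_tilt_deg)
  if (!all(is.finite(angles)) || any(angles <= -180 | angles > 180)) {
    abort("Thorax pose angles must be finite and in (-180, 180] degrees.")
  }
  structure(list(protraction_deg = protraction_deg,
                 medial_rotation_deg = medial_rotation_deg,
                 anterior_tilt_deg = anterior_tilt_deg),
            class = "thorax_pose")
}

#' Rotation from the average scapula frame to the thorax frame
#'
#' Composes the three successive pose rotations in the scapulothoracic
#' YXZ mobile-axis sequence (protraction about Y, then medial rotation
#' about the rotated X, then anterior tilt about the twice-rotated Z):
#' `R = Ry(e1) %*% Rx(e2) %*% Rz(e3)`. Positive protraction, medial
#' rotation and anterior tilt map identically onto the signed internal
#' angles (e1, e2, e3).
#'
#' @param pose A [thorax_pose()].
#' @return A `scapula_frame` with origin at zero.
#' @export
thorax_rotation <- function(pose = thorax_pose()) {
  if (!inherits(pose, "thorax_pose")) {
    abort("`pose` must be a `thorax_pose` object.")
  }
  new_frame(euler_yxz_compose(pose$protraction_deg, pose$medial_rotation_deg,
                              pose$anterior_tilt_deg))
}

#' Rotate average-scapula coordinates into the thorax frame
#'
#' Applies `p -> R %*% p` with `R` the thorax rotation of the given pose.
#' A pure rotation: all norms and inter-landmark distances are preserved.
#'
#' @param data A landmark table in the `average_scapula` space.
#' @param pose A [thorax_pose()], or a `scapula_frame` holding the
#'   rotation directly.
#' @return The table with rotated coordinates and `space = "thorax"`.
#' @export
apply_thorax_rotation <- function(data, pose = thorax_pose()) {
  assert_landmark_tbl(data, space = "average_scapula")
  fr <- if (inherits(pose, "scapula_frame")) pose else thorax_rotation(pose)
  pts <- as.matrix(data[c("x", "y", "z")])
  tcs <- pts %*% t(fr$R)
  data$x <- tcs[, 1L]; data$y <- tcs[, 2L]; data$z <- tcs[, 3L]
  data$space <- "thorax"
  data
}

# elementary rotations, angle in radians
rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3L, 3L)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3L, 3L)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3L, 3L)

#' Compose a rotation from YXZ mobile-axis Euler angles
#'
#' `R = Ry(e1) %*% Rx(e2) %*% Rz(e3)`, the scapulothoracic sequence:
#' e1 retraction/protraction, e2 lateral/medial rotation, e3
#' internal/external rotation, all in degrees.
#'
#' @param e1_deg,e2_deg,e3_deg Angles in degrees; `e2_deg` must lie in
#'   (-90, 90).
#' @return A 3x3 rotation matrix.
#' @seealso [euler_yxz_extract()]
#' @export
euler_yxz_compose <- function(e1_deg, e2_deg, e3_deg) {
  rot_y(deg2rad(e1_deg)) %*% rot_x(deg2rad(e2_deg)) %*% rot_z(deg2rad(e3_deg))
}

#' Extract YXZ mobile-axis Euler angles from a rotation
#'
#' Inverts [euler_yxz_compose()]: for a proper rotation `R`,
#' `e2 = asin(-R[2,3])`, `e1 = atan2(R[1,3], R[3,3])`,
#' `e3 = atan2(R[2,1], R[2,2])`, returned in degrees. Near gimbal lock
#' (|e2| -> 90 degrees, i.e. |R\[2,3\]| within `gimbal_tol` of 1) the
#' decomposition is singular and an error naming the singular element is
#' raised rather than returning numerically meaningless e1/e3.
#'
#' @param R 3x3 proper rotation matrix (or a `scapula_frame`).
#' @param gimbal_tol Tolerance on `1 - |R[2,3]|` below which the pose is
#'   treated as gimbal-locked (default 1e-9). Physiological scapular poses
#'   are far from the singularity.
#' @return Named numeric vector `c(e1_deg, e2_deg, e3_deg)`.
#' @examples
#' euler_yxz_extract(euler_yxz_compose(41.1, 5.4, 13.5))
#' @export
euler_yxz_extract <- function(R, gimbal_tol = 1e-9) {
  if (inherits(R, "scapula_frame")) R <- R$R
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
    abort("`R` must be a 3x3 rotation matrix.")
  }
  s <- -R[2L, 3L]
  if (abs(s) >= 1 - gimbal_tol) {
    abort(sprintf(
      "Gimbal lock: |R[2,3]| = %.12f is within %g of 1; the YXZ middle angle e2 is at +/-90 degrees and e1/e3 are not separable.",
      abs(R[2L, 3L]), gimbal_tol))
  }
  c(e1_deg = rad2deg(atan2(R[1L, 3L], R[3L, 3L])),
    e2_deg = rad2deg(asin(s)),
    e3_deg = rad2deg(atan2(R[2L, 1L], R[2L, 2L])))
}

#' 3D scapular orientation per scapula, observer and measure
#'
#' Runs the orientation chain: landmarks are expressed in the average
#' scapula frame of their scapula ([to_average_cs()]), rotated into the
#' thorax frame ([apply_thorax_rotation()]), then for every
#' (scapula, observer, measure) cell a specific scapula frame is built
#' from that digitization's AA/IA/TS with the same construction rules, and
#' its YXZ Euler angles relative to the thorax frame are extracted.
#'
#' Input already in the `average_scapula` or `thorax` space resumes the
#' chain at the corresponding step.
#'
#' @param data A landmark table (imaging, average-scapula or thorax space).
#' @param pose The [thorax_pose()] defining the thorax frame.
#' @param side,area_epsilon Passed to [build_scapula_frame()].
#' @param gimbal_tol Passed to [euler_yxz_extract()].
#' @return A tibble with one row per (scapula, observer, measure):
#'   `scapula_id`, `observer_id`, `measure_idx`, `e1_deg`
#'   (retraction/protraction), `e2_deg` (lateral/medial rotation),
#'   `e3_deg` (internal/external rotation).
#' @export
scapular_orientation <- function(data, pose = thorax_pose(), side = "right",
                                 area_epsilon = 1, gimbal_tol = 1e-9) {
  assert_landmark_tbl(data)
  space <- unique(data$space)
  if (length(space) != 1L) {
    abort("Records mix coordinate spaces.")
  }
  if (space == "imaging") {
    data <- to_average_cs(data, side = side, area_epsilon = area_epsilon)
    space <- "average_scapula"
  }
  if (space == "average_scapula") {
    data <- apply_thorax_rotation(data, pose)
  }
  wide <- tidyr::pivot_wider(
    data,
    id_cols = c("scapula_id", "observer_id", "measure_idx"),
    names_from = "landmark", values_from = c("x", "y", "z")
  )
  angles <- purrr::pmap(
    list(wide$scapula_id, wide$observer_id, wide$measure_idx,
         wide$x_AA, wide$y_AA, wide$z_AA,
         wide$x_IA, wide$y_IA, wide$z_IA,
         wide$x_TS, wide$y_TS, wide$z_TS),
    function(s, o, m, xa, ya, za, xi, yi, zi, xt, yt, zt) {
      tryCatch({
        fr <- build_scapula_frame(c(xa, ya, za), c(xi, yi, zi), c(xt, yt, zt),
                                  side = side, area_epsilon = area_epsilon)
        euler_yxz_extract(fr$R, gimbal_tol = gimbal_tol)
      }, error = function(e) {
        abort(sprintf("Scapula '%s', observer '%s', measure %d: %s",
                      s, o, m, conditionMessage(e)))
      })
    })
  angles <- do.call(rbind, angles)
  tibble::tibble(
    scapula_id = wide$scapula_id,
    observer_id = wide$observer_id,
    measure_idx = wide$measure_idx,
    e1_deg = angles[, "e1_deg"],
    e2_deg = angles[, "e2_deg"],
    e3_deg = angles[, "e3_deg"]
  )
}
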