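#' Turning angles along an edge polyline
#'
#' For an ordered 3D polyline, the turning angle at each interior vertex is
#' 180 degrees minus the interior angle between the incoming and outgoing
#' segments: a straight continuation turns 0 degrees, a right-angle corner
#' 90 degrees. Turning angles are isometry-invariant, which makes the
#' landmark detectors below invariant under rigid transformation of the
#' polyline.
#'
#' @param polyline A data frame with numeric `x`, `y`, `z` columns, one row
#'   per vertex in traversal order (vertex 1 = anatomical start), or an
#'   n x 3 numeric matrix. At least 3 vertices; consecutive vertices must
#'   be more than 1e-6 mm apart.
#' @return Numeric vector of turning angles in degrees, one per interior
#'   vertex (length `n - 2`).
#' @export
turning_angles <- function(polyline) {
  pts <- as_polyline_matrix(polyline)
  n <- nrow(pts)
  seg <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  vapply(seq_len(n - 2L), function(i) {
    a <- seg[i, ]; b <- seg[i + 1L, ]
    ca <- sum(a * b) / (norm3(a) * norm3(b))
    rad2deg(acos(pmin(1, pmax(-1, ca))))
  }, numeric(1L))
}

as_polyline_matrix <- function(polyline) {
  pts <- if (is.matrix(polyline)) {
    polyline
  } else if (is.data.frame(polyline)) {
    as.matrix(polyline[c("x", "y", "z")])
  } else {
    abort("`polyline` must be a data frame with x/y/z columns or an n x 3 matrix.")
  }
  if (nrow(pts) < 3L || !all(is.finite(pts))) {
    abort("A polyline needs at least 3 finite vertices.")
  }
  gaps <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  if (any(gaps <= 1e-6)) {
    abort(sprintf("Duplicate consecutive vertices (separation <= 1e-6 mm) at position %d.",
                  which(gaps <= 1e-6)[1L]))
  }
  pts
}

#' Detect the acromial angle on the lateral acromion edge
#'
#' Implements the AA positioning strategy: walking the lateral edge of the
#' acromion from its anterior tip, AA is the *first* vertex whose turning
#' angle exceeds the threshold (strictly greater than 45 degrees by
#' default). Edges whose transition is a smooth curve with no angle above
#' the threshold yield a not-found error — the morphology on which the
#' strategy is undefined. When several vertices exceed the threshold
#' (multi-angle morphologies) the first is returned and the ambiguity is
#' flagged.
#'
#' @param polyline Lateral acromion edge polyline, vertex 1 at the
#'   anterior tip (see [turning_angles()] for accepted forms).
#' @param threshold_deg Turning-angle threshold in degrees (default 45,
#'   strict inequality).
#' @return A one-row tibble: `vertex_idx` (index into the polyline), `x`,
#'   `y`, `z`, `turning_angle_deg`, `n_candidates` (how many interior
#'   vertices exceeded the threshold), `ambiguous` (`n_candidates > 1`).
#' @export
detect_AA <- function(polyline, threshold_deg = 45) {
  pts <- as_polyline_matrix(polyline)
  ang <- turning_angles(pts)
  hits <- which(ang > threshold_deg)
  if (length(hits) == 0L) {
    abort(sprintf(
      "No acromial angle found: no turning angle exceeds %g degrees (max %.3g); the edge is a smooth curve.",
      threshold_deg, max(ang)))
  }
  idx <- hits[1L] + 1L  # interior vertex i corresponds to polyline vertex i+1
  tibble::tibble(
    vertex_idx = idx,
    x = unname(pts[idx, 1L]), y = unname(pts[idx, 2L]),
    z = unname(pts[idx, 3L]),
    turning_angle_deg = ang[hits[1L]],
    n_candidates = length(hits),
    ambiguous = length(hits) > 1L
  )
}

#' Detect the inferior angle on the medial scapular edge
#'
#' Implements the IA positioning strategy: the most distal point of the
#' scapula along its medial edge, i.e. the vertex maximizing the projection
#' onto the distal direction. Ties are broken toward the lowest vertex
#' index (the vertex encountered first from the superior end).
#'
#' @param polyline Medial edge polyline, vertex 1 at the superior end.
#' @param distal_direction Length-3 unit vector pointing distally.
#' @return A one-row tibble: `vertex_idx`, `x`, `y`, `z`, `projection`
#'   (the maximized dot product, mm).
#' @export
detect_IA <- function(polyline, distal_direction) {
  pts <- as_polyline_matrix(polyline)
  d <- as.numeric(distal_direction)
  if (length(d) != 3L || !all(is.finite(d)) ||
      abs(norm3(d) - 1) > 1e-6) {
    abort("`distal_direction` must be a finite length-3 unit vector.")
  }
  proj <- as.numeric(pts %*% d)
  idx <- which.max(proj)  # which.max returns the first maximum: the tie-break
  tibble::tibble(vertex_idx = idx,
                 x = unname(pts[idx, 1L]), y = unname(pts[idx, 2L]),
                 z = unname(pts[idx, 3L]), projection = proj[idx])
}
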