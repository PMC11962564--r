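#' Read an STL surface mesh
#'
#' Reads a triangle mesh from a stereolithography (STL) file, in either the
#' ASCII or the binary encoding, into vertex and face arrays. Used for
#' surface-model fixtures; the analysis itself only consumes landmarks.
#'
#' The encoding is detected from the file itself: a file whose size matches
#' the binary layout (80-byte header, 4-byte triangle count, 50 bytes per
#' triangle) is read as binary, otherwise as ASCII. Truncated binary files
#' and malformed ASCII files raise an error rather than returning a partial
#' mesh. Vertices shared between triangles (exact coordinate matches) are
#' merged; zero-area triangles are flagged, not dropped.
#'
#' @param path Path to the STL file.
#' @return An object of class `scapula_mesh`: a list with `vertices`
#'   (n x 3 numeric matrix, mm), `faces` (m x 3 integer matrix of 1-based
#'   vertex indices), `degenerate` (logical vector of length m flagging
#'   zero-area faces) and `encoding` (`"ascii"` or `"binary"`).
#' @export
read_stl_mesh <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  size <- file.info(path)$size
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    header <- readBin(con, "raw", 80L)
    n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n_tri) == 1L && !is.na(n_tri) && n_tri >= 0L &&
        size == 84 + 50 * as.numeric(n_tri)) {
      return(read_stl_binary(con, n_tri))
    }
    close(con)
    on.exit()
  }
  # heuristics failed or file too small for binary: try ASCII
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (!startsWith(tolower(first), "solid")) {
    abort(sprintf(
      "'%s' is neither a well-formed binary STL (size mismatch) nor ASCII.",
      path))
  }
  read_stl_ascii(path)
}

read_stl_binary <- function(con, n_tri) {
  # 50 bytes per facet: 12 little-endian float32 (normal + 3 vertices) + u16
  raw <- readBin(con, "raw", 50L * n_tri)
  if (length(raw) != 50L * n_tri) {
    abort("Truncated binary STL: fewer triangles than declared.")
  }
  tri <- matrix(0, nrow = n_tri, ncol = 9L)
  for (i in seq_len(n_tri)) {
    chunk <- raw[((i - 1L) * 50L + 1L):((i - 1L) * 50L + 48L)]
    vals <- readBin(chunk, "numeric", 12L, size = 4L, endian = "little")
    tri[i, ] <- vals[4:12]  # drop the stored normal
  }
  build_mesh(tri, "binary")
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vx <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vx) == 0L || length(vx) %% 3L != 0L) {
    abort(sprintf("'%s': malformed ASCII STL (%d vertex lines, not a multiple of 3).",
                  path, length(vx)))
  }
  if (!any(startsWith(tolower(lines), "endsolid"))) {
    abort(sprintf("'%s': malformed ASCII STL (missing 'endsolid').", path))
  }
  coords <- purrr::map(strsplit(vx, "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(!is.finite(v))) {
      abort(sprintf("'%s': non-numeric vertex coordinate.", path))
    }
    v
  })
  tri <- matrix(unlist(coords), ncol = 9L, byrow = TRUE)
  build_mesh(tri, "ascii")
}

# tri: one row per triangle, 9 columns (v1 xyz, v2 xyz, v3 xyz)
build_mesh <- function(tri, encoding) {
  pts <- rbind(tri[, 1:3, drop = FALSE],
               tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1L], pts[, 2L], pts[, 3L], sep = "\r")
  idx <- match(key, unique(key))
  vertices <- pts[!duplicated(key), , drop = FALSE]
  colnames(vertices) <- c("x", "y", "z")
  n_tri <- nrow(tri)
  faces <- cbind(idx[seq_len(n_tri)],
                 idx[n_tri + seq_len(n_tri)],
                 idx[2L * n_tri + seq_len(n_tri)])
  degenerate <- vapply(seq_len(n_tri), function(i) {
    a <- vertices[faces[i, 1L], ]
    b <- vertices[faces[i, 2L], ]
    d <- vertices[faces[i, 3L], ]
    triangle_area(a, b, d) < .Machine$double.eps^0.5
  }, logical(1L))
  structure(list(vertices = vertices, faces = faces,
                 degenerate = degenerate, encoding = encoding),
            class = "scapula_mesh")
}

#' @export
print.scapula_mesh <- function(x, ...) {
  cat(sprintf("STL mesh (%s): %d vertices, %d faces (%d degenerate)\n",
              x$encoding, nrow(x$vertices), nrow(x$faces),
              sum(x$degenerate)))
  invisible(x)
}
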