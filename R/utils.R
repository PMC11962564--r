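# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. `seed = NULL` leaves the
# RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive independent child seeds from a master seed, one stream per named
# purpose, so toggling one source of randomness never shifts another.
split_seed <- function(seed, streams) {
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(streams)))
  setNames(as.list(sub), streams)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < .Machine$double.eps^0.5) {
    abort("Cannot normalize a (near-)zero vector.")
  }
  v / n
}

# Area (mm^2) of the triangle spanned by the three landmarks.
triangle_area <- function(AA, IA, TS) {
  0.5 * norm3(cross3(IA - AA, TS - AA))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Columns every landmark table must carry.
LANDMARK_TBL_COLS <- c("scapula_id", "observer_id", "measure_idx",
                       "landmark", "x", "y", "z", "space")

assert_landmark_tbl <- function(data, space = NULL,
                                arg = deparse(substitute(data))) {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame of landmark records.", arg))
  }
  missing_cols <- setdiff(LANDMARK_TBL_COLS, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing columns: %s.",
                  arg, paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(data$landmark), LANDMARK_LABELS)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown landmark label(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(data$x) & is.finite(data$y) & is.finite(data$z))) {
    abort(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  if (!is.null(space)) {
    found <- unique(data$space)
    if (!identical(found, space) && !(length(found) == 1L && found == space)) {
      abort(sprintf(
        "`%s` must be in the '%s' coordinate space (found: %s).",
        arg, space, paste(found, collapse = ", ")
      ))
    }
  }
  invisible(data)
}
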