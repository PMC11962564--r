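#' Mean absolute deviation of a parameter series
#'
#' For every observation (scapula, observer, measure), the deviation is the
#' absolute difference between the observed value and the mean of all
#' observations of that scapula. The summary reports the mean and standard
#' deviation of the `N = n_s * n_o * n_m` deviations and a normal-theory
#' 95% confidence interval `mean +/- 1.96 * sd / sqrt(N)`.
#'
#' @param series A data frame with columns `scapula_id`, `observer_id`,
#'   `measure_idx` and a value column.
#' @param value Name of the value column (default `"value"`).
#' @return A one-row tibble: `mad_mean`, `mad_sd`, `ci_low`, `ci_high`,
#'   `n` (number of deviations).
#' @examples
#' s <- tibble::tibble(scapula_id = "S1", observer_id = c("O1", "O1", "O2"),
#'                     measure_idx = c(1, 2, 1), value = c(1, 2, 3))
#' mean_absolute_deviation(s)  # deviations 1, 0, 1 -> mean 2/3
#' @export
mean_absolute_deviation <- function(series, value = "value") {
  check_series(series, value)
  per_scapula_n <- dplyr::count(series, .data$scapula_id)
  if (any(per_scapula_n$n < 2L)) {
    abort("Every scapula needs at least 2 observations for a deviation to exist.")
  }
  dev <- series |>
    dplyr::group_by(.data$scapula_id) |>
    dplyr::mutate(.dev = abs(.data[[value]] - mean(.data[[value]]))) |>
    dplyr::ungroup()
  d <- dev$.dev
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  half <- 1.96 * s / sqrt(n)
  tibble::tibble(mad_mean = m, mad_sd = s,
                 ci_low = m - half, ci_high = m + half, n = n)
}

check_series <- function(series, value = "value") {
  needed <- c("scapula_id", "observer_id", "measure_idx", value)
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`series` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(series[[value]]))) {
    abort("`series` contains non-finite values.")
  }
  invisible(series)
}

assert_balanced_series <- function(series) {
  counts <- dplyr::count(series, .data$scapula_id, .data$observer_id,
                         .data$measure_idx)
  n_s <- dplyr::n_distinct(series$scapula_id)
  n_o <- dplyr::n_distinct(series$observer_id)
  n_m <- dplyr::n_distinct(series$measure_idx)
  if (nrow(counts) != n_s * n_o * n_m || any(counts$n != 1L)) {
    abort("`series` is not a balanced scapula x observer x measure grid with one value per cell.")
  }
  c(n_s = n_s, n_o = n_o, n_m = n_m)
}

#' Estimate crossed random-effects variance components
#'
#' Fits the balanced crossed main-effects random model
#' `y_som = mu + a_s + b_o + c_m + eps` (scapula, observer, measure,
#' residual) and partitions the total variance as
#' `sigma2_total = sigma2_scapula + sigma2_observer + sigma2_measure +
#' sigma2_residual`.
#'
#' The default `"anova"` method is the closed-form balanced ANOVA
#' (method-of-moments) estimator: main-effect mean squares are equated to
#' their expectations, giving
#' `sigma2_s = (MS_s - MS_res) / (n_o * n_m)` (and cyclically for observer
#' and measure) with `sigma2_res = MS_res` on
#' `N - n_s - n_o - n_m + 2` residual degrees of freedom. Negative
#' estimates are truncated to zero and the total is recomputed as the sum
#' *after* truncation, so downstream ICCs stay in \[0, 1\]; untruncated
#' estimates are kept in the fit for diagnostics. `method = "reml"`
#' delegates to `lme4::lmer` (if installed) with the same model.
#'
#' @param series A balanced parameter series (see
#'   [mean_absolute_deviation()] for columns); needs at least 2 levels of
#'   each factor.
#' @param value Name of the value column.
#' @param method `"anova"` (default, closed form) or `"reml"`.
#' @return An object of class `scapula_vca`; see [tidy.scapula_vca()] and
#'   [glance.scapula_vca()].
#' @export
estimate_variance_components <- function(series, value = "value",
                                         method = c("anova", "reml")) {
  method <- match.arg(method)
  check_series(series, value)
  n <- assert_balanced_series(series)
  if (any(n < 2L)) {
    abort("Variance component estimation needs >= 2 scapulae, observers and measures.")
  }
  y <- series[[value]]
  s <- factor(series$scapula_id)
  o <- factor(series$observer_id)
  m <- factor(series$measure_idx)
  N <- length(y)
  # numerically-zero dispersion (e.g. a zero-noise study carried through
  # arbitrary imaging poses) counts as degenerate: no reliability ratio
  # is meaningful on floating-point jitter alone
  degenerate <- diff(range(y)) <= 1e-9 * max(1, abs(mean(y)))

  if (method == "anova") {
    grand <- mean(y)
    ms <- function(f, reps) {
      means <- tapply(y, f, mean)
      list(ss = reps * sum((means - grand)^2), df = nlevels(f) - 1L)
    }
    a_s <- ms(s, n[["n_o"]] * n[["n_m"]])
    a_o <- ms(o, n[["n_s"]] * n[["n_m"]])
    a_m <- ms(m, n[["n_s"]] * n[["n_o"]])
    ss_tot <- sum((y - grand)^2)
    ss_res <- ss_tot - a_s$ss - a_o$ss - a_m$ss
    df_res <- N - n[["n_s"]] - n[["n_o"]] - n[["n_m"]] + 2L
    ms_res <- ss_res / df_res
    raw <- c(
      scapula = (a_s$ss / a_s$df - ms_res) / (n[["n_o"]] * n[["n_m"]]),
      observer = (a_o$ss / a_o$df - ms_res) / (n[["n_s"]] * n[["n_m"]]),
      measure = (a_m$ss / a_m$df - ms_res) / (n[["n_s"]] * n[["n_o"]]),
      residual = ms_res
    )
    ms_tbl <- tibble::tibble(
      term = c("scapula", "observer", "measure", "residual"),
      sum_sq = c(a_s$ss, a_o$ss, a_m$ss, ss_res),
      df = c(a_s$df, a_o$df, a_m$df, df_res),
      mean_sq = c(a_s$ss / a_s$df, a_o$ss / a_o$df, a_m$ss / a_m$df, ms_res)
    )
  } else {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      abort("method = \"reml\" requires the lme4 package.")
    }
    df <- data.frame(y = y, s = s, o = o, m = m)
    fit <- lme4::lmer(y ~ 1 + (1 | s) + (1 | o) + (1 | m), data = df,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) vc$vcov[match(g, vc$grp)]
    raw <- c(scapula = get("s"), observer = get("o"), measure = get("m"),
             residual = get("Residual"))
    ms_tbl <- NULL
  }

  if (degenerate) raw[] <- 0
  truncated <- pmax(raw, 0)
  structure(
    list(sigma2 = truncated,
         sigma2_raw = raw,
         sigma2_total = sum(truncated),
         mean_squares = ms_tbl,
         n = n, N = N, grand_mean = mean(y),
         method = method, degenerate = degenerate),
    class = "scapula_vca"
  )
}

#' @export
print.scapula_vca <- function(x, digits = 4, ...) {
  cat(sprintf("Crossed random-effects variance components (%s, %d x %d x %d)\n",
              x$method, x$n[["n_s"]], x$n[["n_o"]], x$n[["n_m"]]))
  comp <- rbind(`variance` = x$sigma2, `untruncated` = x$sigma2_raw)
  print(round(comp, digits))
  cat(sprintf("total: %.*g", digits, x$sigma2_total))
  if (x$degenerate) cat("  [degenerate: all values identical]")
  cat("\n")
  invisible(x)
}

#' Tidy a variance-component fit
#'
#' @param x A `scapula_vca` fit.
#' @param ... Unused.
#' @return A tibble with one row per component: `term`, `variance`
#'   (truncated at zero), `variance_raw` (untruncated), `proportion`
#'   (share of the truncated total).
#' @method tidy scapula_vca
#' @export
tidy.scapula_vca <- function(x, ...) {
  tibble::tibble(
    term = names(x$sigma2),
    variance = unname(x$sigma2),
    variance_raw = unname(x$sigma2_raw),
    proportion = if (x$sigma2_total > 0) {
      unname(x$sigma2) / x$sigma2_total
    } else {
      rep(NA_real_, 4L)
    }
  )
}

#' Glance at a variance-component fit
#'
#' @param x A `scapula_vca` fit.
#' @param ... Unused.
#' @return A one-row tibble: total variance, both ICCs and SEMs, the
#'   design sizes, the estimation method and the degenerate flag.
#' @method glance scapula_vca
#' @export
glance.scapula_vca <- function(x, ...) {
  ii <- icc_intra(x)
  ie <- icc_inter(x)
  tibble::tibble(
    sigma2_total = x$sigma2_total,
    icc_intra = ii, icc_inter = ie,
    sem_intra = if (is.na(ii)) NA_real_ else sem(x, ii),
    sem_inter = if (is.na(ie)) NA_real_ else sem(x, ie),
    n_scapulae = x$n[["n_s"]], n_observers = x$n[["n_o"]],
    n_measures = x$n[["n_m"]],
    method = x$method, degenerate = x$degenerate
  )
}

vca_components <- function(vc) {
  if (inherits(vc, "scapula_vca")) {
    return(vc$sigma2)
  }
  needed <- c("scapula", "observer", "measure", "residual")
  if (is.numeric(vc) && all(needed %in% names(vc))) {
    return(vc[needed])
  }
  abort("`vc` must be a `scapula_vca` fit or a named numeric vector with components scapula, observer, measure, residual.")
}

#' Intraclass correlation coefficients from variance components
#'
#' Intraobserver repeatability and interobserver reproducibility as
#' variance ratios over the component sum
#' `sigma2_total = sigma2_scapula + sigma2_observer + sigma2_measure +
#' sigma2_residual`:
#'
#' * `icc_intra = (sigma2_total - (sigma2_measure + sigma2_residual)) /
#'   sigma2_total` — agreement of repeated measures by one observer;
#' * `icc_inter = (sigma2_total - (sigma2_observer + sigma2_residual)) /
#'   sigma2_total` — agreement across observers.
#'
#' With zero total variance the ratio is undefined: `NA` is returned with
#' a warning.
#'
#' @param vc A `scapula_vca` fit or a named numeric vector of components
#'   (`scapula`, `observer`, `measure`, `residual`).
#' @return A single numeric value in \[0, 1\] (components are truncated at
#'   zero upstream), or `NA` if undefined.
#' @export
icc_intra <- function(vc) {
  s2 <- vca_components(vc)
  icc_ratio(s2, s2[["measure"]] + s2[["residual"]])
}

#' @rdname icc_intra
#' @export
icc_inter <- function(vc) {
  s2 <- vca_components(vc)
  icc_ratio(s2, s2[["observer"]] + s2[["residual"]])
}

icc_ratio <- function(s2, error_part) {
  total <- sum(s2)
  if (total <= 0) {
    warn("Total variance is zero: ICC is undefined (returning NA).")
    return(NA_real_)
  }
  (total - error_part) / total
}

#' Standard error of measurement
#'
#' `SEM = sqrt(sigma2_total * (1 - ICC))` — the absolute-reliability
#' counterpart of the (relative) ICC, in the unit of the measurements.
#'
#' @param sigma2_total Total variance (unit^2), or a `scapula_vca` fit
#'   whose total is used.
#' @param icc The ICC to convert (in \[0, 1\]).
#' @return SEM, a non-negative scalar.
#' @export
sem <- function(sigma2_total, icc) {
  if (inherits(sigma2_total, "scapula_vca")) {
    sigma2_total <- sigma2_total$sigma2_total
  }
  if (!is.numeric(icc) || any(!is.finite(icc)) ||
      any(icc < 0 | icc > 1)) {
    abort("`icc` must lie in [0, 1].")
  }
  if (any(sigma2_total < 0)) {
    abort("`sigma2_total` must be non-negative.")
  }
  sqrt(sigma2_total * (1 - icc))
}

#' Total variance implied by a printed (SEM, ICC) pair
#'
#' Inverts the SEM definition: `sigma2_total = SEM^2 / (1 - ICC)`. Useful
#' to reconstruct unreported quantities from a published reliability
#' table, exploiting that the intra- and interobserver SEM of one
#' parameter share the same total variance.
#'
#' @param sem Standard error of measurement (>= 0).
#' @param icc The matching ICC, strictly below 1.
#' @return The total variance (unit^2).
#' @examples
#' # reconstruct SEM_intra from a published (ICC_inter, SEM_inter, ICC_intra)
#' s2 <- sigma2_total_from_sem(sem = 1.0, icc = 0.40)
#' sem(s2, icc = 0.60)
#' @export
sigma2_total_from_sem <- function(sem, icc) {
  if (!is.numeric(sem) || any(sem < 0)) {
    abort("`sem` must be non-negative.")
  }
  if (!is.numeric(icc) || any(icc >= 1) || any(icc < 0)) {
    abort("`icc` must lie in [0, 1).")
  }
  sem^2 / (1 - icc)
}

#' 95% confidence half-width from a SEM
#'
#' `+/- 1.96 * SEM`, the 95% interval half-width around a measurement.
#'
#' @param sem Standard error of measurement (>= 0).
#' @return `1.96 * sem`.
#' @export
reliability_ci <- function(sem) {
  if (!is.numeric(sem) || any(sem < 0)) {
    abort("`sem` must be non-negative.")
  }
  1.96 * sem
}

#' Classify an ICC value
#'
#' Standard interpretation bands: poor (< 0.50), moderate (0.50 to 0.75),
#' good (0.75 to 0.90), excellent (>= 0.90); lower bounds inclusive.
#'
#' @param icc Numeric vector of ICC values in \[0, 1\] (NA allowed).
#' @return A factor with levels poor < moderate < good < excellent.
#' @examples
#' classify_icc(c(0.41, 0.50, 0.75, 0.90))
#' @export
classify_icc <- function(icc) {
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) {
    abort("`icc` must lie in [0, 1].")
  }
  cut(icc, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE, ordered_result = TRUE)
}

#' Effect size implied by an interobserver ICC
#'
#' Converts an ICC with `k` raters into Cohen-type effect size
#' `d = (1 - ICC) / (1 + (k - 1) * ICC)`, as used for post-hoc power
#' considerations in reliability studies.
#'
#' @param icc ICC in \[0, 1\].
#' @param k Number of raters (>= 2).
#' @return The effect size (1 at ICC 0, 0 at ICC 1).
#' @examples
#' effect_size_from_icc(0.41, k = 3)  # ~0.32
#' @export
effect_size_from_icc <- function(icc, k) {
  if (!is.numeric(icc) || any(icc < 0 | icc > 1)) {
    abort("`icc` must lie in [0, 1].")
  }
  if (!is_count(k, min = 2L)) {
    abort("`k` must be an integer >= 2.")
  }
  (1 - icc) / (1 + (k - 1) * icc)
}

#' Per-parameter reliability report
#'
#' Builds a reliability table with one row per parameter: mean absolute
#' deviation summary, variance components, intra-/interobserver ICC with
#' classification, and intra-/interobserver SEM. Values are stored at full
#' precision; printing rounds to the conventional display precision
#' (1 decimal for mm/deg quantities, 2 decimals for ICCs).
#'
#' @param series A long data frame with columns `parameter`, `unit`,
#'   `scapula_id`, `observer_id`, `measure_idx`, `value`, balanced within
#'   every parameter (see [parameter_series()]).
#' @param method Variance estimation method, see
#'   [estimate_variance_components()].
#' @return A tibble of class `scapula_reliability` with columns
#'   `parameter`, `unit`, `mad_mean`, `mad_sd`, `mad_ci_low`, `mad_ci_high`,
#'   `sigma2_total`, `icc_intra`, `sem_intra`, `icc_inter`, `sem_inter`,
#'   `icc_intra_class`, `icc_inter_class`.
#' @export
reliability_table <- function(series, method = "anova") {
  needed <- c("parameter", "unit", "scapula_id", "observer_id",
              "measure_idx", "value")
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`series` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  rows <- series |>
    dplyr::group_by(.data$parameter, .data$unit) |>
    dplyr::group_modify(function(sub, key) {
      mad <- mean_absolute_deviation(sub)
      vc <- estimate_variance_components(sub, method = method)
      ii <- suppressWarnings(icc_intra(vc))
      ie <- suppressWarnings(icc_inter(vc))
      tibble::tibble(
        mad_mean = mad$mad_mean, mad_sd = mad$mad_sd,
        mad_ci_low = mad$ci_low, mad_ci_high = mad$ci_high,
        sigma2_total = vc$sigma2_total,
        icc_intra = ii,
        sem_intra = if (is.na(ii)) NA_real_ else sem(vc, ii),
        icc_inter = ie,
        sem_inter = if (is.na(ie)) NA_real_ else sem(vc, ie)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      icc_intra_class = classify_icc(.data$icc_intra),
      icc_inter_class = classify_icc(.data$icc_inter)
    )
  if (all(rows$parameter %in% PARAMETER_LEVELS)) {
    rows <- dplyr::arrange(
      rows, factor(.data$parameter, levels = PARAMETER_LEVELS))
  }
  class(rows) <- c("scapula_reliability", class(rows))
  rows
}

#' Display-rounded view of a reliability table
#'
#' Applies the conventional report rounding: 1 decimal for mm/deg
#' quantities (MAD, CI bounds, SEM), 2 decimals for ICCs.
#'
#' @param x A `scapula_reliability` table.
#' @return A plain tibble with rounded columns.
#' @export
format_reliability <- function(x) {
  dplyr::mutate(
    tibble::as_tibble(x),
    dplyr::across(dplyr::all_of(c("mad_mean", "mad_sd", "mad_ci_low",
                                  "mad_ci_high", "sem_intra", "sem_inter")),
                  ~ round(.x, 1)),
    dplyr::across(dplyr::all_of(c("icc_intra", "icc_inter")), ~ round(.x, 2)),
    sigma2_total = NULL
  )
}

#' @export
print.scapula_reliability <- function(x, ...) {
  cat("Reliability report (rounded for display; values stored at full precision)\n")
  print(format_reliability(x), n = nrow(x))
  invisible(x)
}
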