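# Variance components, ICC, SEM, MAD, classification, effect size.

test_that("mean absolute deviation matches hand-worked and oracle values", {
  s <- tibble::tibble(scapula_id = "S1", observer_id = c("O1", "O1", "O2"),
                      measure_idx = c(1L, 2L, 1L), value = c(1, 2, 3))
  m <- mean_absolute_deviation(s)
  expect_equal(m$mad_mean, 2 / 3)  # deviations 1, 0, 1

  const <- tibble::tibble(scapula_id = rep("S1", 4),
                          observer_id = rep(c("O1", "O2"), each = 2),
                          measure_idx = rep(1:2, 2), value = 5)
  mc <- mean_absolute_deviation(const)
  expect_equal(mc$mad_mean, 0)
  expect_equal(mc$mad_sd, 0)

  big <- simulate_crossed_series(81, 3, 3,
                                 c(scapula = 3, observer = 1,
                                   measure = 0.5, residual = 0.5), seed = 5)
  got <- mean_absolute_deviation(big)
  want <- oracle_mad(big)
  expect_equal(got$mad_mean, want$mean, tolerance = 1e-12)
  expect_equal(got$mad_sd, want$sd, tolerance = 1e-12)
  expect_equal(got$ci_low, want$mean - want$half, tolerance = 1e-12)
  expect_equal(got$ci_high, want$mean + want$half, tolerance = 1e-12)
  expect_equal(got$n, 81L * 9L)
  expect_true(got$ci_low <= got$mad_mean && got$mad_mean <= got$ci_high)

  expect_error(mean_absolute_deviation(s[1, ]), "at least 2")
})

test_that("ANOVA components equal the EMS linear-system oracle pre-truncation", {
  dims <- list(c(2, 2, 2), c(3, 3, 3), c(4, 3, 3))
  sig <- c(scapula = 2, observer = 0.8, measure = 0.3, residual = 0.5)
  for (k in seq_along(dims)) {
    d <- dims[[k]]
    s <- simulate_crossed_series(d[1], d[2], d[3], sig, seed = 100 + k)
    fit <- estimate_variance_components(s)
    oracle <- oracle_ems_components(s)
    expect_equal(unname(fit$sigma2_raw), unname(oracle), tolerance = 1e-10)
    # truncation invariants
    expect_true(all(fit$sigma2 >= 0))
    expect_equal(fit$sigma2_total, sum(fit$sigma2))
  }
})

test_that("noise-free additive data leaves no residual variance", {
  g <- expand.grid(s = 1:6, o = 1:3, m = 1:3)
  set.seed(9)
  a <- rnorm(6, sd = 2); b <- rnorm(3, sd = 1); cc <- rnorm(3, sd = 0.5)
  s <- tibble::tibble(scapula_id = g$s, observer_id = g$o, measure_idx = g$m,
                      value = a[g$s] + b[g$o] + cc[g$m])
  fit <- estimate_variance_components(s)
  expect_lt(fit$sigma2[["residual"]], 1e-20)
  expect_gt(fit$sigma2[["scapula"]], 0)
})

test_that("degenerate all-identical series is flagged with zero components", {
  g <- expand.grid(s = 1:2, o = 1:2, m = 1:2)
  s <- tibble::tibble(scapula_id = g$s, observer_id = g$o,
                      measure_idx = g$m, value = 7)
  fit <- estimate_variance_components(s)
  expect_true(fit$degenerate)
  expect_equal(unname(fit$sigma2), rep(0, 4))
  expect_warning(icc_intra(fit), "undefined")
  expect_true(is.na(suppressWarnings(icc_intra(fit))))
})

test_that("unbalanced series are rejected", {
  s <- simulate_crossed_series(3, 3, 3,
                               c(scapula = 1, observer = 1, measure = 1,
                                 residual = 1), seed = 1)
  expect_error(estimate_variance_components(s[-5, ]), "balanced")
  expect_error(
    estimate_variance_components(
      dplyr::filter(s, observer_id == 1)),
    ">= 2")
})

test_that("REML route agrees with ANOVA on a well-behaved series", {
  skip_if_not_installed("lme4")
  s <- simulate_crossed_series(60, 3, 3,
                               c(scapula = 4, observer = 0.3,
                                 measure = 0.2, residual = 0.6), seed = 31)
  fa <- estimate_variance_components(s, method = "anova")
  fr <- estimate_variance_components(s, method = "reml")
  # different estimators, same target: agreement within a loose band
  expect_equal(unname(fr$sigma2), unname(fa$sigma2), tolerance = 0.15)
  expect_equal(fr$sigma2[["residual"]], fa$sigma2[["residual"]],
               tolerance = 0.02)
})

test_that("ICC formulas reproduce direct substitutions", {
  vc <- c(scapula = 3, observer = 1, measure = 0.5, residual = 0.5)
  expect_equal(icc_intra(vc), 0.8)  # (5 - 1) / 5
  expect_equal(icc_inter(vc), 0.7)  # (5 - 1.5) / 5
  expect_equal(icc_intra(c(scapula = 2, observer = 0, measure = 0,
                           residual = 0)), 1)
  expect_equal(icc_intra(c(scapula = 0, observer = 0, measure = 0,
                           residual = 2)), 0)
  expect_equal(icc_inter(c(scapula = 2, observer = 0, measure = 1,
                           residual = 0)), 1)
})

test_that("SEM follows sqrt(total x (1 - ICC)) with its algebraic identities", {
  expect_equal(sem(5, 0.8), 1)
  expect_equal(sem(5, 1), 0)
  expect_equal(reliability_ci(1), 1.96)
  expect_equal(reliability_ci(0), 0)
  expect_equal(reliability_ci(0.5), 0.98)
  # shared-total consistency
  ii <- 0.62; ie <- 0.44; s2 <- 2.7
  expect_equal(sem(s2, ii) / sem(s2, ie), sqrt((1 - ii) / (1 - ie)))
  expect_equal(sigma2_total_from_sem(sem(s2, ie), ie), s2)
  expect_error(sem(5, 1.2), "0, 1")
  expect_error(sem(-1, 0.5), "non-negative")
})

test_that("ICC classification uses lower-inclusive band boundaries", {
  expect_equal(as.character(classify_icc(c(0.41, 0.50, 0.75, 0.90))),
               c("poor", "moderate", "good", "excellent"))
  expect_equal(as.character(classify_icc(c(0, 0.4999, 0.7499, 0.8999, 1))),
               c("poor", "poor", "moderate", "good", "excellent"))
  expect_true(is.na(classify_icc(NA_real_)))
  expect_error(classify_icc(1.2), "0, 1")
})

test_that("effect size conversion matches closed forms", {
  expect_equal(effect_size_from_icc(1, k = 3), 0)
  expect_equal(effect_size_from_icc(0, k = 5), 1)
  expect_equal(effect_size_from_icc(0.5, k = 3), 0.25)
  expect_error(effect_size_from_icc(0.5, k = 1), "k")
})

test_that("ICC estimates recover generative values at large n_s", {
  sigma2 <- c(scapula = 0.85, observer = 0.01, measure = 0.01,
              residual = 0.13)
  true_intra <- (0.85 + 0.01) / 1
  true_inter <- (0.85 + 0.01) / 1
  s <- simulate_crossed_series(2000, 3, 3, sigma2, seed = 7)
  fit <- estimate_variance_components(s)
  expect_lt(abs(icc_intra(fit) - true_intra), 0.03)
  expect_lt(abs(icc_inter(fit) - true_inter), 0.03)
})

test_that("tidy and glance expose the fit in broom style", {
  s <- simulate_crossed_series(10, 3, 3,
                               c(scapula = 2, observer = 0.5,
                                 measure = 0.3, residual = 0.4), seed = 3)
  fit <- estimate_variance_components(s)
  td <- tidy(fit)
  expect_equal(td$term, c("scapula", "observer", "measure", "residual"))
  expect_equal(sum(td$proportion), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$sigma2_total, fit$sigma2_total)
  expect_equal(gl$sem_intra, sem(fit, gl$icc_intra))
  expect_equal(gl$n_scapulae, 10L)
})

test_that("the reliability table composes per-series results", {
  sim <- simulate_landmark_study(generator_config(n_scapulae = 5, seed = 14))
  run_series <- parameter_series(
    to_average_cs(dplyr::select(sim$dataset, -side)),
    scapular_orientation(dplyr::select(sim$dataset, -side)))
  tbl <- reliability_table(run_series)
  expect_s3_class(tbl, "scapula_reliability")
  expect_equal(nrow(tbl), 12L)
  expect_equal(tbl$parameter[1:3], c("AA_X", "AA_Y", "AA_Z"))
  expect_equal(tbl$unit, c(rep("mm", 9), rep("deg", 3)))

  # each row equals the single-series calls
  one <- dplyr::filter(run_series, parameter == "IA_Z")
  fit <- estimate_variance_components(one)
  row <- dplyr::filter(tbl, parameter == "IA_Z")
  expect_equal(row$icc_intra, icc_intra(fit))
  expect_equal(row$sem_inter, sem(fit, icc_inter(fit)))
  expect_equal(row$mad_mean, mean_absolute_deviation(one)$mad_mean)

  # display rounding: 1 decimal mm/deg, 2 decimals ICC
  disp <- format_reliability(tbl)
  expect_equal(disp$icc_intra, round(tbl$icc_intra, 2))
  expect_equal(disp$sem_inter, round(tbl$sem_inter, 1))
})

test_that("a zero-noise dataset yields MAD 0 and undefined ICCs throughout", {
  cfg <- generator_config(n_scapulae = 3, sd_scapula = 1, sd_observer = 0,
                          sd_measure = 0, sd_residual = 0, seed = 6)
  d <- dplyr::select(simulate_landmark_study(cfg)$dataset, -side)
  series <- parameter_series(to_average_cs(d), scapular_orientation(d))
  tbl <- reliability_table(series)
  expect_equal(max(tbl$mad_mean), 0, tolerance = 1e-10)
  # within-scapula variance is zero: measure/observer/residual all zero.
  # Coordinates vary across scapulae except at frame-fixed parameters;
  # orientation angles are identical everywhere (total variance 0 -> NA).
  expect_true(all(is.na(tbl$icc_intra[tbl$parameter %in%
                                        c("e1", "e2", "e3")])))
})
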