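# Scapula frames, coordinate re-expression and the YXZ Euler sequence.

test_that("the canonical triplet yields the identity frame", {
  tpl <- canonical_triplet()
  fr <- build_scapula_frame(tpl$AA, tpl$IA, tpl$TS)
  expect_equal(fr$R, diag(3), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))
})

test_that("frames are equivariant under rigid rotation of the triplet", {
  tpl <- canonical_triplet()
  for (seed in 1:5) {
    Q <- oracle_rotation(seed)
    t <- c(5, -20, 300)
    fr0 <- build_scapula_frame(tpl$AA, tpl$IA, tpl$TS)
    fr1 <- build_scapula_frame(as.vector(Q %*% tpl$AA + t),
                               as.vector(Q %*% tpl$IA + t),
                               as.vector(Q %*% tpl$TS + t))
    expect_equal(fr1$R, Q %*% fr0$R, tolerance = 1e-9)
  }
})

test_that("every constructed frame is orthonormal with det +1", {
  set.seed(99)
  for (i in 1:50) {
    AA <- rnorm(3, sd = 50)
    IA <- AA + rnorm(3, sd = 80)
    TS <- AA + rnorm(3, sd = 80)
    if (triangle_area_oracle(AA, IA, TS) < 1) next
    fr <- build_scapula_frame(AA, IA, TS)
    expect_lt(max(abs(crossprod(fr$R) - diag(3))), 1e-9)
    expect_equal(oracle_det3(fr$R), 1, tolerance = 1e-9)
  }
})

test_that("collinear triplets are rejected as degenerate", {
  expect_error(build_scapula_frame(c(0, 0, 0), c(0, 0, 50), c(0, 0, 100)),
               "[Dd]egenerate")
  # sub-epsilon triangle (area ~0.5 mm^2)
  expect_error(build_scapula_frame(c(0, 0, 0), c(0.01, 0, 50), c(0, 0, 100)),
               "[Dd]egenerate")
})

test_that("mean landmarks are per-landmark arithmetic means", {
  d <- tiny_dataset(n_s = 1, n_o = 3, n_m = 3, jitter = 2, seed = 10)
  ml <- mean_landmarks(d)
  # independent column-mean oracle
  for (lab in c("AA", "IA", "TS")) {
    sub <- d[d$landmark == lab, ]
    expect_equal(unlist(ml[ml$landmark == lab, c("x", "y", "z")]),
                 c(x = mean(sub$x), y = mean(sub$y), z = mean(sub$z)))
  }
  # idempotence on identical records
  d0 <- tiny_dataset(n_s = 1, n_o = 2, n_m = 2, jitter = 0)
  ml0 <- mean_landmarks(d0)
  aa <- ml0[ml0$landmark == "AA", ]
  expect_equal(c(aa$x, aa$y, aa$z), canonical_triplet()$AA)
})

test_that("average-CS re-expression inverts cleanly and ignores the pose", {
  sim <- simulate_landmark_study(
    generator_config(n_scapulae = 3, sd_scapula = 1, sd_observer = 0.4,
                     sd_measure = 0.3, sd_residual = 0.6, seed = 21))
  d <- dplyr::select(sim$dataset, -side)
  acs <- to_average_cs(d)
  expect_true(all(acs$space == "average_scapula"))

  # round trip: rebuild imaging coordinates from the frame, per scapula
  for (s in unique(d$scapula_id)) {
    sub <- d[d$scapula_id == s, ]
    ml <- mean_landmarks(sub)
    pick <- function(lab) unlist(ml[ml$landmark == lab, c("x", "y", "z")],
                                 use.names = FALSE)
    fr <- build_scapula_frame(pick("AA"), pick("IA"), pick("TS"))
    back <- as.matrix(acs[acs$scapula_id == s, c("x", "y", "z")]) %*%
      t(fr$R) + matrix(fr$origin, sum(d$scapula_id == s), 3, byrow = TRUE)
    expect_lt(max(abs(back - as.matrix(sub[c("x", "y", "z")]))), 1e-9)
  }
})

test_that("average-CS coordinates are invariant under rigid imaging poses", {
  base <- generator_config(n_scapulae = 4, seed = 33,
                           pose_rotation_deg = 0, pose_translation_mm = 0)
  wild <- generator_config(n_scapulae = 4, seed = 33,
                           pose_rotation_deg = 120, pose_translation_mm = 500)
  acs0 <- to_average_cs(dplyr::select(simulate_landmark_study(base)$dataset,
                                      -side))
  acs1 <- to_average_cs(dplyr::select(simulate_landmark_study(wild)$dataset,
                                      -side))
  expect_lt(max(abs(acs0$x - acs1$x), abs(acs0$y - acs1$y),
                abs(acs0$z - acs1$z)), 1e-8)
})

test_that("the thorax rotation composes the three posture rotations", {
  expect_equal(thorax_rotation(thorax_pose(0, 0, 0))$R, diag(3))
  R <- thorax_rotation(thorax_pose())$R
  expect_equal(unname(euler_yxz_extract(R)), c(41.1, 5.4, 13.5),
               tolerance = 1e-9)
  # quarter-turn protraction: a pure Ry(90) matrix of 0s and 1s
  R90 <- thorax_rotation(thorax_pose(90, 0, 0))$R
  expect_equal(R90, matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3),
               tolerance = 1e-12)
})

test_that("applying the thorax rotation is an isometry matched by a matrix oracle", {
  d <- tiny_dataset(n_s = 2, n_o = 2, n_m = 2, jitter = 1, seed = 17)
  acs <- to_average_cs(d)
  tcs <- apply_thorax_rotation(acs, thorax_pose())
  expect_true(all(tcs$space == "thorax"))
  # norms preserved
  expect_equal(sqrt(acs$x^2 + acs$y^2 + acs$z^2),
               sqrt(tcs$x^2 + tcs$y^2 + tcs$z^2), tolerance = 1e-9)
  # identity pose leaves coordinates unchanged
  id <- apply_thorax_rotation(acs, thorax_pose(0, 0, 0))
  expect_equal(id[c("x", "y", "z")], acs[c("x", "y", "z")])
  # matches the explicit elementary-rotation product
  R <- oracle_yxz(41.1, 5.4, 13.5)
  manual <- as.matrix(acs[c("x", "y", "z")]) %*% t(R)
  expect_lt(max(abs(manual - as.matrix(tcs[c("x", "y", "z")]))), 1e-12)
})

test_that("YXZ compose matches the brute-force matrix product", {
  expect_equal(euler_yxz_compose(0, 0, 0), diag(3))
  expect_equal(euler_yxz_compose(10, 20, 30), oracle_yxz(10, 20, 30),
               tolerance = 1e-12)
  a <- euler_yxz_compose(25, -40, 110)
  expect_equal(a %*% t(a), diag(3), tolerance = 1e-12)
})

test_that("extract inverts compose over a grid of angles", {
  for (e1 in c(-150, -60, 0, 60, 150)) {
    for (e2 in c(-80, -40, 0, 40, 80)) {
      for (e3 in c(-150, -60, 0, 60, 150)) {
        ang <- euler_yxz_extract(euler_yxz_compose(e1, e2, e3))
        expect_equal(unname(ang), c(e1, e2, e3), tolerance = 1e-9)
      }
    }
  }
  expect_equal(unname(euler_yxz_extract(diag(3))), c(0, 0, 0))
})

test_that("near-gimbal poses raise an explicit error", {
  expect_error(euler_yxz_extract(euler_yxz_compose(10, 89.9999999, 30)),
               "[Gg]imbal")
  expect_error(euler_yxz_extract(euler_yxz_compose(10, -90, 30)),
               "R\\[2,3\\]")
  # comfortably away from the singularity: fine
  expect_silent(euler_yxz_extract(euler_yxz_compose(10, 89, 30)))
})

test_that("a zero-noise study reproduces the thorax pose for every cell", {
  cfg <- generator_config(n_scapulae = 3, sd_scapula = 0, sd_observer = 0,
                          sd_measure = 0, sd_residual = 0, seed = 12)
  d <- dplyr::select(simulate_landmark_study(cfg)$dataset, -side)
  ori <- scapular_orientation(d)
  expect_equal(nrow(ori), 3L * 3L * 3L)
  expect_lt(max(abs(ori$e1_deg - 41.1)), 1e-9)
  expect_lt(max(abs(ori$e2_deg - 5.4)), 1e-9)
  expect_lt(max(abs(ori$e3_deg - 13.5)), 1e-9)
  # with a null pose, all angles are zero
  ori0 <- scapular_orientation(d, pose = thorax_pose(0, 0, 0))
  expect_lt(max(abs(c(ori0$e1_deg, ori0$e2_deg, ori0$e3_deg))), 1e-9)
})

test_that("noisy orientations match a straight-line reimplementation", {
  sim <- simulate_landmark_study(generator_config(n_scapulae = 3, seed = 77))
  d <- dplyr::select(sim$dataset, -side)
  ori <- scapular_orientation(d)
  for (s in unique(d$scapula_id)) {
    expected <- oracle_orientation_chain(d[d$scapula_id == s, ],
                                         c(41.1, 5.4, 13.5))
    got <- ori[ori$scapula_id == s, ]
    merged <- merge(got, expected, by = c("observer_id", "measure_idx"))
    expect_equal(nrow(merged), 9L)
    expect_lt(max(abs(merged$e1_deg - merged$e1),
                  abs(merged$e2_deg - merged$e2),
                  abs(merged$e3_deg - merged$e3)), 1e-9)
  }
})

test_that("orientation angles are invariant under rigid imaging poses", {
  base <- generator_config(n_scapulae = 3, seed = 55,
                           pose_rotation_deg = 0, pose_translation_mm = 0)
  wild <- generator_config(n_scapulae = 3, seed = 55,
                           pose_rotation_deg = 150, pose_translation_mm = 800)
  o0 <- scapular_orientation(
    dplyr::select(simulate_landmark_study(base)$dataset, -side))
  o1 <- scapular_orientation(
    dplyr::select(simulate_landmark_study(wild)$dataset, -side))
  expect_lt(max(abs(o0$e1_deg - o1$e1_deg), abs(o0$e2_deg - o1$e2_deg),
                abs(o0$e3_deg - o1$e3_deg)), 1e-8)
})

test_that("transforms preserve inter-landmark distances", {
  d <- tiny_dataset(n_s = 2, n_o = 2, n_m = 2, jitter = 1.5, seed = 29)
  dist_of <- function(tbl) {
    tbl |>
      dplyr::group_by(scapula_id, observer_id, measure_idx) |>
      dplyr::summarise(
        d_aa_ts = sqrt(sum((c(x[landmark == "AA"], y[landmark == "AA"],
                              z[landmark == "AA"]) -
                              c(x[landmark == "TS"], y[landmark == "TS"],
                                z[landmark == "TS"]))^2)),
        .groups = "drop")
  }
  before <- dist_of(d)
  after_acs <- dist_of(to_average_cs(d))
  after_tcs <- dist_of(apply_thorax_rotation(to_average_cs(d)))
  expect_equal(before$d_aa_ts, after_acs$d_aa_ts, tolerance = 1e-9)
  expect_equal(before$d_aa_ts, after_tcs$d_aa_ts, tolerance = 1e-9)
})
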