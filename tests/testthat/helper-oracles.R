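# Independent oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: plain loops,
# explicit matrix algebra, base-R model fitting.

# --- canonical fixture -------------------------------------------------

canonical_triplet <- function() {
  list(AA = c(0, 0, 0), IA = c(0, -120, 60), TS = c(0, 0, 100))
}

# small balanced landmark table built by hand around the canonical triplet
tiny_dataset <- function(n_s = 2, n_o = 2, n_m = 2, jitter = 0, seed = 42) {
  tpl <- canonical_triplet()
  grid <- expand.grid(s = seq_len(n_s), o = seq_len(n_o), m = seq_len(n_m),
                      l = c("AA", "IA", "TS"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- tpl[[g$l]] + rnorm(3, sd = jitter)
    tibble::tibble(scapula_id = sprintf("S%02d", g$s),
                   observer_id = sprintf("O%d", g$o),
                   measure_idx = as.integer(g$m), landmark = g$l,
                   x = p[1], y = p[2], z = p[3], space = "imaging")
  })
  dplyr::bind_rows(rows)
}

# --- geometry oracles --------------------------------------------------

triangle_area_oracle <- function(AA, IA, TS) {
  a <- IA - AA
  b <- TS - AA
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  0.5 * sqrt(sum(cr^2))
}

oracle_det3 <- function(M) {
  # brute-force cofactor expansion
  M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
}

oracle_rotation <- function(seed) {
  # rotation from QR with positive diagonal, det fixed to +1
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (oracle_det3(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# explicit elementary-rotation product for the YXZ mobile sequence
oracle_yxz <- function(e1, e2, e3) {
  r <- pi / 180
  cy <- cos(e1 * r); sy <- sin(e1 * r)
  cx <- cos(e2 * r); sx <- sin(e2 * r)
  cz <- cos(e3 * r); sz <- sin(e3 * r)
  Ry <- matrix(c(cy, 0, -sy,  0, 1, 0,  sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0,  0, cx, sx,  0, -sx, cx), 3, 3)
  Rz <- matrix(c(cz, sz, 0,  -sz, cz, 0,  0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

# straight-line reimplementation of the full orientation chain for one
# scapula: plain loops, no package calls
oracle_orientation_chain <- function(data_one_scapula, pose_deg) {
  d <- as.data.frame(data_one_scapula)
  lm_mean <- function(lab) {
    sub <- d[d$landmark == lab, ]
    c(mean(sub$x), mean(sub$y), mean(sub$z))
  }
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  unitv <- function(v) v / sqrt(sum(v^2))
  frame_of <- function(AA, IA, TS) {
    Z <- unitv(TS - AA)
    X <- unitv(cross(TS - AA, IA - AA))
    cbind(X, cross(Z, X), Z)
  }
  mAA <- lm_mean("AA"); mIA <- lm_mean("IA"); mTS <- lm_mean("TS")
  R_acs <- frame_of(mAA, mIA, mTS)
  R_tcs <- oracle_yxz(pose_deg[1], pose_deg[2], pose_deg[3])

  cells <- unique(d[c("observer_id", "measure_idx")])
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    sub <- d[d$observer_id == cells$observer_id[i] &
               d$measure_idx == cells$measure_idx[i], ]
    pts <- list()
    for (lab in c("AA", "IA", "TS")) {
      p <- sub[sub$landmark == lab, ]
      p_ics <- c(p$x, p$y, p$z)
      p_acs <- t(R_acs) %*% (p_ics - mAA)       # average scapula CS
      pts[[lab]] <- as.vector(R_tcs %*% p_acs)  # thorax CS
    }
    R_scs <- frame_of(pts$AA, pts$IA, pts$TS)
    e2 <- asin(-R_scs[2, 3]) * 180 / pi
    e1 <- atan2(R_scs[1, 3], R_scs[3, 3]) * 180 / pi
    e3 <- atan2(R_scs[2, 1], R_scs[2, 2]) * 180 / pi
    out <- rbind(out, data.frame(observer_id = cells$observer_id[i],
                                 measure_idx = cells$measure_idx[i],
                                 e1 = e1, e2 = e2, e3 = e3))
  }
  out
}

# --- statistics oracles ------------------------------------------------

# expected-mean-squares linear system solved from base-R aov mean squares
oracle_ems_components <- function(series) {
  df <- data.frame(y = series$value,
                   s = factor(series$scapula_id),
                   o = factor(series$observer_id),
                   m = factor(series$measure_idx))
  ns <- nlevels(df$s); no <- nlevels(df$o); nm <- nlevels(df$m)
  an <- summary(stats::aov(y ~ s + o + m, data = df))[[1]]
  ms <- an[["Mean Sq"]]  # order: s, o, m, residuals
  A <- rbind(c(no * nm, 0, 0, 1),
             c(0, ns * nm, 0, 1),
             c(0, 0, ns * no, 1),
             c(0, 0, 0, 1))
  setNames(solve(A, ms), c("scapula", "observer", "measure", "residual"))
}

# two-pass loop computation of the mean absolute deviation summary
oracle_mad <- function(series) {
  devs <- c()
  for (s in unique(series$scapula_id)) {
    v <- series$value[series$scapula_id == s]
    devs <- c(devs, abs(v - mean(v)))
  }
  n <- length(devs)
  list(mean = mean(devs), sd = sd(devs),
       half = 1.96 * sd(devs) / sqrt(n), n = n)
}

# direct crossed-model series simulation: y_som = a_s + b_o + c_m + e
simulate_crossed_series <- function(n_s, n_o, n_m, sigma2, seed) {
  set.seed(seed)
  a <- rnorm(n_s, sd = sqrt(sigma2[["scapula"]]))
  b <- rnorm(n_o, sd = sqrt(sigma2[["observer"]]))
  cc <- rnorm(n_m, sd = sqrt(sigma2[["measure"]]))
  g <- expand.grid(s = seq_len(n_s), o = seq_len(n_o), m = seq_len(n_m))
  tibble::tibble(
    scapula_id = g$s, observer_id = g$o, measure_idx = g$m,
    value = a[g$s] + b[g$o] + cc[g$m] +
      rnorm(nrow(g), sd = sqrt(sigma2[["residual"]]))
  )
}

# exhaustive scans for the landmark positioning strategies
oracle_first_exceedance <- function(angles, threshold) {
  for (i in seq_along(angles)) {
    if (angles[i] > threshold) return(i)
  }
  NA_integer_
}

oracle_max_projection <- function(pts, d) {
  best <- 1L
  for (i in seq_len(nrow(pts))) {
    if (sum(pts[i, ] * d) > sum(pts[best, ] * d)) best <- i
  }
  best
}

# apply one rigid transform to all landmarks of given scapulae
apply_rigid <- function(data, Q, t) {
  pts <- as.matrix(data[c("x", "y", "z")]) %*% t(Q) +
    matrix(t, nrow(data), 3, byrow = TRUE)
  data$x <- pts[, 1]; data$y <- pts[, 2]; data$z <- pts[, 3]
  data
}
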