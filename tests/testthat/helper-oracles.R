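# Independent oracles used across the suite.  These deliberately avoid the
# package's own estimators: Monte-Carlo sampling and closed-form geometry
# only.

# Uniform points on a unit sphere (seeded).
runif_sphere <- function(n, seed) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
  })
}

# Monte-Carlo SASA of a set of spheres: sample points on each expanded
# sphere, keep those outside every other expanded sphere.
mc_sasa <- function(xyz, radii, probe, n_points = 1e5, seed = 42) {
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    ri <- radii[i] + probe
    pts <- sweep(runif_sphere(n_points, seed + i) * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      rj <- radii[j] + probe
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 >= rj^2
    }
    total <- total + 4 * pi * ri^2 * mean(free)
  }
  total
}

# Exact distance from a point to the allowed probe-centre region for TWO
# spheres (outside both expanded spheres).  Used by the Monte-Carlo SES
# shell oracle below.
.dist_to_allowed_2spheres <- function(x, c1, c2, R1, R2) {
  d1 <- sqrt(sum((x - c1)^2)); d2 <- sqrt(sum((x - c2)^2))
  if (d1 >= R1 && d2 >= R2) return(0)
  cand <- c()
  if (d1 > 1e-12) {
    y <- c1 + (x - c1) * (R1 / d1) # radial exit from sphere 1
    if (sqrt(sum((y - c2)^2)) >= R2 - 1e-12) cand <- c(cand, R1 - d1)
  }
  if (d2 > 1e-12) {
    y <- c2 + (x - c2) * (R2 / d2)
    if (sqrt(sum((y - c1)^2)) >= R1 - 1e-12) cand <- c(cand, R2 - d2)
  }
  # intersection circle of the two expanded spheres
  dd <- sqrt(sum((c2 - c1)^2))
  if (dd < R1 + R2 && dd > abs(R1 - R2)) {
    a <- (dd^2 + R1^2 - R2^2) / (2 * dd)
    rho <- sqrt(max(R1^2 - a^2, 0))
    ax <- (c2 - c1) / dd
    zz <- sum((x - c1) * ax)
    s <- sqrt(max(sum((x - c1)^2) - zz^2, 0))
    cand <- c(cand, sqrt((s - rho)^2 + (zz - a)^2))
  }
  min(cand)
}

# Monte-Carlo SES area for two fused spheres via a thin shell around the
# iso-surface {dist-to-allowed = probe} of the exact distance field.
mc_ses_two_spheres <- function(c1, c2, r1, r2, probe, n = 4e5,
                               eps = 0.05, seed = 7) {
  R1 <- r1 + probe; R2 <- r2 + probe
  lo <- pmin(c1 - r1, c2 - r2) - 2 * eps
  hi <- pmax(c1 + r1, c2 + r2) + 2 * eps
  vol <- prod(hi - lo)
  pts <- withr::with_seed(seed, {
    matrix(runif(3 * n), ncol = 3) %*% diag(hi - lo) +
      matrix(lo, n, 3, byrow = TRUE)
  })
  phi <- apply(pts, 1, function(x)
    .dist_to_allowed_2spheres(x, c1, c2, R1, R2) - probe)
  vol * mean(abs(phi) < eps) / (2 * eps)
}

# Brute-force AUC: pairwise comparison with ties counted one half.
pair_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Random proper rotation matrix (seeded).
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# Apply a rigid motion to a ProteinStructure.
rigid_move <- function(s, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
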