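# Independent pure-R oracles and small fixture builders. These deliberately
# avoid the package's computational paths (and its compiled kernels) so they
# can serve as cross-checks.

unit_vec <- function(v) v / sqrt(sum(v^2))

ocross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# 2D atan2 oracle for the projected angle between two directions.
oracle_projected_angle <- function(u, v, frame, plane) {
  A <- cbind(frame$x, frame$y, frame$z)
  uc <- as.numeric(u %*% A)
  vc <- as.numeric(v %*% A)
  idx <- if (plane == "YZ") c(2, 3) else c(1, 2)
  a1 <- atan2(uc[idx[2]], uc[idx[1]])
  a2 <- atan2(vc[idx[2]], vc[idx[1]])
  d <- abs(a1 - a2) * 180 / pi
  if (d > 180) d <- 360 - d
  d %% 180
}

# Brute-force Moller-Trumbore sweep over every triangle, plain R.
oracle_ray_sweep <- function(origin, dir, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ts <- numeric(0)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    e1 <- b - a; e2 <- cc - a
    p <- ocross(dir, e2)
    det <- sum(e1 * p)
    if (abs(det) < 1e-12) next
    tvec <- origin - a
    u <- sum(tvec * p) / det
    if (u < -1e-12 || u > 1 + 1e-12) next
    q <- ocross(tvec, e1)
    w <- sum(dir * q) / det
    if (w < -1e-12 || u + w > 1 + 1e-12) next
    t <- sum(e2 * q) / det
    if (t > 1e-9) ts <- c(ts, t)
  }
  sort(ts)
}

# Signed fan-triangulation area of an ordered coplanar 3D polygon.
oracle_polygon_area <- function(pts) {
  n <- nrow(pts)
  nrm <- ocross(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  s <- 0
  for (i in 2:(n - 1)) {
    tri <- ocross(pts[i, ] - pts[1, ], pts[i + 1, ] - pts[1, ])
    s <- s + sum(tri * nrm) / 2
  }
  abs(s)
}

# Tie-corrected standardized Wilcoxon rank-sum statistic (mid-ranks).
oracle_rank_stat <- function(gi, gj) {
  r <- rank(c(gi, gj))
  ni <- length(gi); nj <- length(gj); N <- ni + nj
  W <- sum(r[seq_len(ni)])
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  (W - ni * (N + 1) / 2) / sqrt(V)
}

# Two-sided normal-approximation Wilcoxon p (no continuity correction).
oracle_wilcox_p <- function(gi, gj) {
  2 * stats::pnorm(abs(oracle_rank_stat(gi, gj)), lower.tail = FALSE)
}

# Permutation reference for the all-pairs rank comparison: permute all
# labels, recompute every pairwise statistic, and compare each observed
# |t| to the permutation distribution of the max |t| (family-wise).
oracle_permutation_reference <- function(groups, B = 10000, seed = 1) {
  set.seed(seed)
  ns <- lengths(groups)
  pooled <- unlist(groups)
  idx <- rep(seq_along(groups), ns)
  pairs <- utils::combn(length(groups), 2)
  obs <- apply(pairs, 2, function(pr) {
    abs(oracle_rank_stat(groups[[pr[1]]], groups[[pr[2]]]))
  })
  maxes <- replicate(B, {
    lab <- sample(idx)
    max(apply(pairs, 2, function(pr) {
      abs(oracle_rank_stat(pooled[lab == pr[1]], pooled[lab == pr[2]]))
    }))
  })
  vapply(obs, function(o) mean(maxes >= o - 1e-12), numeric(1))
}

# ---- fixture builders -------------------------------------------------------

cube_mesh <- function(side = 1, center = c(0, 0, 0)) {
  s <- side / 2
  v <- rbind(c(-s,-s,-s), c(s,-s,-s), c(s,s,-s), c(-s,s,-s),
             c(-s,-s, s), c(s,-s, s), c(s,s, s), c(-s,s, s))
  v <- sweep(v, 2, center, "+")
  f <- rbind(c(1,3,2), c(1,4,3),  # bottom z-
             c(5,6,7), c(5,7,8),  # top z+
             c(1,2,6), c(1,6,5),  # y-
             c(2,3,7), c(2,7,6),  # x+
             c(3,4,8), c(3,8,7),  # y+
             c(4,1,5), c(4,5,8))  # x-
  clav_mesh(v, f)
}

# Watertight UV sphere / ellipsoid (radii rx, ry, rz).
ellipsoid_mesh <- function(radii = c(1, 1, 1), center = c(0, 0, 0),
                           n_theta = 32, n_phi = 16) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)[c(-1, -(n_phi + 1))]
  verts <- do.call(rbind, lapply(ph, function(p) {
    cbind(radii[1] * sin(p) * cos(th),
          radii[2] * sin(p) * sin(th),
          radii[3] * cos(p))
  }))
  north <- c(0, 0, radii[3])
  south <- c(0, 0, -radii[3])
  nv <- nrow(verts)
  verts <- rbind(verts, north, south)
  faces <- list()
  nxt <- c(seq_len(n_theta - 1) + 1, 1)
  nrings <- length(ph)
  for (i in seq_len(nrings - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- (i - 1) * n_theta + nxt
    faces[[i]] <- rbind(cbind(a, b, b + n_theta), cbind(a, b + n_theta, a + n_theta))
  }
  ring1 <- seq_len(n_theta)
  ringN <- (nrings - 1) * n_theta + seq_len(n_theta)
  faces[[nrings]] <- cbind(nv + 1L, ring1[nxt], ring1)
  faces[[nrings + 1]] <- cbind(nv + 2L, ringN, ringN[nxt])
  m <- clav_mesh(sweep(verts, 2, center, "+"), do.call(rbind, faces))
  if (mesh_volume(m) < 0) m <- clav_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  m
}

# Closed cylinder along z, and a clavicle-model wrapper around it so that
# placement/measurement code can run on an analytically simple bone.
cylinder_mesh <- function(radius = 5, length = 100, n_theta = 24,
                          n_z = 20) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(-length / 2, length / 2, length.out = n_z + 1)
  verts <- do.call(rbind, lapply(zs, function(z) {
    cbind(radius * cos(th), radius * sin(th), z)
  }))
  nv <- nrow(verts)
  verts <- rbind(verts, c(0, 0, -length / 2), c(0, 0, length / 2))
  nxt <- c(seq_len(n_theta - 1) + 1, 1)
  faces <- list()
  for (i in seq_len(n_z)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- (i - 1) * n_theta + nxt
    faces[[i]] <- rbind(cbind(a, b, b + n_theta), cbind(a, b + n_theta, a + n_theta))
  }
  ring1 <- seq_len(n_theta)
  ringN <- n_z * n_theta + seq_len(n_theta)
  faces[[n_z + 1]] <- cbind(nv + 1L, ring1[nxt], ring1)
  faces[[n_z + 2]] <- cbind(nv + 2L, ringN, ringN[nxt])
  m <- clav_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m <- clav_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  m
}

cylinder_clavicle <- function(radius = 40, length = 160, id = "cyl") {
  structure(list(
    mesh = cylinder_mesh(radius, length, n_theta = 48, n_z = 40),
    landmarks = list(sc_most_anterior = c(0, 0, -length / 2),
                     acj_most_posterior = c(0, 0, length / 2),
                     cranial_hint = c(0, 1, 0),
                     acj_end_patch = integer(0)),
    side = "left", params = NULL, id = id),
    class = "clavicle_model")
}

# A coarse synthetic clavicle shared by several test files.
test_clavicle <- function(seed = 1, length = 148, diameter = 11.5,
                          resolution = 48) {
  generate_clavicle(clavicle_params(length = length,
                                    midshaft_diameter = diameter,
                                    mesh_resolution = resolution),
                    seed = seed, id = paste0("test_", seed))
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  R <- rotation_axis_angle(ax, stats::runif(1, -180, 180))
  rigid_transform(R, stats::runif(3, -30, 30))
}
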