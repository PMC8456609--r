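id_frame <- clav_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("projected angles match the 2D atan2 oracle and trivial cases", {
  # identical directions project to zero angle
  expect_equal(projected_angle(c(0.3, 0.5, 0.2), c(0.3, 0.5, 0.2),
                               id_frame, "YZ"), 0)
  # in-plane vectors keep their angle: Y axis vs 45-degree Y/Z diagonal
  expect_equal(projected_angle(c(0, 1, 0), c(0, 1, 1) / sqrt(2),
                               id_frame, "YZ"), 45, tolerance = 1e-9)
  u <- c(0.1, 0.99, 0.1)
  v <- c(-0.1, 0.99, 0.1)
  expect_equal(projected_angle(u, v, id_frame, "YZ"),
               oracle_projected_angle(u, v, id_frame, "YZ"),
               tolerance = 1e-9)
  set.seed(42)
  for (i in 1:25) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    for (pl in c("YZ", "XY")) {
      got <- projected_angle(u, v, id_frame, pl)
      expect_equal(got, oracle_projected_angle(u, v, id_frame, pl),
                   tolerance = 1e-9)
      # symmetry in the two arguments
      expect_equal(got, projected_angle(v, u, id_frame, pl),
                   tolerance = 1e-12)
    }
  }
  # no folding: negating one oriented direction reflects the angle to 180 - a
  a <- projected_angle(c(0.2, -1, 0.3), c(-0.25, -1, -0.1), id_frame, "YZ")
  b <- projected_angle(c(0.2, -1, 0.3), -c(-0.25, -1, -0.1), id_frame, "YZ")
  expect_equal(a + b, 180, tolerance = 1e-9)
})

test_that("degenerate projections are rejected", {
  expect_error(projected_angle(c(1, 0, 0), c(0, 1, 0), id_frame, "YZ"),
               "degenerate")
})

test_that("frames are validated as orthonormal and right-handed", {
  expect_error(clav_frame(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 1)),
               "unit norm")
  expect_error(clav_frame(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  # left-handed triple rejected
  expect_error(clav_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1)),
               "right-handed")
  # random constructions via axis-angle rotations all satisfy the invariants
  for (i in 1:100) {
    R <- rotation_axis_angle(stats::rnorm(3), stats::runif(1, -180, 180))
    fr <- clav_frame(stats::rnorm(3), R[, 1], R[, 2], R[, 3])
    expect_s3_class(fr, "clav_frame")
  }
})

test_that("rigid transforms compose, invert, and round-trip", {
  a <- random_rigid(1)
  b <- random_rigid(2)
  p <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(apply_transform(compose_transforms(a, b), p),
               apply_transform(a, apply_transform(b, p)), tolerance = 1e-12)
  expect_equal(apply_transform(invert_transform(a), apply_transform(a, p)),
               p, tolerance = 1e-9)
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
})

test_that("point containment agrees with analytic shapes", {
  cube <- cube_mesh()
  expect_true(point_in_mesh(c(0, 0, 0), cube))
  sph <- ellipsoid_mesh(c(1, 1, 1))
  expect_false(point_in_mesh(c(2, 0, 0), sph))
  # 1000 random points vs the analytic ellipsoid inequality
  radii <- c(3, 2, 1.5)
  ell <- ellipsoid_mesh(radii, n_theta = 64, n_phi = 32)
  set.seed(7)
  pts <- cbind(stats::runif(1000, -3.5, 3.5), stats::runif(1000, -2.5, 2.5),
               stats::runif(1000, -2, 2))
  analytic <- rowSums(sweep(pts, 2, radii, "/")^2) < 1
  got <- point_in_mesh(pts, ell)
  expect_gte(sum(got == analytic), 999)
})

test_that("point_in_mesh requires a watertight mesh", {
  cube <- cube_mesh()
  open_mesh <- clav_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(point_in_mesh(c(0, 0, 0), open_mesh), "watertight")
})

test_that("ray crossings match geometry and the brute-force sweep", {
  sph <- ellipsoid_mesh(c(1, 1, 1) * 5, n_theta = 48, n_phi = 24)
  # generic chord offset from the poles and seams
  cr <- ray_mesh_crossings(c(-20, 0.4, 0.3), c(1, 0, 0), sph)
  half <- sqrt(25 - 0.4^2 - 0.3^2)
  expect_equal(nrow(cr), 2)
  expect_equal(cr$distance, c(20 - half, 20 + half), tolerance = 0.01)
  # tangent-type miss
  miss <- ray_mesh_crossings(c(-20, 0, 5.5), c(1, 0, 0), sph)
  expect_equal(nrow(miss), 0)
  # synthetic clavicle midshaft vs pure-R all-triangle sweep
  clav <- test_clavicle(seed = 3)
  set.seed(11)
  for (i in 1:10) {
    o <- c(stats::runif(1, -5, 5), 30, stats::runif(1, -40, 40))
    d <- unit_vec(c(stats::rnorm(1, 0, 0.1), -1, stats::rnorm(1, 0, 0.1)))
    got <- ray_mesh_crossings(o, d, clav$mesh)$distance
    want <- oracle_ray_sweep(o, d, clav$mesh)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("crossing parity matches point containment", {
  clav <- test_clavicle(seed = 5)
  origin <- c(0, 50, 0)  # well outside, above the bone
  set.seed(13)
  for (i in 1:20) {
    p <- c(stats::runif(1, -10, 10), stats::runif(1, -8, 8),
           stats::runif(1, -60, 60))
    d <- unit_vec(p - origin)
    crossings <- ray_mesh_crossings(origin, d, clav$mesh)
    n_before <- sum(crossings$distance < sqrt(sum((p - origin)^2)) - 1e-7)
    expect_equal(n_before %% 2 == 1, unname(point_in_mesh(p, clav$mesh)))
  }
})

test_that("mirroring is an involution that preserves measurements", {
  clav <- test_clavicle(seed = 9)
  m2 <- mirror_mesh(mirror_mesh(clav$mesh, c(1, 0, 0)), c(1, 0, 0))
  expect_equal(m2$vertices, clav$mesh$vertices, tolerance = 1e-12)
  cube <- cube_mesh(2)
  mc <- mirror_mesh(cube, c(0, 0, 1))
  expect_true(isTRUE(is_watertight(mc)))
  expect_equal(mesh_volume(mc), mesh_volume(cube), tolerance = 1e-12)
  # a right-side bone mirrored to the left keeps its measurements
  right <- mirror_clavicle(clav)
  expect_equal(right$side, "right")
  expect_equal(measure_length(right), measure_length(clav), tolerance = 1e-9)
  expect_equal(measure_midshaft_diameter(right),
               measure_midshaft_diameter(clav), tolerance = 1e-9)
})
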