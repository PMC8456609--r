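fixture_names <- c("distal_radial_8", "lateral_extension_6", "straight_6")

test_that("the plate frame is built from the three landmarks", {
  # axis-aligned construction: medial at origin, lateral on +z, dorsal on -x
  plate <- list(medial_end_pt = c(0, 0, 0), lateral_end_pt = c(0, 0, 50),
                dorsal_mid_pt = c(-3, 0, 25), screws = list())
  class(plate) <- "plate_model"
  fr <- compute_plate_frame(plate)
  expect_equal(fr$z, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$x, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))
  # collinear landmarks rejected
  plate$dorsal_mid_pt <- c(0, 0, 25)
  expect_error(compute_plate_frame(plate), "collinear")
})

test_that("the basal plane contains all three landmarks", {
  for (nm in fixture_names) {
    p <- make_plate_fixture(nm)
    fr <- compute_plate_frame(p)
    n <- fr$y  # basal plane normal is the frame Y axis
    for (pt in list(p$medial_end_pt, p$lateral_end_pt, p$dorsal_mid_pt)) {
      expect_lt(abs(sum((pt - fr$origin) * n)), 1e-9)
    }
  }
})

test_that("plate frames are equivariant under rigid transforms", {
  p <- make_plate_fixture("distal_radial_8")
  fr <- compute_plate_frame(p)
  for (s in 1:5) {
    tf <- random_rigid(s)
    fr2 <- compute_plate_frame(transform_plate(p, tf))
    expect_equal(fr2$origin, apply_transform(tf, fr$origin),
                 tolerance = 1e-9)
    for (ax in c("x", "y", "z")) {
      expect_equal(fr2[[ax]],
                   apply_transform(tf, fr[[ax]], direction = TRUE),
                   tolerance = 1e-9)
    }
  }
})

test_that("fixture fan angles reproduce the product values", {
  want <- list(distal_radial_8 = c(20, 32),
               lateral_extension_6 = c(12, 38),
               straight_6 = c(3, 12))
  for (nm in fixture_names) {
    fa <- measure_fan_angles(make_plate_fixture(nm))
    expect_equal(fa$alpha, want[[nm]][1], tolerance = 0.5 / want[[nm]][1])
    expect_equal(fa$beta, want[[nm]][2], tolerance = 0.5 / want[[nm]][2])
  }
  expect_error(make_plate_fixture("hook_plate"), "unknown fixture")
})

test_that("two parallel screws give zero fan angles", {
  p <- make_plate_fixture("straight_6")
  d <- p$screws[[1]]$direction
  p$screws <- list(
    list(hole_index = 1L, entry = c(0, 0, 50), direction = d,
         diameter = 2.7, max_length = 40),
    list(hole_index = 2L, entry = c(2, 0, 54), direction = d,
         diameter = 2.7, max_length = 40))
  fa <- measure_fan_angles(p)
  expect_equal(fa$alpha, 0)
  expect_equal(fa$beta, 0)
})

test_that("fan angles equal the brute-force all-pairs maximum", {
  # random screw sets: the reported angle must dominate every pair
  p0 <- make_plate_fixture("lateral_extension_6")
  fr <- compute_plate_frame(p0)
  set.seed(21)
  for (rep in 1:5) {
    dirs <- lapply(1:6, function(i) {
      unit_vec(c(stats::rnorm(1, 0, 0.25), -1, stats::rnorm(1, 0, 0.25)))
    })
    p <- p0
    p$screws <- lapply(1:6, function(i) {
      list(hole_index = i, entry = c(0, 0, 45 + i), direction = dirs[[i]],
           diameter = 2.7, max_length = 40)
    })
    fa <- measure_fan_angles(p)
    pairs <- utils::combn(6, 2)
    alpha_brute <- max(apply(pairs, 2, function(pr) {
      projected_angle(dirs[[pr[1]]], dirs[[pr[2]]], fr, "YZ")
    }))
    beta_brute <- max(apply(pairs, 2, function(pr) {
      projected_angle(dirs[[pr[1]]], dirs[[pr[2]]], fr, "XY")
    }))
    expect_equal(fa$alpha, alpha_brute, tolerance = 1e-9)
    expect_equal(fa$beta, beta_brute, tolerance = 1e-9)
  }
})

test_that("fan angles are invariant under rigid motion and mirroring", {
  for (nm in fixture_names) {
    p <- make_plate_fixture(nm)
    fa <- measure_fan_angles(p)
    fa_t <- measure_fan_angles(transform_plate(p, random_rigid(33)))
    expect_equal(fa_t$alpha, fa$alpha, tolerance = 1e-6)
    expect_equal(fa_t$beta, fa$beta, tolerance = 1e-6)
    # mirror across the basal plane (frame XZ plane through the origin)
    fr <- compute_plate_frame(p)
    pm <- p
    pm$medial_end_pt <- mirror_points(p$medial_end_pt, fr$y, fr$origin)
    pm$lateral_end_pt <- mirror_points(p$lateral_end_pt, fr$y, fr$origin)
    pm$dorsal_mid_pt <- mirror_points(p$dorsal_mid_pt, fr$y, fr$origin)
    pm$screws <- lapply(p$screws, function(s) {
      s$entry <- mirror_points(s$entry, fr$y, fr$origin)
      s$direction <- as.numeric(
        s$direction - 2 * sum(s$direction * fr$y) * fr$y)
      s
    })
    fa_m <- measure_fan_angles(pm)
    expect_equal(fa_m$alpha, fa$alpha, tolerance = 1e-6)
    expect_equal(fa_m$beta, fa$beta, tolerance = 1e-6)
  }
})
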