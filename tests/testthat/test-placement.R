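# A light configuration keeps the unit tests quick; the default study
# configuration is exercised end-to-end in the acceptance suite.
fast_cfg <- placement_config(n_multistart = 4, max_iterations = 120,
                             gap_sample_count = 120, seed = 1)

test_that("a straight plate seats on a wide cylinder with a tiny gap", {
  cyl <- cylinder_clavicle(radius = 40, length = 160)
  plate <- make_plate_fixture("straight_6")
  pl <- place_plate(cyl, plate, fast_cfg)
  expect_true(pl$feasible)
  expect_lt(pl$gap_rms, 0.5)
  expect_lt(pl$acj_distance, 2)
  expect_gte(pl$acj_distance, 0)
  expect_length(check_constraints(cyl, plate, pl$transform, fast_cfg), 0)
})

test_that("placement is deterministic for fixed inputs and config", {
  clav <- test_clavicle(seed = 31, resolution = 40)
  plate <- make_plate_fixture("straight_6")
  a <- place_plate(clav, plate, fast_cfg)
  b <- place_plate(clav, plate, fast_cfg)
  expect_identical(a$transform$R, b$transform$R)
  expect_identical(a$transform$t, b$transform$t)
})

test_that("placement is equivariant under rigid motion of the clavicle", {
  clav <- test_clavicle(seed = 31, resolution = 40)
  plate <- make_plate_fixture("straight_6")
  a <- place_plate(clav, plate, fast_cfg)
  tf <- random_rigid(77)
  b <- place_plate(transform_clavicle(clav, tf), plate, fast_cfg)
  composed <- compose_transforms(tf, a$transform)
  expect_lt(max(abs(b$transform$t - composed$t)), 0.1)
  ang <- acos(pmin(1, (sum(diag(t(b$transform$R) %*% composed$R)) - 1) / 2))
  expect_lt(ang * 180 / pi, 0.1)
  expect_equal(b$acj_distance, a$acj_distance, tolerance = 1e-6)
})

test_that("constraint checks flag ACJ overlap but not a floating plate", {
  clav <- test_clavicle(seed = 31, resolution = 40)
  plate <- make_plate_fixture("straight_6")
  pl <- place_plate(clav, plate, fast_cfg)
  fr <- compute_clavicle_frame(clav$landmarks)
  # push the plate 10 mm laterally past the ACJ
  shift <- rigid_transform(diag(3), fr$z * 10)
  v <- check_constraints(clav, plate, compose_transforms(shift, pl$transform),
                         fast_cfg)
  expect_true("ACJ_OVERLAP" %in% v)
  # a plate floating 5 mm above bone: no ACJ or overhang violation
  lift <- rigid_transform(diag(3), fr$y * 5)
  v2 <- check_constraints(clav, plate, compose_transforms(lift, pl$transform),
                          fast_cfg)
  expect_false("ACJ_OVERLAP" %in% v2)
  expect_false("SHAFT_OVERHANG" %in% v2)
})

test_that("ACJ distance responds exactly to axial translation", {
  clav <- test_clavicle(seed = 31, resolution = 40)
  plate <- make_plate_fixture("straight_6")
  pl <- place_plate(clav, plate, fast_cfg)
  d0 <- acj_plate_distance(clav, plate, pl$transform)
  expect_equal(d0, pl$acj_distance, tolerance = 1e-9)
  fr <- compute_clavicle_frame(clav$landmarks)
  medial <- rigid_transform(diag(3), -fr$z * 3)
  d3 <- acj_plate_distance(clav, plate,
                           compose_transforms(medial, pl$transform))
  expect_equal(d3 - d0, 3, tolerance = 1e-9)
})

test_that("zero-sigma jitter is the identity perturbation", {
  clav <- test_clavicle(seed = 31, resolution = 40)
  plate <- make_plate_fixture("straight_6")
  pl <- place_plate(clav, plate, fast_cfg)
  j <- jitter_placement(pl, jitter_spec(0, 0, 0, seed = 5))
  expect_equal(j$transform$R, pl$transform$R, tolerance = 1e-12)
  expect_equal(j$transform$t, pl$transform$t, tolerance = 1e-12)
})

test_that("jitter translation magnitudes follow the half-normal law", {
  # mean |dz| for dz ~ N(0, sigma) is sigma * sqrt(2/pi)
  base <- structure(list(plate_name = "x", clavicle_id = "y",
                         transform = rigid_transform(),
                         examiner_id = 1L, trial_id = 1L, seed = 0,
                         gap_rms = 0, acj_distance = 0, feasible = TRUE),
                    class = "placement")
  plate <- make_plate_fixture("straight_6")
  sigma <- 0.5
  dz <- vapply(1:1000, function(i) {
    j <- jitter_placement(base, jitter_spec(sigma, 0, 0, seed = i),
                          plate = plate)
    # pivot = plate lateral end; its displacement is the drawn translation
    p0 <- apply_transform(base$transform, plate$lateral_end_pt)
    p1 <- apply_transform(j$transform, plate$lateral_end_pt)
    (p1 - p0)[3]
  }, numeric(1))
  m_true <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt((1 - 2 / pi) / 1000)
  expect_lt(abs(mean(abs(dz)) - m_true), 3 * se)
})
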