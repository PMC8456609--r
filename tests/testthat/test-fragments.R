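test_that("a perpendicular screw through a cylinder spans its diameter", {
  cyl <- cylinder_clavicle(radius = 11.5 / 2, length = 120)
  plate <- make_plate_fixture("straight_6")
  # aim one screw straight down through the midshaft (slightly off the
  # mesh seams so the chord is generic)
  plate$screws <- list(list(hole_index = 1L, entry = c(0.2, 20, 0.3),
                            direction = c(0, -1, 0), diameter = 2.7,
                            max_length = 60))
  tr <- trace_screws(cyl, plate, rigid_transform())
  expect_equal(tr$in_bone_length, 11.5, tolerance = 0.1 / 11.5)
  expect_true(tr$has_inferior_exit)
  # a screw running parallel above the bone never touches it
  plate$screws[[1]]$entry <- c(0, 20, -50)
  plate$screws[[1]]$direction <- c(0, 0, 1)
  tr2 <- trace_screws(cyl, plate, rigid_transform())
  expect_equal(tr2$in_bone_length, 0)
  expect_false(tr2$has_inferior_exit)
})

test_that("screw traces match the brute-force triangle sweep", {
  clav <- test_clavicle(seed = 23, resolution = 40)
  plate <- make_plate_fixture("lateral_extension_6")
  cfg <- placement_config(n_multistart = 4, max_iterations = 120, seed = 2)
  pl <- place_plate(clav, plate, cfg)
  tr <- trace_screws(clav, plate, pl$transform)
  for (i in seq_along(plate$screws)) {
    s <- plate$screws[[i]]
    o <- apply_transform(pl$transform, s$entry)
    d <- unit_vec(apply_transform(pl$transform, s$direction,
                                  direction = TRUE))
    want <- oracle_ray_sweep(o, d, clav$mesh)
    want <- want[want <= s$max_length]
    if (length(want) >= 2) {
      entry <- o + want[1] * d
      exitp <- o + want[2] * d
      expect_equal(c(tr$entry_x[i], tr$entry_y[i], tr$entry_z[i]), entry,
                   tolerance = 1e-6)
      expect_equal(c(tr$exit_x[i], tr$exit_y[i], tr$exit_z[i]), exitp,
                   tolerance = 1e-6)
    }
  }
})

test_that("contained counts honor the cut plane and grow with fragment size", {
  clav <- test_clavicle(seed = 23, resolution = 40)
  plate <- make_plate_fixture("distal_radial_8")
  cfg <- placement_config(n_multistart = 4, max_iterations = 120, seed = 2)
  pl <- place_plate(clav, plate, cfg)
  tr <- trace_screws(clav, plate, pl$transform)
  # a cut through the ACJ point leaves no bone lateral of it
  expect_equal(count_contained(tr, axial_plane_at(clav, 0)), 0L)
  counts <- vapply(c(10, 15, 20, 25, 30), function(fs) {
    count_contained(tr, axial_plane_at(clav, fs))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[4], 8L)
  # every contained screw lies strictly inside the bone mid-trace
  plane <- axial_plane_at(clav, 25)
  for (i in seq_len(nrow(tr))) {
    if (tr$in_bone_length[i] < 2) next
    mid <- (c(tr$entry_x[i], tr$entry_y[i], tr$entry_z[i]) +
              c(tr$exit_x[i], tr$exit_y[i], tr$exit_z[i])) / 2
    expect_true(point_in_mesh(mid, clav$mesh))
  }
})

test_that("covered area reduces to the shoelace of simple shapes", {
  plate <- make_plate_fixture("straight_6")
  mk_traces <- function(pts, inferior = TRUE) {
    data.frame(hole_index = seq_len(nrow(pts)),
               entry_x = pts[, 1], entry_y = pts[, 2] + 10,
               entry_z = pts[, 3],
               exit_x = pts[, 1], exit_y = pts[, 2], exit_z = pts[, 3],
               in_bone_length = 10,
               has_inferior_exit = inferior,
               dist_from_acj = 5)
  }
  # planar 5 x 10 rectangle -> 50 mm^2
  rect <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 0, 10), c(0, 0, 10))
  plate$screws <- lapply(1:4, function(i) {
    list(hole_index = i, entry = rect[i, ], direction = c(0, -1, 0),
         diameter = 2.7, max_length = 40)
  })
  expect_equal(as.numeric(covered_area(mk_traces(rect), plate)), 50,
               tolerance = 1e-9)
  # two exits only -> zero area
  expect_equal(as.numeric(covered_area(mk_traces(rect[1:2, ]), plate)), 0)
  # random simple coplanar polygons match the fan-triangulation oracle
  # (radial polygons with bounded angular gaps are guaranteed simple)
  set.seed(3)
  for (rep in 1:10) {
    ang <- (0:5) * pi / 3 + stats::runif(6, -0.4, 0.4)
    r <- stats::runif(6, 2, 6)
    pts2 <- cbind(r * cos(ang), 0, r * sin(ang))
    basis <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(basis) < 0) basis[, 3] <- -basis[, 3]
    pts3 <- pts2 %*% t(basis)
    plate$screws <- lapply(1:6, function(i) {
      list(hole_index = i, entry = pts3[i, ], direction = c(0, -1, 0),
           diameter = 2.7, max_length = 40)
    })
    got <- as.numeric(covered_area(mk_traces(pts3), plate))
    expect_equal(got, oracle_polygon_area(pts3), tolerance = 1e-9)
  }
})

test_that("self-intersecting hole orders fall back to the convex hull", {
  plate <- make_plate_fixture("straight_6")
  # bow-tie order of a unit square
  pts <- rbind(c(0, 0, 0), c(1, 0, 1), c(1, 0, 0), c(0, 0, 1))
  plate$screws <- lapply(1:4, function(i) {
    list(hole_index = i, entry = pts[i, ], direction = c(0, -1, 0),
         diameter = 2.7, max_length = 40)
  })
  traces <- data.frame(hole_index = 1:4, entry_x = pts[, 1],
                       entry_y = pts[, 2] + 10, entry_z = pts[, 3],
                       exit_x = pts[, 1], exit_y = pts[, 2],
                       exit_z = pts[, 3], in_bone_length = 10,
                       has_inferior_exit = TRUE, dist_from_acj = 5)
  a <- covered_area(traces, plate)
  expect_true(attr(a, "convex_hull"))
  expect_equal(as.numeric(a), 1, tolerance = 1e-9)
})

test_that("ligament involvement follows the attachment intervals", {
  # 5 mm fracture line: lateral to both ligaments, Craig type 1/3 range
  r5 <- ligament_involvement(5)
  expect_length(r5$zones, 0)
  expect_match(r5$craig_hint, "type 1/3")
  r20 <- ligament_involvement(20)
  expect_equal(r20$zones, "trapezoid")
  expect_match(r20$craig_hint, "2B/5")
  r47 <- ligament_involvement(47)
  expect_setequal(r47$zones, c("trapezoid", "conoid"))
  expect_equal(ligament_zones$trapezoid, c(8, 26))
  expect_equal(ligament_zones$conoid, c(26, 47))
})
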