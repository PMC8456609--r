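# Plate fixtures and the plate coordinate system.
#
# A plate model carries three frame landmarks (medial end, lateral end, and
# the dorsal-rim midpoint, all at mid-thickness), a slab body mesh, and an
# ordered set of locking screws (entry point + top-to-tip unit direction,
# plate-local mm). In plate-local coordinates the plate runs along +Z
# (medial end at the origin), +X is volar/anterior, +Y cranial; the underside
# that seats on bone is y = -thickness/2. Screw hole order is the
# covered-area polygon adjacency: index 1 is the most medial/anterior hole
# and the sequence traces the hole loop.

plate_screw <- function(hole_index, entry, a_deg, b_deg,
                        diameter = 2.7, max_length = 40) {
  # a = inclination in the coronal (YZ) plane, b = in the sagittal (XY)
  # plane, both measured from straight-down (-Y); direction top -> tip.
  dir <- unit(c(tan(b_deg * pi / 180), -1, tan(a_deg * pi / 180)))
  list(hole_index = as.integer(hole_index), entry = as.numeric(entry),
       direction = dir, diameter = diameter, max_length = max_length)
}

# Lofted curved-slab plate body: midline x(z) = -bow * sin(pi z / length)
# (pre-contoured to follow the clavicle's posterior-convex lateral bow),
# rectangular section of the given width profile, thickness 2 mm.
plate_body_mesh <- function(length, shaft_width, pad_width, pad_from, bow,
                            thickness = 2, nz = 31) {
  zs <- seq(0, length, length.out = nz)
  xm <- -bow * sin(pi * zs / length)
  w <- shaft_width + (pad_width - shaft_width) *
    smoothstep((zs - pad_from) / (0.6 * (length - pad_from)))
  h <- thickness / 2
  verts <- matrix(0, 4 * nz, 3)
  for (i in seq_len(nz)) {
    rows <- (4 * i - 3):(4 * i)
    verts[rows, ] <- cbind(
      xm[i] + c(-w[i] / 2, w[i] / 2, w[i] / 2, -w[i] / 2),
      c(-h, -h, h, h), zs[i])
  }
  faces <- vector("list", nz + 1)
  for (i in seq_len(nz - 1)) {
    a <- (4 * i - 3):(4 * i)
    b <- a[c(2, 3, 4, 1)]
    c1 <- a + 4L
    d1 <- b + 4L
    faces[[i]] <- rbind(cbind(a, b, d1), cbind(a, d1, c1))
  }
  faces[[nz]] <- rbind(c(1L, 4L, 3L), c(1L, 3L, 2L))  # medial cap, -z outward
  top <- 4L * (nz - 1L)
  faces[[nz + 1]] <- rbind(top + c(1L, 2L, 3L), top + c(1L, 3L, 4L))
  mesh <- clav_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(mesh) < 0) {
    mesh <- clav_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
  }
  mesh
}

#' Construct one of the three packaged lateral-clavicle plate fixtures
#'
#' The fixtures emulate the three commercially shaped implant families
#' compared in the study: `distal_radial_8` (eight radially fanned lateral
#' locking screws, coronal/sagittal fan 20/32 degrees), `lateral_extension_6`
#' (two rows of three screws angled 19 degrees forward/backward, fan 12/38),
#' and `straight_6` (six near-parallel screws, fan 3/12). Screw directions
#' are fixture constants chosen so the fan angles measured through the plate
#' frame reproduce those printed values exactly.
#'
#' @param name one of `"distal_radial_8"`, `"lateral_extension_6"`,
#'   `"straight_6"`.
#' @return list of class `plate_model` with `name`, `body`, landmark points,
#'   `screws`, `length`, `thickness`.
#' @export
make_plate_fixture <- function(name = c("distal_radial_8",
                                        "lateral_extension_6",
                                        "straight_6")) {
  if (!is.character(name) || !name[1] %in%
      c("distal_radial_8", "lateral_extension_6", "straight_6")) {
    stop("unknown fixture: ", name[1], call. = FALSE)
  }
  name <- name[1]
  thickness <- 2
  if (name == "distal_radial_8") {
    Lp <- 62; ws <- 10; wp <- 16; pad_from <- Lp - 18; bow <- 6
    xm <- function(z) -bow * sin(pi * z / Lp)
    cz <- Lp - 8
    phi <- (180 + 45 * (0:7)) * pi / 180  # hole 1 most medial, loop order
    screws <- lapply(1:8, function(i) {
      plate_screw(i,
                  entry = c(xm(cz) + 5 * sin(phi[i]), 0,
                            cz + 5 * cos(phi[i])),
                  a_deg = 10 * cos(phi[i]),
                  b_deg = 16 * sin(phi[i]))
    })
  } else if (name == "lateral_extension_6") {
    Lp <- 60; ws <- 10; wp <- 16; pad_from <- Lp - 16; bow <- 6
    xm <- function(z) -bow * sin(pi * z / Lp)
    zf <- c(Lp - 12, Lp - 8.5, Lp - 5)
    ent <- rbind(cbind(xm(zf) + 3.8, 0, zf),          # anterior row, medial->lateral
                 cbind(xm(rev(zf)) - 3.8, 0, rev(zf)))  # posterior row, lateral->medial
    a <- c(-6, 0, 6, 6, 0, -6)
    b <- c(19, 19, 19, -19, -19, -19)
    screws <- lapply(1:6, function(i) plate_screw(i, ent[i, ], a[i], b[i]))
  } else {
    Lp <- 58; ws <- 9; wp <- 14; pad_from <- Lp - 15; bow <- 6
    xm <- function(z) -bow * sin(pi * z / Lp)
    zf <- c(Lp - 12.5, Lp - 8, Lp - 3.5)
    ent <- rbind(cbind(xm(zf) + 3.5, 0, zf),
                 cbind(xm(rev(zf)) - 3.5, 0, rev(zf)))
    a <- c(-1.5, 0, 1.5, 1.5, 0, -1.5)
    b <- c(6, 6, 6, -6, -6, -6)
    screws <- lapply(1:6, function(i) plate_screw(i, ent[i, ], a[i], b[i]))
  }
  body <- plate_body_mesh(Lp, ws, wp, pad_from, bow, thickness)
  wmid <- ws + (wp - ws) * smoothstep((Lp / 2 - pad_from) /
                                        (0.6 * (Lp - pad_from)))
  structure(list(
    name = name, body = body,
    medial_end_pt = c(0, 0, 0),
    lateral_end_pt = c(0, 0, Lp),
    dorsal_mid_pt = c(-bow - wmid / 2, 0, Lp / 2),
    screws = screws, length = Lp, thickness = thickness,
    shaft_width = ws, pad_width = wp, pad_from = pad_from, bow = bow),
    class = "plate_model")
}

#' @export
print.plate_model <- function(x, ...) {
  cat("<plate_model>", x$name, "-", length(x$screws), "lateral screws,",
      x$length, "mm long\n")
  invisible(x)
}

plate_landmark_matrix <- function(plate) {
  rbind(plate$medial_end_pt, plate$lateral_end_pt, plate$dorsal_mid_pt)
}

#' Plate coordinate system from the three plate landmarks
#'
#' The basal plane passes through the medial end, lateral end, and
#' dorsal-rim midpoint (all at mid-thickness). Z runs from the medial to the
#' lateral end point; X lies in the basal plane perpendicular to Z and
#' points volar (the side opposite the dorsal landmark); Y = Z x X points
#' cranial, away from the screw-tip half-space.
#'
#' @param plate a `plate_model`.
#' @return a [clav_frame()] with origin at the medial end point.
#' @export
compute_plate_frame <- function(plate) {
  med <- plate$medial_end_pt
  lat <- plate$lateral_end_pt
  dor <- plate$dorsal_mid_pt
  area2 <- sqrt(sum(cross(lat - med, dor - med)^2))
  if (area2 / 2 <= 1) {
    stop("collinear landmarks: plate landmark triangle area <= 1 mm^2",
         call. = FALSE)
  }
  z <- unit(lat - med)
  dproj <- (dor - med) - sum((dor - med) * z) * z
  x <- -unit(dproj)  # volar = opposite the dorsal-rim side
  y <- cross(z, x)
  if (length(plate$screws) > 0) {
    dirs <- t(vapply(plate$screws, `[[`, numeric(3), "direction"))
    if (mean(dirs %*% y) > 0) {  # keep Y cranial (screws point caudal)
      x <- -x
      y <- -y
    }
  }
  clav_frame(origin = med, axis_x = x, axis_y = y, axis_z = z)
}

#' Measure the coronal and sagittal screw fan angles of a plate
#'
#' The fan angle alpha is the largest projected angle between any two screw
#' directions in the plate frame's YZ (coronal) plane — attained by the most
#' medial and most lateral screws; beta is the analogue in the XY (sagittal)
#' plane for the most anterior/posterior screws. Ties resolve to the lowest
#' hole index.
#'
#' @param plate a `plate_model` with >= 2 screws.
#' @return list of class `fan_angles`: `alpha`, `beta` (degrees) and
#'   `extreme` (hole indices: medial, lateral, anterior, posterior).
#' @export
measure_fan_angles <- function(plate) {
  if (length(plate$screws) < 2) stop("need at least 2 screws", call. = FALSE)
  fr <- compute_plate_frame(plate)
  dirs <- t(vapply(plate$screws, `[[`, numeric(3), "direction"))
  ids <- vapply(plate$screws, `[[`, integer(1), "hole_index")
  dl <- to_frame_coords(fr, dirs, direction = TRUE)
  pair_max <- function(idx2) {
    n <- nrow(dl)
    best <- c(0, 1, 1)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- dl[i, idx2]; v <- dl[j, idx2]
        nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
        if (nu <= 1e-9 || nv <= 1e-9) {
          stop("degenerate projection for screw pair", call. = FALSE)
        }
        ang <- acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
        if (ang > best[1] + 1e-12) best <- c(ang, i, j)
      }
    }
    best
  }
  am <- pair_max(c(2, 3))  # YZ / coronal
  bm <- pair_max(c(1, 2))  # XY / sagittal
  s <- -sign(mean(dl[, 2]))  # screws point caudal: -Y dominant
  incl_a <- atan2(dl[, 3], s * dl[, 2])
  incl_b <- atan2(dl[, 1], s * dl[, 2])
  ia <- c(am[2], am[3]); ib <- c(bm[2], bm[3])
  structure(list(
    alpha = am[1], beta = bm[1],
    extreme = c(medial = ids[ia[which.min(incl_a[ia])]],
                lateral = ids[ia[which.max(incl_a[ia])]],
                posterior = ids[ib[which.min(incl_b[ib])]],
                anterior = ids[ib[which.max(incl_b[ib])]])),
    class = "fan_angles")
}

#' @export
print.fan_angles <- function(x, ...) {
  cat(sprintf("fan angles: alpha = %.2f deg (coronal), beta = %.2f deg (sagittal)\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Apply a rigid transform to an entire plate model
#' @param plate a `plate_model`.
#' @param tf a [rigid_transform()].
#' @return the transformed `plate_model`.
#' @export
transform_plate <- function(plate, tf) {
  plate$body <- clav_mesh(apply_transform(tf, plate$body$vertices),
                          plate$body$faces)
  plate$medial_end_pt <- apply_transform(tf, plate$medial_end_pt)
  plate$lateral_end_pt <- apply_transform(tf, plate$lateral_end_pt)
  plate$dorsal_mid_pt <- apply_transform(tf, plate$dorsal_mid_pt)
  plate$screws <- lapply(plate$screws, function(s) {
    s$entry <- apply_transform(tf, s$entry)
    s$direction <- apply_transform(tf, s$direction, direction = TRUE)
    s
  })
  plate
}

#' Serialize a plate fixture to JSON
#' @param plate a `plate_model`.
#' @param path output path.
#' @export
write_plate_json <- function(plate, path) {
  jsonlite::write_json(list(
    name = plate$name,
    length = plate$length, thickness = plate$thickness,
    medial_end_pt = plate$medial_end_pt,
    lateral_end_pt = plate$lateral_end_pt,
    dorsal_mid_pt = plate$dorsal_mid_pt,
    screws = lapply(plate$screws, function(s) {
      list(hole_index = s$hole_index, entry = s$entry,
           direction = s$direction, diameter = s$diameter,
           max_length = s$max_length)
    })), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plate fixture from JSON (body mesh is not serialized)
#' @param path JSON path written by [write_plate_json()].
#' @return a `plate_model` without a `body` mesh.
#' @export
read_plate_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    name = j$name, body = NULL,
    medial_end_pt = as.numeric(j$medial_end_pt),
    lateral_end_pt = as.numeric(j$lateral_end_pt),
    dorsal_mid_pt = as.numeric(j$dorsal_mid_pt),
    screws = lapply(seq_len(nrow(j$screws)), function(i) {
      list(hole_index = as.integer(j$screws$hole_index[i]),
           entry = as.numeric(j$screws$entry[[i]]),
           direction = as.numeric(j$screws$direction[[i]]),
           diameter = j$screws$diameter[i],
           max_length = j$screws$max_length[i])
    }),
    length = j$length, thickness = j$thickness),
    class = "plate_model")
}
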