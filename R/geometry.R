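#' @useDynLib clavsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- vectors and frames -----------------------------------------------------

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n <= 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

#' Construct an orthonormal right-handed coordinate frame
#'
#' A frame holds an origin (mm) and three mutually orthogonal unit axes.
#' Plate and clavicle coordinate systems are represented this way: Z runs
#' medial-to-lateral along the object, X points anterior (volar), Y cranial.
#'
#' @param origin numeric length-3, mm.
#' @param axis_x,axis_y,axis_z numeric length-3 unit direction vectors.
#' @return An object of class `clav_frame`.
#' @export
clav_frame <- function(origin, axis_x, axis_y, axis_z) {
  origin <- as.numeric(origin)
  axis_x <- as.numeric(axis_x); axis_y <- as.numeric(axis_y)
  axis_z <- as.numeric(axis_z)
  stopifnot(length(origin) == 3, length(axis_x) == 3,
            length(axis_y) == 3, length(axis_z) == 3)
  tol <- 1e-9
  for (a in list(axis_x, axis_y, axis_z)) {
    if (abs(sqrt(sum(a^2)) - 1) > tol) {
      stop("frame axes must have unit norm", call. = FALSE)
    }
  }
  if (abs(sum(axis_x * axis_y)) > tol || abs(sum(axis_y * axis_z)) > tol ||
      abs(sum(axis_z * axis_x)) > tol) {
    stop("frame axes must be pairwise orthogonal", call. = FALSE)
  }
  if (abs(sum(cross(axis_x, axis_y) * axis_z) - 1) > 1e-9) {
    stop("frame must be right-handed (x cross y = z)", call. = FALSE)
  }
  structure(list(origin = origin, x = axis_x, y = axis_y, z = axis_z),
            class = "clav_frame")
}

#' @export
print.clav_frame <- function(x, ...) {
  cat("<clav_frame>\n origin:", signif(x$origin, 6), "\n")
  cat(" x:", signif(x$x, 6), "\n y:", signif(x$y, 6),
      "\n z:", signif(x$z, 6), "\n")
  invisible(x)
}

cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Express world points or directions in frame coordinates
#'
#' @param frame a [clav_frame()].
#' @param p numeric length-3 or an n x 3 matrix of world points.
#' @param direction logical; if `TRUE`, skip the origin shift.
#' @return Coordinates in the frame basis, same shape as `p`.
#' @export
to_frame_coords <- function(frame, p, direction = FALSE) {
  A <- cbind(frame$x, frame$y, frame$z)
  if (is.matrix(p)) {
    q <- if (direction) p else sweep(p, 2, frame$origin)
    q %*% A
  } else {
    q <- if (direction) p else p - frame$origin
    as.numeric(q %*% A)
  }
}

#' @rdname to_frame_coords
#' @export
from_frame_coords <- function(frame, p, direction = FALSE) {
  A <- cbind(frame$x, frame$y, frame$z)
  if (is.matrix(p)) {
    q <- p %*% t(A)
    if (direction) q else sweep(q, 2, frame$origin, "+")
  } else {
    q <- as.numeric(A %*% p)
    if (direction) q else q + frame$origin
  }
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (determinant +1).
#' @param translation numeric length-3, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be a proper orthonormal matrix", call. = FALSE)
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or directions
#' @param tf a [rigid_transform()].
#' @param p length-3 vector or n x 3 matrix.
#' @param direction logical; directions are rotated only.
#' @export
apply_transform <- function(tf, p, direction = FALSE) {
  if (is.matrix(p)) {
    q <- p %*% t(tf$R)
    if (direction) q else sweep(q, 2, tf$t, "+")
  } else {
    q <- as.numeric(tf$R %*% p)
    if (direction) q else q + tf$t
  }
}

#' Compose rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Rotation matrix from small Euler angles (degrees, X-Y-Z intrinsic)
#' @param rx,ry,rz rotations in degrees about x, y, z.
#' @export
rotation_xyz <- function(rx = 0, ry = 0, rz = 0) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#' @param axis length-3 rotation axis (any norm).
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  axis <- unit(axis)
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# ---- triangle meshes --------------------------------------------------------

#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `clav_mesh`.
#' @export
clav_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "clav_mesh")
}

#' @export
print.clav_mesh <- function(x, ...) {
  cat("<clav_mesh>", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  invisible(x)
}

#' Check mesh watertightness and orientation
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and consistently oriented when each directed edge appears once.
#'
#' @param mesh a [clav_mesh()].
#' @return logical scalar; attribute `"reason"` explains a failure.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key_dir)) {
    return(structure(FALSE, reason = "duplicated directed edge (inconsistent orientation)"))
  }
  key_undir <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key_undir)
  if (any(tab != 2)) {
    return(structure(FALSE, reason = "edge not shared by exactly two faces"))
  }
  TRUE
}

#' Signed volume of a closed mesh (positive for outward normals)
#' @param mesh a [clav_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(a * cr) / 6
}

face_normals <- function(mesh, faces = seq_len(nrow(mesh$faces))) {
  v <- mesh$vertices
  f <- mesh$faces[faces, , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Test whether points lie strictly inside a watertight mesh
#'
#' Uses the generalized winding number, which is robust to rays grazing
#' edges or coplanar patches.
#'
#' @param p length-3 vector or n x 3 matrix of query points, mm.
#' @param mesh a watertight [clav_mesh()].
#' @return logical vector.
#' @export
point_in_mesh <- function(p, mesh) {
  wt <- is_watertight(mesh)
  if (!isTRUE(wt)) {
    stop("point_in_mesh requires a watertight mesh: ", attr(wt, "reason"),
         call. = FALSE)
  }
  P <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  w <- cpp_winding_number(P, mesh$vertices, mesh$faces)
  w > 0.5
}

#' Ordered ray/mesh crossings
#'
#' Casts a ray and returns every surface crossing sorted by distance,
#' with the outward unit normal of the crossed face.
#'
#' @param origin length-3 ray origin, mm.
#' @param direction length-3 unit direction.
#' @param mesh a [clav_mesh()].
#' @return data frame with columns `distance`, `face`, and hit coordinates
#'   `x`,`y`,`z`, plus normal components `nx`,`ny`,`nz`; zero rows for a miss.
#' @export
ray_mesh_crossings <- function(origin, direction, mesh) {
  stopifnot(abs(sqrt(sum(direction^2)) - 1) < 1e-6)
  h <- cpp_ray_mesh(origin, direction, mesh$vertices, mesh$faces)
  if (nrow(h) == 0) {
    return(data.frame(distance = numeric(0), face = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      nx = numeric(0), ny = numeric(0), nz = numeric(0)))
  }
  pts <- matrix(origin, nrow(h), 3, byrow = TRUE) +
    h[, 1] %o% as.numeric(direction)
  nrm <- face_normals(mesh, as.integer(h[, 2]))
  data.frame(distance = h[, 1], face = as.integer(h[, 2]),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
}

#' Minimum unsigned distance from points to a mesh surface
#' @param p length-3 vector or n x 3 matrix.
#' @param mesh a [clav_mesh()].
#' @return numeric vector of distances, mm.
#' @export
point_mesh_distance <- function(p, mesh) {
  P <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  cpp_point_mesh_dist(P, mesh$vertices, mesh$faces)
}

#' Mirror a mesh across a plane through the origin
#'
#' Vertices are reflected and face winding is flipped so normals stay
#' outward; right-sided bones become left-sided ones this way.
#'
#' @param mesh a [clav_mesh()].
#' @param plane_normal length-3 unit normal of the mirror plane.
#' @param plane_point a point on the mirror plane (default origin).
#' @return the mirrored [clav_mesh()].
#' @export
mirror_mesh <- function(mesh, plane_normal, plane_point = c(0, 0, 0)) {
  n <- unit(plane_normal)
  v <- sweep(mesh$vertices, 2, plane_point)
  v <- v - 2 * (v %*% n) %*% t(n)
  v <- sweep(v, 2, plane_point, "+")
  clav_mesh(v, mesh$faces[, c(1, 3, 2)])
}

#' Reflect points across a plane
#' @inheritParams mirror_mesh
#' @param p length-3 vector or n x 3 matrix.
#' @export
mirror_points <- function(p, plane_normal, plane_point = c(0, 0, 0)) {
  n <- unit(plane_normal)
  if (!is.matrix(p)) {
    q <- p - plane_point
    return(q - 2 * sum(q * n) * n + plane_point)
  }
  q <- sweep(p, 2, plane_point)
  sweep(q - 2 * (q %*% n) %*% t(n), 2, plane_point, "+")
}

# ---- projected angles -------------------------------------------------------

#' Angle between two directions projected into a frame plane
#'
#' Both directions are expressed in the frame basis, projected into the
#' named coordinate plane (YZ = coronal, XY = sagittal), and the unsigned
#' angle between the oriented projections is returned in degrees.
#' Screw directions are oriented plate-top-to-tip, so fan angles between
#' like-oriented screws come out directly; no folding is applied.
#'
#' @param u,v length-3 direction vectors (world coordinates, any norm > 0).
#' @param frame a [clav_frame()].
#' @param plane `"YZ"` or `"XY"`.
#' @return angle in degrees, in [0, 180).
#' @export
projected_angle <- function(u, v, frame, plane = c("YZ", "XY")) {
  plane <- match.arg(plane)
  uc <- to_frame_coords(frame, u, direction = TRUE)
  vc <- to_frame_coords(frame, v, direction = TRUE)
  idx <- if (plane == "YZ") c(2, 3) else c(1, 2)
  u2 <- uc[idx]; v2 <- vc[idx]
  nu <- sqrt(sum(u2^2)); nv <- sqrt(sum(v2^2))
  if (nu <= 1e-9 || nv <= 1e-9) {
    stop("degenerate projection: direction is perpendicular to the ", plane,
         " plane", call. = FALSE)
  }
  # atan2 of the 2D cross/dot pair: exact for parallel projections and
  # better conditioned than acos near 0 and 180 degrees
  atan2(abs(u2[1] * v2[2] - u2[2] * v2[1]), sum(u2 * v2)) * 180 / pi
}
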