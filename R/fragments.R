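# Screw tracing through bone, fragment containment counting, inferior-cortex
# covered area, and coracoclavicular ligament zone mapping.

#' Coracoclavicular ligament attachment zones (mm from the ACJ)
#'
#' Trapezoid ligament 8-26 mm, conoid ligament 26-47 mm from the ACJ along
#' the clavicle axis.
#' @export
ligament_zones <- list(trapezoid = c(8, 26), conoid = c(26, 47),
                       combined = c(8, 47))

#' Trace each screw of a placed plate through the bone
#'
#' Casts the world-space axis of every screw: the first cortex crossing is
#' the entry, the second the (bicortical) exit, capped at the screw's
#' maximum length. Screws missing the bone are recorded with zero in-bone
#' length. An exit counts as an inferior-cortex exit when the exit surface
#' normal points caudal (clavicle-frame Y component < -0.2).
#'
#' @param clavicle a `clavicle_model`.
#' @param plate a `plate_model`.
#' @param tf plate-local-to-world [rigid_transform()].
#' @return data frame of class `screw_traces`: one row per screw with
#'   `hole_index`, entry/exit coordinates, `in_bone_length`,
#'   `has_inferior_exit`, `dist_from_acj` (of the inferior exit, mm).
#' @export
trace_screws <- function(clavicle, plate, tf) {
  fr <- compute_clavicle_frame(clavicle$landmarks)
  z_acj <- to_frame_coords(fr, clavicle$landmarks$acj_most_posterior)[3]
  rows <- lapply(plate$screws, function(s) {
    o <- apply_transform(tf, s$entry)
    d <- unit(apply_transform(tf, s$direction, direction = TRUE))
    cr <- ray_mesh_crossings(o, d, clavicle$mesh)
    cr <- cr[cr$distance <= s$max_length, , drop = FALSE]
    out <- list(hole_index = s$hole_index,
                ex = NA_real_, ey = NA_real_, ez = NA_real_,
                xx = NA_real_, xy = NA_real_, xz = NA_real_,
                in_bone_length = 0,
                has_inferior_exit = FALSE, dist_from_acj = NA_real_)
    if (nrow(cr) >= 1) {
      t1 <- cr$distance[1]
      t2 <- if (nrow(cr) >= 2) cr$distance[2] else s$max_length
      entry <- o + t1 * d
      exitp <- o + t2 * d
      out$ex <- entry[1]; out$ey <- entry[2]; out$ez <- entry[3]
      out$xx <- exitp[1]; out$xy <- exitp[2]; out$xz <- exitp[3]
      out$in_bone_length <- t2 - t1
      if (nrow(cr) >= 2) {
        nrm <- c(cr$nx[2], cr$ny[2], cr$nz[2])
        if (sum(nrm * fr$y) < -0.2) {
          out$has_inferior_exit <- TRUE
          out$dist_from_acj <- z_acj - to_frame_coords(fr, exitp)[3]
        }
      }
    }
    out
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  names(df) <- c("hole_index", "entry_x", "entry_y", "entry_z",
                 "exit_x", "exit_y", "exit_z", "in_bone_length",
                 "has_inferior_exit", "dist_from_acj")
  class(df) <- c("screw_traces", class(df))
  df
}

#' Count screws completely inserted in a lateral fragment
#'
#' A screw counts when it has at least 2 mm of bone purchase and every one
#' of 51 uniformly sampled points of its entry-to-exit segment lies on the
#' lateral (ACJ) side of the cut plane.
#'
#' @param traces a `screw_traces` data frame from [trace_screws()].
#' @param plane a cut plane from [axial_plane_at()].
#' @return integer count.
#' @export
count_contained <- function(traces, plane) {
  n <- 0L
  for (i in seq_len(nrow(traces))) {
    if (traces$in_bone_length[i] < 2) next
    e <- c(traces$entry_x[i], traces$entry_y[i], traces$entry_z[i])
    x <- c(traces$exit_x[i], traces$exit_y[i], traces$exit_z[i])
    s <- seq(0, 1, length.out = 51)
    pts <- outer(1 - s, e) + outer(s, x)
    side <- (pts - matrix(plane$point, 51, 3, byrow = TRUE)) %*% plane$normal
    if (all(side >= 0)) n <- n + 1L
  }
  n
}

# Shoelace area of an ordered planar polygon given as 2-column matrix.
shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

# Does the closed polygon self-intersect (non-adjacent edge crossing)?
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(FALSE)
  seg <- cbind(xy, xy[c(2:n, 1), ])
  crosses <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (crosses(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Area enclosed by the screw exits on the inferior cortex
#'
#' Collects the inferior-cortex exit points in fixture hole order, fits a
#' least-squares plane, projects the points into it, and returns the
#' absolute shoelace area of the hole-order polygon. A self-intersecting
#' ordering falls back to the convex hull (flagged via the `"convex_hull"`
#' attribute). Fewer than 3 exit points give area 0.
#'
#' @param traces a `screw_traces` data frame.
#' @param plate the `plate_model` (defines hole order).
#' @param max_dist_from_acj optional mm cutoff: only exits within this
#'   distance of the ACJ enter the polygon (the primary study value uses 25).
#' @param contained_only optional logical vector (by row of `traces`)
#'   restricting the polygon to fragment-contained screws.
#' @return area in mm^2.
#' @export
covered_area <- function(traces, plate, max_dist_from_acj = NULL,
                         contained_only = NULL) {
  keep <- traces$has_inferior_exit
  if (!is.null(max_dist_from_acj)) {
    keep <- keep & !is.na(traces$dist_from_acj) &
      traces$dist_from_acj <= max_dist_from_acj
  }
  if (!is.null(contained_only)) keep <- keep & contained_only
  idx_order <- order(match(traces$hole_index,
                           vapply(plate$screws, `[[`, integer(1),
                                  "hole_index")))
  tr <- traces[idx_order, , drop = FALSE]
  keep <- keep[idx_order]
  pts <- as.matrix(tr[keep, c("exit_x", "exit_y", "exit_z")])
  if (nrow(pts) < 3) return(structure(0, convex_hull = FALSE))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  basis <- sv$v[, 1:2, drop = FALSE]
  xy <- sweep(pts, 2, ctr) %*% basis
  hull_used <- FALSE
  if (polygon_self_intersects(xy)) {
    hull <- grDevices::chull(xy[, 1], xy[, 2])
    xy <- xy[hull, , drop = FALSE]
    hull_used <- TRUE
  }
  structure(shoelace_area(xy), convex_hull = hull_used)
}

#' Ligament attachment zones involved by a fracture line
#'
#' Returns the coracoclavicular ligament zones whose attachment interval
#' intersects `[0, fracture_distance)` and a Craig-classification hint:
#' fracture lines within 10 mm of the ACJ correspond to Craig type 1/3,
#' larger fragments to type 2B/5 (coracoclavicular ligament involved).
#'
#' @param fracture_distance mm from the ACJ, >= 0.
#' @return list with `zones` (character subset of trapezoid/conoid) and
#'   `craig_hint`.
#' @export
ligament_involvement <- function(fracture_distance) {
  stopifnot(fracture_distance >= 0)
  zones <- character(0)
  if (fracture_distance > ligament_zones$trapezoid[1]) {
    zones <- c(zones, "trapezoid")
  }
  if (fracture_distance > ligament_zones$conoid[1]) {
    zones <- c(zones, "conoid")
  }
  list(zones = zones,
       craig_hint = if (fracture_distance <= 10) "type 1/3 range"
       else "type 2B/5 range (ligament involved)")
}
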