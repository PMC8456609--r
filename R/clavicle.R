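# Parametric clavicle generator and the ISB-inspired clavicle coordinate
# system. Generated bones are left-sided: the lateral (acromial) end sits at
# +Z, anterior is +X, cranial is +Y in the construction coordinates.

#' Parameters of a synthetic clavicle
#'
#' @param length end-to-end bone length, mm (100-200).
#' @param midshaft_diameter mean midshaft diameter, mm (6-20).
#' @param s_curve_amplitude_medial sagitta of the anterior-convex medial bow,
#'   mm; default 10% of length.
#' @param s_curve_amplitude_lateral sagitta of the posterior-convex lateral
#'   bow, mm; default 6% of length.
#' @param lateral_flare_width full anteroposterior width of the flattened
#'   lateral end, mm; default twice the midshaft diameter.
#' @param lateral_end_thickness craniocaudal thickness of the lateral end,
#'   mm; default 0.8 x midshaft diameter.
#' @param cross_section_ellipticity anteroposterior/craniocaudal radius ratio
#'   of the midshaft section.
#' @param mesh_resolution number of axial segments of the lofted surface.
#' @return list of class `clavicle_params`.
#' @export
clavicle_params <- function(length = 148,
                            midshaft_diameter = 11.5,
                            s_curve_amplitude_medial = 0.10 * length,
                            s_curve_amplitude_lateral = 0.06 * length,
                            lateral_flare_width = 2 * midshaft_diameter,
                            lateral_end_thickness = 0.8 * midshaft_diameter,
                            cross_section_ellipticity = 1.2,
                            mesh_resolution = 72) {
  if (length < 100 || length > 200) {
    stop("invalid params: length must be in [100, 200] mm", call. = FALSE)
  }
  if (midshaft_diameter < 6 || midshaft_diameter > 20) {
    stop("invalid params: midshaft_diameter must be in [6, 20] mm",
         call. = FALSE)
  }
  if (s_curve_amplitude_medial < 0 || s_curve_amplitude_lateral < 0) {
    stop("invalid params: bow amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(length = length, midshaft_diameter = midshaft_diameter,
                 s_curve_amplitude_medial = s_curve_amplitude_medial,
                 s_curve_amplitude_lateral = s_curve_amplitude_lateral,
                 lateral_flare_width = lateral_flare_width,
                 lateral_end_thickness = lateral_end_thickness,
                 cross_section_ellipticity = cross_section_ellipticity,
                 mesh_resolution = mesh_resolution),
            class = "clavicle_params")
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# Axial-plane (x over normalized length t) S-shaped centerline: natural cubic
# spline through the two bow apexes and the 55% inflection.
clavicle_centerline <- function(params) {
  am <- params$s_curve_amplitude_medial
  al <- params$s_curve_amplitude_lateral
  stats::splinefun(x = c(0, 0.275, 0.55, 0.775, 1),
                   y = c(0, am, 0, -al, 0), method = "natural")
}

#' Generate one synthetic clavicle surface model
#'
#' Builds a watertight lofted surface: an S-shaped centerline in the axial
#' plane (anterior-convex medial bow, posterior-convex lateral bow),
#' elliptical cross-sections through the shaft, and a widened, flattened
#' super-elliptical lateral end where a plate can seat. Landmarks (most
#' anterior sternoclavicular-end point, most posterior acromial-end point,
#' acromial end-face patch) are emitted from the construction itself. A small
#' seed-keyed smooth modulation (<= 2% of the local radii) individualizes
#' bones beyond pure size scaling. The axial coordinate is calibrated so the
#' length measured along the clavicle frame Z axis matches `params$length`.
#'
#' @param params a [clavicle_params()].
#' @param seed integer; the generator is deterministic in `(params, seed)`.
#' @param id model identifier string.
#' @return list of class `clavicle_model` with `mesh`, `landmarks`, `side`,
#'   `params`, `id`.
#' @export
generate_clavicle <- function(params, seed = 0, id = "clavicle") {
  if (!inherits(params, "clavicle_params")) {
    params <- do.call(clavicle_params, params)
  }
  rs <- local({
    set.seed(as.integer(seed %% 2147483647))
    list(phase = stats::runif(4, 0, 2 * pi),
         amp = stats::runif(4, 0, 0.02))
  })
  n_ax <- max(24L, as.integer(params$mesh_resolution))
  n_rad <- 20L
  L <- params$length
  d <- params$midshaft_diameter
  rho <- params$cross_section_ellipticity
  rx0 <- rho * d / (1 + rho)   # anteroposterior radius at midshaft
  ry0 <- d / (1 + rho)         # craniocaudal radius at midshaft
  xc_fun <- clavicle_centerline(params)

  build <- function(zscale, dscale) {
    tt <- seq(0, 1, length.out = n_ax + 1)
    xc <- xc_fun(tt)
    # radius profiles: medial flare, midshaft, lateral flare + flattening
    med <- 1 + 0.35 * smoothstep((0.16 - tt) / 0.16)
    lat_s <- smoothstep((tt - 0.75) / 0.25)
    rx <- (rx0 * med) * (1 - lat_s) + (params$lateral_flare_width / 2) * lat_s
    ry <- (ry0 * med) * (1 - lat_s) + (params$lateral_end_thickness / 2) * lat_s
    npow <- 2 + 1.5 * lat_s  # ellipse -> flattened super-ellipse
    # smooth individual modulation, fades at both ends so landmarks stay exact
    fade <- smoothstep(tt / 0.08) * smoothstep((1 - tt) / 0.08)
    mod_rx <- 1 + fade * (rs$amp[1] * sin(2 * pi * tt + rs$phase[1]) +
                            rs$amp[2] * sin(4 * pi * tt + rs$phase[2]))
    mod_ry <- 1 + fade * (rs$amp[3] * sin(2 * pi * tt + rs$phase[3]) +
                            rs$amp[4] * sin(6 * pi * tt + rs$phase[4]))
    rx <- rx * mod_rx * dscale
    ry <- ry * mod_ry * dscale
    th <- seq(0, 2 * pi, length.out = n_rad + 1)[-(n_rad + 1)]
    nv_ring <- n_rad * (n_ax + 1)
    verts <- matrix(0, nv_ring + 2, 3)
    for (i in seq_len(n_ax + 1)) {
      e <- 2 / npow[i]
      cx <- rx[i] * sign(cos(th)) * abs(cos(th))^e
      cy <- ry[i] * sign(sin(th)) * abs(sin(th))^e
      rows <- ((i - 1) * n_rad + 1):(i * n_rad)
      verts[rows, ] <- cbind(xc[i] + cx, cy, (tt[i] - 0.5) * L * zscale)
    }
    # end-cap centers: medial (sternal) at index nv_ring+1, lateral +2
    verts[nv_ring + 1, ] <- c(xc[1], 0, -0.5 * L * zscale)
    verts[nv_ring + 2, ] <- c(xc[n_ax + 1], 0, 0.5 * L * zscale)
    faces <- vector("list", n_ax + 2)
    for (i in seq_len(n_ax)) {
      a <- (i - 1) * n_rad + seq_len(n_rad)
      b <- (i - 1) * n_rad + c(seq_len(n_rad - 1) + 1, 1)
      c1 <- a + n_rad
      d1 <- b + n_rad
      # quad (a,b,d1,c1); outward orientation fixed below via volume sign
      faces[[i]] <- rbind(cbind(a, b, d1), cbind(a, d1, c1))
    }
    ring1 <- seq_len(n_rad)
    ringN <- n_ax * n_rad + seq_len(n_rad)
    nxt <- c(seq_len(n_rad - 1) + 1, 1)
    faces[[n_ax + 1]] <- cbind(nv_ring + 1L, ring1[nxt], ring1)      # medial cap
    faces[[n_ax + 2]] <- cbind(nv_ring + 2L, ringN, ringN[nxt])     # lateral cap
    mesh <- clav_mesh(verts, do.call(rbind, faces))
    if (mesh_volume(mesh) < 0) {
      mesh <- clav_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
    }
    n_lat_cap <- nrow(mesh$faces) - n_rad + seq_len(n_rad)
    lat_ring <- mesh$vertices[ringN, , drop = FALSE]
    med_ring <- mesh$vertices[ring1, , drop = FALSE]
    landmarks <- list(
      sc_most_anterior = med_ring[which.max(med_ring[, 1]), ],
      acj_most_posterior = lat_ring[which.min(lat_ring[, 1]), ],
      acj_end_patch = as.integer(n_lat_cap),
      cranial_hint = c(0, 1, 0))
    list(mesh = mesh, landmarks = landmarks)
  }

  # calibrate the axial and radial scales so the measured frame-Z length and
  # midshaft section diameter hit params$length and params$midshaft_diameter
  zscale <- 1
  dscale <- 1
  for (k in 1:4) {
    built <- build(zscale, dscale)
    model <- structure(list(mesh = built$mesh, landmarks = built$landmarks,
                            side = "left", params = params, id = id),
                       class = "clavicle_model")
    meas_l <- measure_length(model)
    meas_d <- measure_midshaft_diameter(model)
    if (abs(meas_l - L) < 0.05 && abs(meas_d - d) < 0.02) break
    zscale <- zscale * L / meas_l
    dscale <- dscale * d / meas_d
  }
  model
}

#' @export
print.clavicle_model <- function(x, ...) {
  cat("<clavicle_model>", x$id, sprintf("(%s side)", x$side), "\n")
  cat(" length param:", signif(x$params$length, 4), "mm, midshaft diameter:",
      signif(x$params$midshaft_diameter, 4), "mm\n")
  print(x$mesh)
  invisible(x)
}

#' Population specification for synthetic clavicles
#'
#' Lengths and midshaft diameters are drawn independently from truncated
#' normal distributions centered at the stated means with
#' sd = (max - min) / 4, truncated to the stated ranges — the simplest
#' distribution consistent with a reported mean and range.
#'
#' @param n number of clavicles.
#' @param length_mean,length_min,length_max mm.
#' @param diameter_mean,diameter_min,diameter_max mm.
#' @param seed integer RNG seed.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n = 10,
                            length_mean = 148, length_min = 132,
                            length_max = 167,
                            diameter_mean = 11.5, diameter_min = 8.9,
                            diameter_max = 13.6,
                            seed = 0) {
  stopifnot(n >= 1,
            length_min <= length_mean, length_mean <= length_max,
            diameter_min <= diameter_mean, diameter_mean <= diameter_max)
  structure(list(n = as.integer(n), length_mean = length_mean,
                 length_min = length_min, length_max = length_max,
                 diameter_mean = diameter_mean, diameter_min = diameter_min,
                 diameter_max = diameter_max, seed = as.integer(seed)),
            class = "population_spec")
}

# Truncated-normal draws by inverse-CDF; mean mu, sd s, truncated to [a, b].
rtruncnorm <- function(n, mu, s, a, b) {
  pa <- stats::pnorm(a, mu, s)
  pb <- stats::pnorm(b, mu, s)
  stats::qnorm(stats::runif(n, pa, pb), mu, s)
}

#' Sample a population of synthetic left clavicles
#'
#' @param spec a [population_spec()].
#' @param mesh_resolution axial segment count passed to each model.
#' @return list of [generate_clavicle()] models, all left-sided.
#' @export
sample_population <- function(spec = population_spec(),
                              mesh_resolution = 72) {
  set.seed(spec$seed)
  sL <- (spec$length_max - spec$length_min) / 4
  sD <- (spec$diameter_max - spec$diameter_min) / 4
  lens <- rtruncnorm(spec$n, spec$length_mean, sL,
                     spec$length_min, spec$length_max)
  dias <- rtruncnorm(spec$n, spec$diameter_mean, sD,
                     spec$diameter_min, spec$diameter_max)
  seeds <- sample.int(2^31 - 1, spec$n)
  lapply(seq_len(spec$n), function(i) {
    generate_clavicle(
      clavicle_params(length = lens[i], midshaft_diameter = dias[i],
                      mesh_resolution = mesh_resolution),
      seed = seeds[i],
      id = sprintf("clav_%02d", i))
  })
}

# ---- clavicle frame and measurements ---------------------------------------

#' Clavicle coordinate system from anatomical landmarks
#'
#' Z connects the most anterior sternoclavicular point to the most posterior
#' acromioclavicular (ACJ) point, pointing laterally toward the ACJ; Y is
#' perpendicular to Z pointing cranially (disambiguated by the stored cranial
#' hint); X = Y x Z points anteriorly. The origin is the midpoint of the two
#' landmark points.
#'
#' @param landmarks list with `sc_most_anterior`, `acj_most_posterior`,
#'   `cranial_hint` (each length-3).
#' @return a [clav_frame()].
#' @export
compute_clavicle_frame <- function(landmarks) {
  sc <- landmarks$sc_most_anterior
  acj <- landmarks$acj_most_posterior
  if (sqrt(sum((acj - sc)^2)) < 50) {
    stop("degenerate landmarks: SC and ACJ points must be >= 50 mm apart",
         call. = FALSE)
  }
  z <- unit(acj - sc)
  hint <- landmarks$cranial_hint
  if (is.null(hint)) {
    stop("landmarks must carry a cranial_hint vector", call. = FALSE)
  }
  yraw <- hint - sum(hint * z) * z
  if (sqrt(sum(yraw^2)) < 1e-9) {
    stop("degenerate landmarks: cranial hint parallel to the long axis",
         call. = FALSE)
  }
  y <- unit(yraw)
  x <- cross(y, z)
  clav_frame(origin = (sc + acj) / 2, axis_x = x, axis_y = y, axis_z = z)
}

#' Clavicular length along the clavicle Z axis
#'
#' Straight-line extent of the mesh vertices projected on the clavicle frame
#' Z axis (the paper's measurement convention is unstated; this end-to-end
#' convention is declared in the methods vignette).
#'
#' @param clavicle a `clavicle_model`.
#' @return length in mm.
#' @export
measure_length <- function(clavicle) {
  fr <- compute_clavicle_frame(clavicle$landmarks)
  zc <- to_frame_coords(fr, clavicle$mesh$vertices)[, 3]
  max(zc) - min(zc)
}

# All intersection points of mesh edges with the plane z = z0 in frame coords.
mesh_section_points <- function(mesh, frame, z0) {
  vc <- to_frame_coords(frame, mesh$vertices)
  f <- mesh$faces
  edges <- unique(rbind(
    cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
    cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
    cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
  za <- vc[edges[, 1], 3] - z0
  zb <- vc[edges[, 2], 3] - z0
  hit <- (za <= 0 & zb > 0) | (zb <= 0 & za > 0)
  if (!any(hit)) return(matrix(0, 0, 3))
  ea <- edges[hit, 1]; eb <- edges[hit, 2]
  s <- za[hit] / (za[hit] - zb[hit])
  vc[ea, , drop = FALSE] + s * (vc[eb, , drop = FALSE] -
                                  vc[ea, , drop = FALSE])
}

#' Midshaft diameter at 50% of the axial extent
#'
#' Sections the mesh with the plane at half the Z extent and returns the mean
#' of the section's anteroposterior (X) and craniocaudal (Y) extents.
#'
#' @param clavicle a `clavicle_model`.
#' @return diameter in mm.
#' @export
measure_midshaft_diameter <- function(clavicle) {
  fr <- compute_clavicle_frame(clavicle$landmarks)
  zc <- to_frame_coords(fr, clavicle$mesh$vertices)[, 3]
  z0 <- (max(zc) + min(zc)) / 2
  pts <- mesh_section_points(clavicle$mesh, fr, z0)
  if (nrow(pts) == 0) stop("empty section at the midshaft", call. = FALSE)
  mean(c(max(pts[, 1]) - min(pts[, 1]), max(pts[, 2]) - min(pts[, 2])))
}

#' Transverse cut plane at a given distance from the ACJ
#'
#' The plane normal is the clavicle Z axis; the plane point lies
#' `distance_from_acj` mm medial to the most posterior ACJ landmark. The
#' lateral fragment is the half-space on the ACJ side (larger frame Z).
#'
#' @param clavicle a `clavicle_model`.
#' @param distance_from_acj mm, >= 0.
#' @return list with `point`, `normal` (world coordinates) and `frame`.
#' @export
axial_plane_at <- function(clavicle, distance_from_acj) {
  if (distance_from_acj < 0) {
    stop("position out of range: distance must be >= 0", call. = FALSE)
  }
  if (distance_from_acj > measure_length(clavicle)) {
    stop("position out of range: beyond the clavicle length", call. = FALSE)
  }
  fr <- compute_clavicle_frame(clavicle$landmarks)
  list(point = clavicle$landmarks$acj_most_posterior - fr$z * distance_from_acj,
       normal = fr$z, frame = fr)
}

#' Mirror a clavicle model across the sagittal plane (right <-> left)
#'
#' @param clavicle a `clavicle_model`.
#' @param plane_normal mirror plane normal (default the world X axis).
#' @return the mirrored `clavicle_model` with flipped `side`.
#' @export
mirror_clavicle <- function(clavicle, plane_normal = c(1, 0, 0)) {
  lm <- clavicle$landmarks
  n <- unit(plane_normal)
  lm$sc_most_anterior <- mirror_points(lm$sc_most_anterior, n)
  lm$acj_most_posterior <- mirror_points(lm$acj_most_posterior, n)
  lm$cranial_hint <- {
    h <- lm$cranial_hint - 2 * sum(lm$cranial_hint * n) * n
    h
  }
  structure(list(mesh = mirror_mesh(clavicle$mesh, n),
                 landmarks = lm,
                 side = if (clavicle$side == "left") "right" else "left",
                 params = clavicle$params, id = clavicle$id),
            class = "clavicle_model")
}

#' Apply a rigid transform to a clavicle model (mesh and landmarks)
#' @param clavicle a `clavicle_model`.
#' @param tf a [rigid_transform()].
#' @return the transformed `clavicle_model`.
#' @export
transform_clavicle <- function(clavicle, tf) {
  lm <- clavicle$landmarks
  lm$sc_most_anterior <- apply_transform(tf, lm$sc_most_anterior)
  lm$acj_most_posterior <- apply_transform(tf, lm$acj_most_posterior)
  lm$cranial_hint <- apply_transform(tf, lm$cranial_hint, direction = TRUE)
  structure(list(mesh = clav_mesh(apply_transform(tf, clavicle$mesh$vertices),
                                  clavicle$mesh$faces),
                 landmarks = lm, side = clavicle$side,
                 params = clavicle$params, id = clavicle$id),
            class = "clavicle_model")
}

#' Write a clavicle model as STL plus a JSON landmark sidecar
#' @param clavicle a `clavicle_model`.
#' @param stl_path STL output path; sidecar written next to it as `.json`.
#' @param ascii passed to [write_stl()].
#' @export
write_clavicle <- function(clavicle, stl_path, ascii = TRUE) {
  write_stl(clavicle$mesh, stl_path, ascii = ascii)
  side_path <- sub("\\.stl$", ".json", stl_path, ignore.case = TRUE)
  lm <- clavicle$landmarks
  jsonlite::write_json(
    list(id = clavicle$id, side = clavicle$side,
         sc_most_anterior = lm$sc_most_anterior,
         acj_most_posterior = lm$acj_most_posterior,
         cranial_hint = lm$cranial_hint,
         acj_end_patch = lm$acj_end_patch),
    side_path, auto_unbox = TRUE, digits = NA)
  invisible(c(stl_path, side_path))
}

#' Read a clavicle model from STL + JSON landmark sidecar
#' @param stl_path STL file path (sidecar expected at the same stem `.json`).
#' @return a `clavicle_model`.
#' @export
read_clavicle <- function(stl_path) {
  mesh <- read_stl(stl_path)
  side_path <- sub("\\.stl$", ".json", stl_path, ignore.case = TRUE)
  meta <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  structure(list(
    mesh = mesh,
    landmarks = list(sc_most_anterior = as.numeric(meta$sc_most_anterior),
                     acj_most_posterior = as.numeric(meta$acj_most_posterior),
                     cranial_hint = as.numeric(meta$cranial_hint),
                     acj_end_patch = as.integer(meta$acj_end_patch)),
    side = meta$side, params = NULL, id = meta$id),
    class = "clavicle_model")
}
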