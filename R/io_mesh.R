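# STL and PLY readers/writers for clav_mesh objects.
# STL stores one triangle per facet with no shared vertices; on read,
# coincident vertices (within 1e-6 mm after float32 round-trip) are merged so
# watertight connectivity survives a round trip.

#' Write a mesh as STL
#'
#' @param mesh a [clav_mesh()].
#' @param path output file path.
#' @param ascii write ASCII STL (`TRUE`) or binary STL (`FALSE`).
#' @export
write_stl <- function(mesh, path, ascii = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid clavsim", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid clavsim", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("clavsim binary STL", width = 80, flag = "-"))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary, auto-detected)
#'
#' @param path STL file path.
#' @param merge_tol vertices closer than this (mm) are merged.
#' @return a [clav_mesh()].
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  head <- readBin(path, "raw", n = 84)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") && {
    # binary files may also start with "solid"; check facet keyword in text
    txt <- suppressWarnings(readLines(path, n = 3))
    any(grepl("facet|endsolid", txt))
  }
  if (is_ascii) {
    lines <- readLines(path)
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    coords <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  merge_triangle_soup(coords, merge_tol)
}

merge_triangle_soup <- function(coords, tol) {
  key <- apply(round(coords / tol), 1, paste, collapse = "_")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  clav_mesh(verts, faces[keep, , drop = FALSE])
}

#' Write a mesh as ASCII PLY
#' @param mesh a [clav_mesh()].
#' @param path output file path.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path PLY file path.
#' @return a [clav_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2])) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  start <- which(lines == "end_header")[1]
  vdat <- do.call(rbind, lapply(strsplit(lines[(start + 1):(start + nv)], "\\s+"),
                                function(x) as.numeric(x[1:3])))
  fdat <- do.call(rbind, lapply(
    strsplit(lines[(start + nv + 1):(start + nv + nf)], "\\s+"),
    function(x) as.integer(x[2:4]) + 1L))
  clav_mesh(vdat, fdat)
}
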