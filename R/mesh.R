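#' Triangle surface mesh
#'
#' Vertices in world mm plus a triangle index list, optionally carrying a
#' per-vertex scalar (e.g. a distance map).
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param scalars optional length-N per-vertex values.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, scalars = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(scalars) && length(scalars) != nrow(vertices))
    stop("scalars must have one value per vertex")
  structure(list(vertices = vertices, faces = faces, scalars = scalars),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$scalars))
    cat(sprintf(", scalars in [%.4g, %.4g]", min(x$scalars), max(x$scalars)))
  cat("\n")
  invisible(x)
}

#' Weld duplicated vertices
#'
#' Merges vertices closer than `tol` (by coordinate quantization on a grid of
#' pitch `tol`) and drops degenerate faces. STL files store each triangle
#' corner independently; welding restores shared vertices.
#' @param mesh a [triangle_mesh].
#' @param tol welding tolerance in mm.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  key <- paste(round(mesh$vertices[, 1] / tol), round(mesh$vertices[, 2] / tol),
               round(mesh$vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v <- mesh$vertices[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  good <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  triangle_mesh(v, f[good, , drop = FALSE],
                if (is.null(mesh$scalars)) NULL else mesh$scalars[first])
}

#' Edge census: is the mesh closed?
#'
#' A closed (watertight) mesh has every undirected edge shared by exactly two
#' faces.
#' @param mesh a [triangle_mesh].
#' @return list with `closed` (logical), `boundary_edges` and
#'   `nonmanifold_edges` counts.
#' @export
edge_census <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  list(closed = all(cnt == 2L),
       boundary_edges = sum(cnt == 1L),
       nonmanifold_edges = sum(cnt > 2L))
}

#' Enclosed volume of a closed mesh
#'
#' Signed tetrahedron sum (divergence theorem). Orientation is auto-corrected
#' so the returned volume is non-negative; an open mesh is an error.
#' @param mesh a closed [triangle_mesh].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  ec <- edge_census(mesh)
  if (!ec$closed)
    stop(sprintf("mesh is not closed (%d boundary edges, %d non-manifold edges)",
                 ec$boundary_edges, ec$nonmanifold_edges))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
           a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
           a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  abs(s)
}

#' Centroid of the solid enclosed by a closed mesh
#' @param mesh a closed, consistently oriented [triangle_mesh].
#' @return length-3 world point (mm).
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol6 <- sum(det6)
  if (abs(vol6) < 1e-12) return(colMeans(v))
  ctr <- colSums(((a + b + c_) / 4) * det6) / vol6
  as.numeric(ctr)
}

#' Apply a rigid transform to a mesh
#' @param mesh a [triangle_mesh].
#' @param t a [rigid_transform].
#' @export
transform_mesh <- function(mesh, t) {
  triangle_mesh(transform_points(t, mesh$vertices), mesh$faces, mesh$scalars)
}

#' Read a stereolithography (STL) surface file
#'
#' Detects binary vs ascii automatically. Triangle corners are welded into
#' shared vertices within `tol` mm.
#' @param path file path.
#' @param tol vertex welding tolerance in mm.
#' @return A [triangle_mesh].
#' @export
read_stl <- function(path, tol = 1e-6) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  if (length(head) < 80) stop("not an STL file (truncated header): ", path)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(n) == 1 && !is.na(n) && fsize == 84 + 50 * as.numeric(n)
  if (is_binary) {
    raw <- readBin(con, "raw", 50 * n)
    m <- matrix(raw, nrow = 50)
    fl <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric", 12 * n,
                  size = 4, endian = "little")
    tri <- matrix(fl, nrow = n, byrow = TRUE)  # n x 12: normal, v1, v2, v3
    verts <- matrix(NA_real_, 3 * n, 3)
    verts[seq(1, 3 * n, 3), ] <- tri[, 4:6, drop = FALSE]
    verts[seq(2, 3 * n, 3), ] <- tri[, 7:9, drop = FALSE]
    verts[seq(3, 3 * n, 3), ] <- tri[, 10:12, drop = FALSE]
    faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    if (!any(grepl("^\\s*solid", txt[1])) || !any(grepl("vertex", txt)))
      stop("not an STL file: ", path)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) %% 3 != 0) stop("malformed ascii STL: vertex count not a multiple of 3")
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    if (anyNA(verts)) stop("malformed ascii STL: non-numeric vertex")
    faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  }
  weld_vertices(triangle_mesh(verts, faces), tol = tol)
}

#' Write a mesh as STL
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  n <- nrow(f)
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    block <- t(cbind(nrm, a, b, c_))  # 12 floats per face, column-major
    fl <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    out <- matrix(as.raw(0), 50, n)
    out[1:48, ] <- matrix(fl, 48, n)
    writeBin(as.vector(out), con)
  } else {
    lines <- character(7 * n + 2)
    lines[1] <- "solid erupt3d"
    for (i in seq_len(n)) {
      o <- 1 + (i - 1) * 7
      lines[o + 1] <- sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3])
      lines[o + 2] <- "  outer loop"
      lines[o + 3] <- sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3])
      lines[o + 4] <- sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3])
      lines[o + 5] <- sprintf("    vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3])
      lines[o + 6] <- "  endloop"
      lines[o + 7] <- "endfacet"
    }
    lines[7 * n + 2] <- "endsolid erupt3d"
    writeLines(lines, path)
  }
  invisible(path)
}
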