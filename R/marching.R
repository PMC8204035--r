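# Isosurfacing by marching tetrahedra: every grid cube is cut into the six
# Kuhn tetrahedra sharing its main diagonal (a translation-invariant
# decomposition, so shared faces agree between neighbouring cubes and the
# surface is watertight by construction). Iso-crossing vertices are placed by
# linear interpolation of the field along the grid edge; on a binary 0/1
# field at level 0.5 this reduces to the edge midpoint.

# Corner offsets of a cube, corner ids 1..8
.mt_corner_offsets <- cbind(
  c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
  c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
  c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

# Six tetrahedra around the 1-7 diagonal (corner ids into .mt_corner_offsets)
.mt_tets <- rbind(
  c(1L, 2L, 3L, 7L),
  c(1L, 3L, 4L, 7L),
  c(1L, 4L, 8L, 7L),
  c(1L, 8L, 5L, 7L),
  c(1L, 5L, 6L, 7L),
  c(1L, 6L, 2L, 7L))

# Triangle table: for each of the 16 inside-patterns of a tet's 4 corners,
# a matrix with one row per triangle; each row holds 3 edges as (corner,
# corner) pairs: (p1, q1, p2, q2, p3, q3).
.mt_tri_table <- local({
  tab <- vector("list", 16)
  for (case in 0:15) {
    bits <- as.integer(intToBits(case))[1:4]
    ins <- which(bits == 1L)
    outs <- which(bits == 0L)
    if (length(ins) == 0 || length(ins) == 4) {
      tab[[case + 1]] <- matrix(integer(0), 0, 6)
    } else if (length(ins) == 1) {
      tab[[case + 1]] <- matrix(c(ins, outs[1], ins, outs[2], ins, outs[3]), 1, 6)
    } else if (length(ins) == 3) {
      tab[[case + 1]] <- matrix(c(ins[1], outs, ins[2], outs, ins[3], outs), 1, 6)
    } else {
      i1 <- ins[1]; i2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
      # quad e11 e12 e22 e21 (a planar Varignon parallelogram), split in two
      tab[[case + 1]] <- rbind(c(i1, o1, i1, o2, i2, o2),
                               c(i1, o1, i2, o2, i2, o1))
    }
  }
  tab
})

# For orientation: representative inside and outside corner of a tet case
.mt_inout <- function(cs) {
  bits <- as.integer(intToBits(cs))[1:4]
  c(which(bits == 1L)[1], which(bits == 0L)[1])
}

#' Extract an iso-surface from a scalar volume (marching tetrahedra)
#'
#' Returns the closed surface of the region where the field exceeds `level`.
#' The volume is padded by one below-level voxel so the surface always
#' closes; vertex positions are linearly interpolated along grid edges.
#'
#' @param vol an [image_volume] (scalar field).
#' @param level iso level.
#' @param keep_largest keep only the largest 6-connected above-level
#'   component.
#' @return A closed [triangle_mesh] in world mm.
#' @export
iso_surface <- function(vol, level, keep_largest = TRUE) {
  stopifnot(inherits(vol, "image_volume"))
  field <- vol$data
  m <- field > level
  if (!any(m)) stop("empty selection: no voxels above the iso level")
  d <- dim(field)
  if (keep_largest) {
    lab <- .label_components(as.logical(m), as.integer(d))
    if (attr(lab, "n_components") > 1L) {
      counts <- tabulate(lab, attr(lab, "n_components"))
      drop <- array(lab != 0L & lab != which.max(counts), d)
      # demote non-largest components just below the level
      field[drop] <- level - max(abs(level), 1) * 1e-3
      m[drop] <- FALSE
    }
  }
  dp <- d + 2L
  pad_val <- level - max(abs(level), 1)
  fp <- array(pad_val, dp)
  fp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  mp <- array(FALSE, dp)
  mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  D1 <- dp[1]; D2 <- dp[2]
  nb <- dp - 1L
  base <- cbind(rep.int(seq_len(nb[1]), nb[2] * nb[3]),
                rep.int(rep(seq_len(nb[2]), each = nb[1]), nb[3]),
                rep(seq_len(nb[3]), each = nb[1] * nb[2]))
  node_id <- function(ijk) ijk[, 1] + (ijk[, 2] - 1L) * D1 + (ijk[, 3] - 1L) * D1 * D2
  vnum <- array(0L, dp); vnum[mp] <- 1L
  s <- array(0L, nb)
  for (ci in 1:8) {
    off <- .mt_corner_offsets[ci, ]
    s <- s + vnum[(1 + off[1]):(nb[1] + off[1]),
                  (1 + off[2]):(nb[2] + off[2]),
                  (1 + off[3]):(nb[3] + off[3])]
  }
  active <- which(s > 0L & s < 8L)
  if (length(active) == 0) stop("empty selection: no surface")
  ab <- base[active, , drop = FALSE]
  corner_ids <- matrix(0L, length(active), 8)
  for (ci in 1:8)
    corner_ids[, ci] <- node_id(sweep(ab, 2, .mt_corner_offsets[ci, ], "+"))
  vals <- matrix(vnum[corner_ids], nrow(corner_ids), 8)

  tris <- vector("list", 6)
  for (tt in 1:6) {
    tc <- .mt_tets[tt, ]
    tn <- corner_ids[, tc, drop = FALSE]
    tv <- vals[, tc, drop = FALSE]
    case <- tv[, 1] + 2L * tv[, 2] + 4L * tv[, 3] + 8L * tv[, 4]
    out <- vector("list", 16)
    for (cs in 1:14) {
      rows <- which(case == cs)
      if (length(rows) == 0) next
      tmpl <- .mt_tri_table[[cs + 1]]
      io <- .mt_inout(cs)
      per <- vector("list", nrow(tmpl))
      for (r in seq_len(nrow(tmpl))) {
        e <- tmpl[r, ]
        per[[r]] <- cbind(tn[rows, e[1]], tn[rows, e[2]],
                          tn[rows, e[3]], tn[rows, e[4]],
                          tn[rows, e[5]], tn[rows, e[6]],
                          tn[rows, io[1]], tn[rows, io[2]])
      }
      out[[cs + 1]] <- do.call(rbind, per)
    }
    tris[[tt]] <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  }
  tris <- do.call(rbind, tris)
  if (is.null(tris) || nrow(tris) == 0) stop("empty selection: no surface")

  node_xyz <- function(id) cbind((id - 1) %% D1 + 1,
                                 ((id - 1) %/% D1) %% D2 + 1,
                                 (id - 1) %/% (D1 * D2) + 1)
  Nn <- as.numeric(D1) * D2 * dp[3]
  ekey <- function(a, b) pmin(a, b) + pmax(a, b) * Nn
  keys <- cbind(ekey(tris[, 1], tris[, 2]), ekey(tris[, 3], tris[, 4]),
                ekey(tris[, 5], tris[, 6]))
  uk <- unique(as.vector(keys))
  vid <- matrix(match(as.vector(keys), uk), ncol = 3)
  amin <- uk %% Nn; amax <- uk %/% Nn
  # interpolated iso-crossing along each unique edge (clamped away from the
  # end nodes so coincident vertices cannot arise)
  va <- fp[amin]; vb <- fp[amax]
  frac <- (level - va) / (vb - va)
  frac <- pmin(pmax(frac, 1e-6), 1 - 1e-6)
  pa <- node_xyz(amin); pb <- node_xyz(amax)
  vpos <- pa + frac * (pb - pa)

  p1 <- vpos[vid[, 1], , drop = FALSE]
  p2 <- vpos[vid[, 2], , drop = FALSE]
  p3 <- vpos[vid[, 3], , drop = FALSE]
  n <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
             (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
             (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  ref <- node_xyz(tris[, 8]) - node_xyz(tris[, 7])  # inside -> outside
  flip <- rowSums(n * ref) < 0
  tmp <- vid[flip, 2]
  vid[flip, 2] <- vid[flip, 3]
  vid[flip, 3] <- tmp

  world <- voxel_to_world(vol, vpos - 1)  # padded node (2,2,2) is voxel (1,1,1)
  triangle_mesh(world, vid)
}

#' Surface a binary mask
#'
#' The 0.5-level surface of a binary volume: [iso_surface] on the 0/1 field,
#' where linear interpolation puts every vertex at a grid-edge midpoint.
#' Only the largest 6-connected foreground component is surfaced.
#'
#' @param mask an [image_volume] with logical or 0/1 data.
#' @param keep_largest keep only the largest connected component (default).
#' @return A closed [triangle_mesh] in world mm.
#' @export
mesh_from_mask <- function(mask, keep_largest = TRUE) {
  stopifnot(inherits(mask, "image_volume"))
  mv <- mask
  mv$data <- array(as.numeric(mask$data != 0), dim(mask$data))
  iso_surface(mv, 0.5, keep_largest = keep_largest)
}
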