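#' 3D image volume
#'
#' A scalar 3D grid with physical geometry: voxel spacing (mm), origin (mm,
#' the world position of the center of voxel [1,1,1]) and axis direction
#' cosines. The world position of voxel (i, j, k) (1-based) is
#' `origin + direction %*% (spacing * (c(i,j,k) - 1))`. All module interfaces
#' exchange mm, never voxel indices.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing length-3 positive voxel size in mm.
#' @param origin length-3 world position of the first voxel center (mm).
#' @param direction 3x3 orthonormal direction-cosine matrix (columns = world
#'   directions of the array axes).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("each axis must have at least 2 voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive mm values")
  direction <- as.matrix(direction)
  if (sqrt(sum((crossprod(direction) - diag(3))^2)) > 1e-6)
    stop("direction matrix not orthonormal")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image volume %d x %d x %d, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world` maps 1-based (possibly fractional) voxel indices to world
#' mm; `world_to_voxel` is its inverse.
#' @param vol an [image_volume].
#' @param idx N x 3 matrix of 1-based voxel indices.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*") %*% t(vol$direction), 2, vol$origin, "+")
}

#' @rdname voxel_to_world
#' @param pts N x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, vol$origin, "-") %*% vol$direction, 2, vol$spacing, "/") + 1
}

#' World coordinates of every voxel center
#' @param vol an [image_volume].
#' @return dim(vol) x 3 matrix, voxels in array (column-major) order.
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(rep.int(seq_len(d[1]), d[2] * d[3]),
               rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  voxel_to_world(vol, idx)
}

#' Axis-aligned region of interest box in world mm
#' @param lower,upper length-3 corners in mm, `lower < upper` componentwise.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3 || length(upper) != 3 || any(lower >= upper))
    stop("ROI box needs lower < upper componentwise")
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

#' Crop a volume to an ROI box
#'
#' Keeps exactly the voxels whose centers lie inside the box (half-open on the
#' upper faces: lower <= center < upper). The origin is updated so that every
#' kept voxel keeps its physical coordinates. Requires an axis-aligned
#' direction matrix (the only case where an ROI box maps to an index box).
#'
#' @param vol an [image_volume].
#' @param roi a [roi_box] in world mm.
#' @export
crop_to_roi <- function(vol, roi) {
  stopifnot(inherits(vol, "image_volume"), inherits(roi, "roi_box"))
  if (any(abs(vol$direction - diag(3)) > 1e-9))
    stop("crop_to_roi requires an identity direction matrix")
  d <- dim(vol$data)
  keep <- vector("list", 3)
  for (ax in 1:3) {
    coord <- vol$origin[ax] + vol$spacing[ax] * (seq_len(d[ax]) - 1)
    keep[[ax]] <- which(coord >= roi$lower[ax] & coord < roi$upper[ax])
    if (length(keep[[ax]]) == 0)
      stop("ROI does not intersect the volume along axis ", ax)
  }
  sub <- vol$data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  new_origin <- voxel_to_world(vol, matrix(c(keep[[1]][1], keep[[2]][1], keep[[3]][1]), 1))[1, ]
  image_volume(sub, spacing = vol$spacing, origin = new_origin,
               direction = vol$direction)
}

#' Mean-pool downsampling by an integer factor per axis
#'
#' Used to build the multi-resolution pyramid for registration. Each output
#' voxel is the mean of a `f1 x f2 x f3` block; trailing voxels that do not
#' fill a block are dropped. Spacing is scaled and the origin shifted to the
#' center of the first block so world coordinates are preserved.
#' @param vol an [image_volume].
#' @param factor integer scalar or length-3 vector of shrink factors.
#' @export
downsample_volume <- function(vol, factor) {
  f <- rep(as.integer(factor), length.out = 3)
  if (any(f < 1)) stop("shrink factors must be >= 1")
  if (all(f == 1L)) return(vol)
  d <- dim(vol$data)
  nd <- d %/% f
  if (any(nd < 2)) stop("volume too small for shrink factor")
  a <- vol$data[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]), drop = FALSE]
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(f), prod(nd))
  a <- array(colMeans(a), nd)
  new_origin <- vol$origin + as.numeric(vol$direction %*% (vol$spacing * (f - 1) / 2))
  image_volume(a, spacing = vol$spacing * f, origin = new_origin,
               direction = vol$direction)
}
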