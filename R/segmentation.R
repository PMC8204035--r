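#' Livewire cost weights
#'
#' Per-pixel local cost `w_g * (1 - g/g_max) + w_z * z + w_d * d` where `g` is
#' the Sobel gradient magnitude, `z` a binary Laplacian zero-crossing term
#' (0 on zero-crossing pixels, 1 elsewhere) and `d` a gradient-direction
#' incoherence term in [0, 1] (0 where the local gradient direction is
#' spatially coherent, as along a clean edge). Default weights 0.43 / 0.43 /
#' 0.14 follow common livewire practice.
#' @param w_g,w_z,w_d non-negative weights, sum > 0.
#' @export
livewire_params <- function(w_g = 0.43, w_z = 0.43, w_d = 0.14) {
  if (any(c(w_g, w_z, w_d) < 0) || w_g + w_z + w_d <= 0)
    stop("livewire weights must be non-negative with positive sum")
  structure(list(w_g = w_g, w_z = w_z, w_d = w_d), class = "livewire_params")
}

.shift2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  out[] <- m[rs, cs]
  out
}

#' Livewire local cost image
#'
#' @param slice 2D numeric matrix of intensities.
#' @param params a [livewire_params].
#' @return 2D matrix of per-pixel local costs; low cost on strong edges.
#' @export
livewire_cost <- function(slice, params = livewire_params()) {
  slice <- as.matrix(slice)
  if (nrow(slice) < 3 || ncol(slice) < 3) stop("slice must be at least 3 x 3")
  # Sobel gradient
  gx <- (.shift2(slice, 1, -1) + 2 * .shift2(slice, 1, 0) + .shift2(slice, 1, 1)) -
    (.shift2(slice, -1, -1) + 2 * .shift2(slice, -1, 0) + .shift2(slice, -1, 1))
  gy <- (.shift2(slice, -1, 1) + 2 * .shift2(slice, 0, 1) + .shift2(slice, 1, 1)) -
    (.shift2(slice, -1, -1) + 2 * .shift2(slice, 0, -1) + .shift2(slice, 1, -1))
  g <- sqrt(gx^2 + gy^2)
  gmax <- max(g)
  if (gmax <= 0) {
    warning("constant slice: uniform livewire cost")
    f_g <- matrix(1, nrow(slice), ncol(slice))
  } else f_g <- 1 - g / gmax
  # Laplacian zero crossings (4-neighbour Laplacian)
  lap <- .shift2(slice, 1, 0) + .shift2(slice, -1, 0) +
    .shift2(slice, 0, 1) + .shift2(slice, 0, -1) - 4 * slice
  f_z <- matrix(1, nrow(slice), ncol(slice))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ln <- .shift2(lap, d[1], d[2])
    zc <- (lap == 0 & ln != 0) | (lap * ln < 0 & abs(lap) <= abs(ln))
    f_z[zc] <- 0
  }
  # gradient-direction coherence over a 3x3 neighbourhood
  box <- function(m) {
    s <- matrix(0, nrow(m), ncol(m))
    for (dr in -1:1) for (dc in -1:1) s <- s + .shift2(m, dr, dc)
    s
  }
  sx <- box(gx); sy <- box(gy); sg <- box(g)
  coher <- ifelse(sg > 0, sqrt(sx^2 + sy^2) / sg, 0)
  f_d <- 1 - pmin(coher, 1)
  params$w_g * f_g + params$w_z * f_z + params$w_d * f_d
}

#' Minimum-cost livewire path between two pixels
#'
#' Dijkstra shortest path on the 8-connected pixel graph; a step between
#' neighbouring pixels costs `len * (cost_from + cost_to) / 2` with
#' `len = sqrt(2)` for diagonal steps.
#' @param cost 2D cost matrix (from [livewire_cost]).
#' @param seed,target length-2 (row, col) pixel coordinates, 1-based.
#' @return matrix of path pixels (row, col) from seed to target inclusive,
#'   with the cumulative cost in `attr(, "cost")`.
#' @export
livewire_path <- function(cost, seed, target) {
  cost <- as.matrix(cost)
  seed <- as.integer(seed); target <- as.integer(target)
  if (any(seed < 1) || any(target < 1) || seed[1] > nrow(cost) ||
      target[1] > nrow(cost) || seed[2] > ncol(cost) || target[2] > ncol(cost))
    stop("seed/target outside the image")
  if (all(seed == target)) {
    out <- matrix(seed, 1, 2)
    attr(out, "cost") <- 0
    return(out)
  }
  r <- .dijkstra_grid(cost, seed - 1L, target - 1L)
  out <- r$path
  attr(out, "cost") <- r$cost
  out
}

#' Closed slice contour
#'
#' A closed simple polygon on one slice of a volume, in in-plane mm
#' coordinates.
#' @param axis `"axial"` (z slices), `"coronal"` (y) or `"sagittal"` (x).
#' @param index 1-based slice index along that axis.
#' @param points N x 2 matrix of in-plane mm coordinates (closed implicitly;
#'   do not repeat the first point).
#' @export
slice_contour <- function(axis = c("axial", "coronal", "sagittal"), index, points) {
  axis <- match.arg(axis)
  points <- matrix(as.numeric(points), ncol = 2)
  points <- points[!duplicated(points) | seq_len(nrow(points)) == 1, , drop = FALSE]
  if (nrow(points) < 3) stop("a contour needs at least 3 distinct points")
  if (.polygon_self_intersects(points)) stop("contour polygon is self-intersecting")
  if (.shoelace(points) < 0) points <- points[nrow(points):1, , drop = FALSE]
  structure(list(axis = axis, index = as.integer(index), points = points),
            class = "slice_contour")
}

.shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  # pairs of non-adjacent edges
  ij <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  if (nrow(ij) == 0) return(FALSE)
  p1 <- a[ij[, 1], , drop = FALSE]; p2 <- b[ij[, 1], , drop = FALSE]
  p3 <- a[ij[, 2], , drop = FALSE]; p4 <- b[ij[, 2], , drop = FALSE]
  cr <- function(o, u, v)
    (u[, 1] - o[, 1]) * (v[, 2] - o[, 2]) - (u[, 2] - o[, 2]) * (v[, 1] - o[, 1])
  d1 <- cr(p3, p4, p1); d2 <- cr(p3, p4, p2)
  d3 <- cr(p1, p2, p3); d4 <- cr(p1, p2, p4)
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
        ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Assemble livewire path segments into a closed slice contour
#'
#' Chains pixel-path segments head-to-tail (flipping segments where needed),
#' converts pixel coordinates to in-plane mm and returns a [slice_contour].
#' Orientation is normalized to counter-clockwise, so segment order/direction
#' does not matter.
#'
#' @param segments list of pixel-path matrices (each N x 2, row/col), as from
#'   [livewire_path], chaining head-to-tail around the structure.
#' @param slice_meta list with `axis`, `index`, `origin` (length-2 mm) and
#'   `spacing` (length-2 mm/pixel) of the slice plane; see [get_slice].
#' @export
close_contour <- function(segments, slice_meta) {
  if (length(segments) < 1) stop("no segments")
  chain <- segments[[1]]
  for (s in segments[-1]) {
    if (all(s[1, ] == chain[nrow(chain), ])) {
    } else if (all(s[nrow(s), ] == chain[nrow(chain), ])) {
      s <- s[nrow(s):1, , drop = FALSE]
    } else if (all(s[nrow(s), ] == chain[1, ])) {
      chain <- chain[nrow(chain):1, , drop = FALSE]
      s <- s[nrow(s):1, , drop = FALSE]
    } else if (all(s[1, ] == chain[1, ])) {
      chain <- chain[nrow(chain):1, , drop = FALSE]
    } else stop("segments do not chain head-to-tail")
    chain <- rbind(chain, s[-1, , drop = FALSE])
  }
  if (all(chain[1, ] == chain[nrow(chain), ]))
    chain <- chain[-nrow(chain), , drop = FALSE]
  pts <- cbind(slice_meta$origin[1] + (chain[, 1] - 1) * slice_meta$spacing[1],
               slice_meta$origin[2] + (chain[, 2] - 1) * slice_meta$spacing[2])
  slice_contour(slice_meta$axis, slice_meta$index, pts)
}

#' Extract a 2D slice and its in-plane geometry
#'
#' @param vol an [image_volume] with identity direction.
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param index slice index along that axis.
#' @return list with `image` (2D matrix), `axis`, `index`, `origin`,
#'   `spacing` (in-plane, mm). For axial slices the in-plane axes are (x, y),
#'   for coronal (x, z), for sagittal (y, z).
#' @export
get_slice <- function(vol, axis = c("axial", "coronal", "sagittal"), index) {
  axis <- match.arg(axis)
  if (any(abs(vol$direction - diag(3)) > 1e-9))
    stop("slicing requires an identity direction matrix")
  ax <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  inplane <- setdiff(1:3, ax)
  img <- switch(ax, vol$data[index, , ], vol$data[, index, ], vol$data[, , index])
  list(image = img, axis = axis, index = as.integer(index),
       origin = vol$origin[inplane], spacing = vol$spacing[inplane])
}

# rasterize a closed polygon (mm) onto a slice grid -> logical matrix
.rasterize_contour <- function(points, origin, spacing, dims) {
  u <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  v <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  g <- cbind(rep(u, times = dims[2]), rep(v, each = dims[1]))
  bnd <- rbind(points, points[1, ])
  matrix(mgcv::in.out(bnd, g), dims[1], dims[2])
}

# signed distance field of a mask in pixels (negative inside), via EBImage
.sdf <- function(mask) {
  m <- EBImage::Image(mask * 1)
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(EBImage::Image(1 - mask)))
  dout - din
}

#' Interpolate stacked slice contours into a binary volume
#'
#' Shape-based interpolation: each axial contour is rasterized and converted
#' to a signed distance field on its slice; distance fields are linearly
#' interpolated between neighbouring contour slices along z, and voxels with
#' non-positive interpolated distance become foreground. Slices beyond the
#' first/last contour stay empty. Coronal and sagittal contours act as carving
#' constraints: on the planes they cover, foreground must fall inside them.
#'
#' @param contours list of [slice_contour]s; at least two axial contours on
#'   distinct slices.
#' @param target an [image_volume] providing the output grid (data ignored).
#' @return binary [image_volume] (0/1).
#' @export
interpolate_contours <- function(contours, target) {
  stopifnot(inherits(target, "image_volume"))
  if (any(abs(target$direction - diag(3)) > 1e-9))
    stop("contour interpolation requires an identity direction matrix")
  ax <- Filter(function(cc) cc$axis == "axial", contours)
  if (length(ax) < 2)
    stop("need at least two axial contours to interpolate between")
  ks <- vapply(ax, function(cc) cc$index, 0L)
  if (anyDuplicated(ks)) stop("multiple axial contours on the same slice")
  ord <- order(ks)
  ax <- ax[ord]; ks <- ks[ord]
  d <- dim(target$data)
  inplane_dims <- d[1:2]
  sdfs <- lapply(ax, function(cc) {
    m <- .rasterize_contour(cc$points, target$origin[1:2], target$spacing[1:2],
                            inplane_dims)
    .sdf(m)
  })
  out <- array(FALSE, d)
  for (i in seq_len(length(ax) - 1)) {
    k0 <- ks[i]; k1 <- ks[i + 1]
    for (k in k0:k1) {
      w <- if (k1 == k0) 0 else (k - k0) / (k1 - k0)
      sdf <- (1 - w) * sdfs[[i]] + w * sdfs[[i + 1]]
      out[, , k] <- sdf <= 0
    }
  }
  # carving constraints from the orthogonal views
  for (cc in contours) {
    if (cc$axis == "axial") next
    if (cc$axis == "sagittal") {
      m <- .rasterize_contour(cc$points, target$origin[2:3], target$spacing[2:3],
                              d[2:3])
      out[cc$index, , ] <- out[cc$index, , ] & m
    } else {
      m <- .rasterize_contour(cc$points, target$origin[c(1, 3)],
                              target$spacing[c(1, 3)], d[c(1, 3)])
      out[, cc$index, ] <- out[, cc$index, ] & m
    }
  }
  res <- target
  res$data <- array(as.numeric(out), d)
  res
}

#' Segment a volume by an intensity band
#'
#' Binary mask of voxels with intensity in `[lo, hi]`, largest connected
#' component, surfaced with [mesh_from_mask]. This is the thresholding
#' segmentation used for registration validation surfaces and for unattended
#' phantom tooth extraction.
#'
#' @param vol an [image_volume].
#' @param lo,hi intensity band (inclusive).
#' @return a closed [triangle_mesh].
#' @export
threshold_segment <- function(vol, lo, hi = Inf) {
  if (lo >= hi) stop("need lo < hi")
  if (!any(vol$data >= lo & vol$data <= hi))
    stop("empty selection: no voxels in the intensity band")
  # gray-value isosurfacing: the in-band indicator field is positive inside
  # the band and crosses zero at the band edges, so vertices land at the
  # sub-voxel interpolated threshold crossings (as thresholding software does)
  fv <- vol
  f <- vol$data - lo
  if (is.finite(hi)) f <- pmin(f, hi - vol$data)
  fv$data <- array(f, dim(vol$data))
  iso_surface(fv, 0)
}

#' Unattended phantom tooth segmentation
#'
#' Thresholds the tooth intensity band, keeps the largest component and
#' surfaces it. A non-interactive stand-in for livewire contouring so the
#' full pipeline can run unattended on phantoms.
#' @param vol an [image_volume].
#' @param band length-2 intensity band `(lo, hi)`.
#' @export
auto_segment <- function(vol, band) {
  threshold_segment(vol, band[1], band[2])
}

#' Livewire-based tooth segmentation (observer emulation)
#'
#' Re-enacts interactive livewire delineation without a human: on every
#' `slice_step`-th axial slice where the intensity band has enough area, it
#' places `n_anchors` anchor points near the apparent boundary (jittered by up
#' to `jitter_vox` voxels, emulating operator click scatter), traces livewire
#' paths between consecutive anchors on the slice's cost image, closes the
#' contour, and finally reconstructs the volume with [interpolate_contours]
#' and surfaces it.
#'
#' @param vol an [image_volume].
#' @param band length-2 tooth intensity band.
#' @param slice_step trace every this-many axial slices.
#' @param n_anchors anchors per contour.
#' @param jitter_vox uniform anchor jitter amplitude in voxels.
#' @param seed integer seed for the jitter stream.
#' @param params [livewire_params].
#' @param min_area_px minimum in-band pixel count for a slice to be traced.
#' @return a closed [triangle_mesh].
#' @export
segment_tooth_livewire <- function(vol, band, slice_step = 3L, n_anchors = 10L,
                                   jitter_vox = 1, seed = 0L,
                                   params = livewire_params(),
                                   min_area_px = 40L) {
  mask <- vol$data >= band[1] & vol$data <= band[2]
  if (!any(mask)) stop("empty selection: no voxels in the intensity band")
  lab <- .label_components(as.logical(mask), dim(vol$data))
  counts <- tabulate(lab, attr(lab, "n_components"))
  mask <- array(lab == which.max(counts), dim(vol$data))
  kk <- which(apply(mask, 3, sum) >= min_area_px)
  if (length(kk) < 2) stop("tooth band too thin to contour")
  ks <- unique(c(seq(min(kk), max(kk), by = slice_step), max(kk)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  contours <- list()
  for (k in ks) {
    sl <- get_slice(vol, "axial", k)
    mk <- mask[, , k]
    # boundary pixels of the rough mask
    er <- mk & .shift2(mk, 1, 0) & .shift2(mk, -1, 0) & .shift2(mk, 0, 1) &
      .shift2(mk, 0, -1)
    bd <- which(mk & !er, arr.ind = TRUE)
    if (nrow(bd) < n_anchors) next
    ctr <- colMeans(bd)
    ang <- atan2(bd[, 2] - ctr[2], bd[, 1] - ctr[1])
    ord <- order(ang)
    pick <- ord[round(seq(1, length(ord), length.out = n_anchors + 1))[-(n_anchors + 1)]]
    anchors <- bd[pick, , drop = FALSE] +
      matrix(round(runif(2 * n_anchors, -jitter_vox, jitter_vox)), n_anchors, 2)
    anchors[, 1] <- pmin(pmax(anchors[, 1], 2L), nrow(mk) - 1L)
    anchors[, 2] <- pmin(pmax(anchors[, 2], 2L), ncol(mk) - 1L)
    cost <- livewire_cost(sl$image, params)
    segs <- vector("list", n_anchors)
    for (a in seq_len(n_anchors)) {
      b <- if (a == n_anchors) 1L else a + 1L
      segs[[a]] <- livewire_path(cost, anchors[a, ], anchors[b, ])
    }
    cc <- tryCatch(close_contour(segs, sl), error = function(e) NULL)
    if (!is.null(cc)) contours[[length(contours) + 1]] <- cc
  }
  if (length(contours) < 2) stop("livewire contouring failed on too many slices")
  mesh_from_mask(interpolate_contours(contours, vol))
}
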