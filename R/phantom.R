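#' Phantom specification
#'
#' Parameters of the synthetic paired-CBCT phantom: a bone-like block with
#' embedded low-intensity pores (trabecular-like structure that anchors the
#' registration) and a canine-like tooth, imaged at two "time points". Between
#' the time points the tooth moves by a known local rigid motion and the whole
#' scene by a known global motion (simulated head repositioning), with
#' independent additive Gaussian intensity noise per scan.
#'
#' The tooth analog is a superellipsoid crown fused to a tapered cone root:
#' for z >= 0 the solid is the upper half of the superellipsoid
#' `|x/r|^e + |y/r|^e + |z/r|^e <= 1`, and for z in `[-root_length, 0)` a
#' circular frustum tapering from `root_radius` to `root_taper * root_radius`.
#' With `root_length = 0` the solid is the full superellipsoid (pure crown),
#' so the sphere is recovered at exponent 2. The solid has closed-form volume
#' (see [tooth_volume_analytic]), which anchors the segmentation accuracy
#' tests. Default shape parameters give a volume near 455 mm^3, the scale of
#' mean maxillary canine volumes in children around mixed-dentition age.
#'
#' @param voxel_mm isotropic voxel size in mm (0.1 to 0.5; CBCT protocols for
#'   cleft imaging use 0.15-0.2 mm).
#' @param grid_dims length-3 integer grid size.
#' @param crown_radius,crown_exponent,root_length,root_radius,root_taper tooth
#'   shape parameters (mm, unitless exponent, mm, mm, unitless fraction).
#'   `crown_radius` may be a scalar or length-2 `(mesiodistal, palatofacial)`
#'   semi-axes; canine crowns are mesiodistally wide and palatofacially
#'   narrow, which also makes rotation about the long axis observable.
#' @param tooth_pose_pre [rigid_transform] placing the canonical tooth in the
#'   pre-operative scene (world mm).
#' @param local_motion [rigid_transform]: tooth motion between time points in
#'   world (pre-scan) space.
#' @param global_motion [rigid_transform]: whole-scene motion between scans.
#' @param noise_sd intensity noise SD (same arbitrary units as intensities).
#' @param intensities named list/vector with `background`, `bone`, `tooth`
#'   levels, strictly increasing.
#' @param seed integer seed controlling the noise stream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_mm = 0.2,
                         grid_dims = c(116L, 116L, 176L),
                         crown_radius = c(5.0, 3.5), crown_exponent = 3,
                         root_length = 9, root_radius = 3.2, root_taper = 0.2,
                         tooth_pose_pre = make_rigid(t = c(0, 0, 3)),
                         local_motion = rigid_transform(),
                         global_motion = rigid_transform(),
                         noise_sd = 5,
                         intensities = c(background = 0, bone = 100, tooth = 160),
                         seed = 1L) {
  if (voxel_mm < 0.1 || voxel_mm > 0.5) stop("voxel_mm must be in [0.1, 0.5]")
  crown_radius <- rep(as.numeric(crown_radius), length.out = 2)
  if (any(crown_radius <= 0)) stop("crown radius must be positive")
  if (crown_exponent < 1) stop("crown exponent must be >= 1")
  if (root_length < 0 || root_radius <= 0 || root_taper < 0 || root_taper > 1)
    stop("degenerate root parameters")
  ints <- as.numeric(intensities[c("background", "bone", "tooth")])
  if (any(is.na(ints)) || !(ints[1] < ints[2] && ints[2] < ints[3]))
    stop("intensity levels must be strictly ordered background < bone < tooth")
  gd <- as.integer(grid_dims)
  ext <- gd * voxel_mm / 2
  # fixed scene geometry (world mm, grid centered at the origin)
  bone_box <- roi_box(c(-10.6, -10.6, -15.5), pmin(c(10.6, 10.6, 14), ext - 0.2))
  pores <- cbind(x = c(-5.5, 5.5, -3.0, 5.0, 0.0, -6.0, 1.0, -1.5),
                 y = c(-4.5, -3.0, 5.5, 5.0, -6.0, 1.5, 0.5, -2.0),
                 z = c(-13.6, -14.0, -13.9, -13.3, -13.5, -14.2, -13.2, -14.0),
                 r = c(2.4, 2.0, 1.6, 2.2, 1.8, 1.4, 2.1, 1.5))
  spec <- structure(list(
    voxel_mm = voxel_mm, grid_dims = gd,
    crown_radius = crown_radius, crown_exponent = crown_exponent,
    root_length = root_length, root_radius = root_radius,
    root_taper = root_taper,
    tooth_pose_pre = tooth_pose_pre, local_motion = local_motion,
    global_motion = global_motion, noise_sd = noise_sd,
    intensities = c(background = ints[1], bone = ints[2], tooth = ints[3]),
    bone_box = bone_box, pores = pores,
    roi = roi_box(c(-8.5, -8.5, -16.3), c(8.5, 8.5, -11.9)),
    seed = as.integer(seed)), class = "phantom_spec")
  bb <- .tooth_bbox(spec)
  corners <- as.matrix(expand.grid(c(bb$lower[1], bb$upper[1]),
                                   c(bb$lower[2], bb$upper[2]),
                                   c(bb$lower[3], bb$upper[3])))
  pre_corners <- transform_points(tooth_pose_pre, corners)
  if (any(pre_corners < matrix(bone_box$lower, nrow(pre_corners), 3, byrow = TRUE)) ||
      any(pre_corners > matrix(bone_box$upper, nrow(pre_corners), 3, byrow = TRUE)))
    stop("tooth does not fit inside the bone block at its pre-operative pose")
  spec
}

# canonical-space tooth bounding box
.tooth_bbox <- function(spec) {
  rx <- max(spec$crown_radius[1], spec$root_radius)
  ry <- max(spec$crown_radius[2], spec$root_radius)
  rz <- spec$crown_radius[1]
  lo <- c(-rx, -ry, -spec$root_length)
  hi <- c(rx, ry, rz)
  if (spec$root_length == 0) lo[3] <- -rz
  list(lower = lo, upper = hi)
}

# inside test for the canonical tooth solid; pts N x 3 in canonical mm
.tooth_inside <- function(spec, pts) {
  e <- spec$crown_exponent
  rx <- spec$crown_radius[1]
  ry <- spec$crown_radius[2]
  rz <- spec$crown_radius[1]
  z <- pts[, 3]
  se <- (abs(pts[, 1]) / rx)^e + (abs(pts[, 2]) / ry)^e + (abs(z) / rz)^e <= 1
  if (spec$root_length == 0) return(se)
  rootr <- spec$root_radius *
    (1 + (z / spec$root_length) * (1 - spec$root_taper))
  root <- z < 0 & z >= -spec$root_length &
    pts[, 1]^2 + pts[, 2]^2 <= pmax(rootr, 0)^2
  (z >= 0 & se) | root
}

#' Closed-form volume of the phantom tooth solid
#'
#' Crown: (half-)superellipsoid volume
#' `8 rx ry rz Gamma(1+1/e)^3 / Gamma(1+3/e)` (with `rz = rx`);
#' root: circular frustum `pi L (R^2 + R r + r^2) / 3` with tip radius
#' `r = taper * R`. With `root_length = 0` the full superellipsoid volume is
#' returned.
#' @param spec a [phantom_spec].
#' @return volume in mm^3.
#' @export
tooth_volume_analytic <- function(spec) {
  e <- spec$crown_exponent
  r <- spec$crown_radius
  vse <- 8 * r[1] * r[2] * r[1] * gamma(1 + 1 / e)^3 / gamma(1 + 3 / e)
  if (spec$root_length == 0) return(vse)
  R0 <- spec$root_radius
  R1 <- spec$root_taper * R0
  vse / 2 + pi * spec$root_length * (R0^2 + R0 * R1 + R1^2) / 3
}

#' Triangulated surface of the phantom tooth
#'
#' Voxelizes the canonical implicit solid at `resolution` mm and extracts the
#' surface with [mesh_from_mask]. At the default resolution the mesh volume is
#' within 2 percent of [tooth_volume_analytic].
#' @param spec a [phantom_spec].
#' @param resolution tessellation voxel size in mm.
#' @return a closed [triangle_mesh] in canonical tooth coordinates (mm).
#' @export
make_tooth_mesh <- function(spec, resolution = 0.15) {
  bb <- .tooth_bbox(spec)
  lo <- bb$lower - 2 * resolution
  hi <- bb$upper + 2 * resolution
  dims <- pmax(ceiling((hi - lo) / resolution) + 1, 4)
  vol <- image_volume(array(0, dims), spacing = rep(resolution, 3), origin = lo)
  pts <- voxel_centers(vol)
  vol$data[] <- as.numeric(.tooth_inside(spec, pts))
  if (!any(vol$data > 0)) stop("degenerate tooth parameters: empty solid")
  mesh_from_mask(vol)
}

#' Generate a pre/post phantom scan pair with known ground truth
#'
#' The pre-operative volume voxelizes the bone block (with pores) and the
#' tooth at its pre-operative pose; the post-operative volume voxelizes the
#' same scene with the tooth additionally moved by `local_motion` and the
#' whole scene by `global_motion`. Voxelization is by voxel-center inclusion
#' against the analytic implicit solids; noise is additive Gaussian with a
#' seed-controlled stream, drawn independently for the two scans. The same
#' spec and seed always reproduce the identical pair.
#'
#' @param spec a [phantom_spec].
#' @return a list of class `phantom_pair` with elements `pre`, `post`
#'   ([image_volume]s), `truth_global`, `truth_local` ([rigid_transform]s),
#'   `truth_tooth_pre`, `truth_tooth_post` ([triangle_mesh]es), `frame`
#'   ([anatomical_frame] at the pre-operative tooth centroid), `roi`
#'   (registration [roi_box] over stable bone) and `spec`.
#' @param tooth_mesh optional precomputed canonical tooth mesh (from
#'   [make_tooth_mesh]); avoids re-tessellating in cohort generation.
#' @export
generate_pair <- function(spec, tooth_mesh = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  gd <- spec$grid_dims
  h <- spec$voxel_mm
  origin <- -(gd - 1) * h / 2
  template <- image_volume(array(0, gd), spacing = rep(h, 3), origin = origin)
  pts <- voxel_centers(template)
  ints <- spec$intensities
  ext_lo <- origin - h / 2
  ext_hi <- origin + (gd - 0.5) * h

  pose_post <- compose_transforms(spec$global_motion,
                                  compose_transforms(spec$local_motion,
                                                     spec$tooth_pose_pre))
  for (nm in c("pre", "post")) {
    pose <- if (nm == "pre") spec$tooth_pose_pre else pose_post
    bb <- .tooth_bbox(spec)
    corners <- as.matrix(expand.grid(c(bb$lower[1], bb$upper[1]),
                                     c(bb$lower[2], bb$upper[2]),
                                     c(bb$lower[3], bb$upper[3])))
    wc <- transform_points(pose, corners)
    if (any(wc < matrix(ext_lo, 8, 3, byrow = TRUE)) ||
        any(wc > matrix(ext_hi, 8, 3, byrow = TRUE))) {
      stop(sprintf(
        "tooth leaves the grid in the %s scan; offending pose:\n%s", nm,
        paste(capture.output(print(unclass(pose))), collapse = "\n")))
    }
  }

  scene <- function(scene_t) {
    # scene_t maps pre-scene coordinates to this scan's coordinates
    inv <- invert_transform(scene_t)
    q <- if (max(abs(unclass(scene_t) - diag(4))) < 1e-15) pts
         else transform_points(inv, pts)   # back to pre-scene space
    img <- rep(ints["background"], nrow(pts))
    bb <- spec$bone_box
    inbone <- q[, 1] >= bb$lower[1] & q[, 1] < bb$upper[1] &
      q[, 2] >= bb$lower[2] & q[, 2] < bb$upper[2] &
      q[, 3] >= bb$lower[3] & q[, 3] < bb$upper[3]
    for (p in seq_len(nrow(spec$pores))) {
      ctr <- spec$pores[p, 1:3]
      pr <- spec$pores[p, 4]
      near <- which(inbone &
                      abs(q[, 1] - ctr[1]) <= pr &
                      abs(q[, 2] - ctr[2]) <= pr &
                      abs(q[, 3] - ctr[3]) <= pr)
      if (length(near)) {
        d2 <- (q[near, 1] - ctr[1])^2 + (q[near, 2] - ctr[2])^2 +
          (q[near, 3] - ctr[3])^2
        inbone[near[d2 <= pr^2]] <- FALSE
      }
    }
    img[inbone] <- ints["bone"]
    img
  }

  tooth_img <- function(pose) {
    inv <- invert_transform(pose)
    bb <- .tooth_bbox(spec)
    # prefilter by the transformed bounding box
    wc <- transform_points(pose, as.matrix(expand.grid(
      c(bb$lower[1], bb$upper[1]), c(bb$lower[2], bb$upper[2]),
      c(bb$lower[3], bb$upper[3]))))
    lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
    cand <- which(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
                    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
                    pts[, 3] >= lo[3] & pts[, 3] <= hi[3])
    qc <- transform_points(inv, pts[cand, , drop = FALSE])
    cand[.tooth_inside(spec, qc)]
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)

  pre <- template
  img <- scene(rigid_transform())
  img[tooth_img(spec$tooth_pose_pre)] <- ints["tooth"]
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  pre$data[] <- img

  post <- template
  img <- scene(spec$global_motion)
  img[tooth_img(pose_post)] <- ints["tooth"]
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  post$data[] <- img

  tooth <- if (is.null(tooth_mesh)) make_tooth_mesh(spec) else tooth_mesh
  truth_pre <- transform_mesh(tooth, spec$tooth_pose_pre)
  truth_post <- transform_mesh(tooth, pose_post)
  frame <- anatomical_frame(diag(3), origin = mesh_centroid(truth_pre),
                            side = "left")
  structure(list(pre = pre, post = post,
                 truth_global = spec$global_motion,
                 truth_local = spec$local_motion,
                 truth_tooth_pre = truth_pre, truth_tooth_post = truth_post,
                 frame = frame, roi = spec$roi, spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("Phantom CBCT pair:", paste(dim(x$pre$data), collapse = " x "),
      "voxels at", x$spec$voxel_mm, "mm\n")
  cat(sprintf("  local tooth motion: %.3f deg / (%.2f, %.2f, %.2f) mm\n",
              rotation_angle_deg(x$truth_local), x$truth_local[1, 4],
              x$truth_local[2, 4], x$truth_local[3, 4]))
  cat(sprintf("  global scene motion: %.3f deg / (%.2f, %.2f, %.2f) mm\n",
              rotation_angle_deg(x$truth_global), x$truth_global[1, 4],
              x$truth_global[2, 4], x$truth_global[3, 4]))
  invisible(x)
}

#' Generate a cohort of phantom pairs with randomized motions
#'
#' Each case draws an independent local tooth motion (uniform per-component
#' translations up to `max_trans` mm and rotations up to `max_rot` degrees,
#' bracketing reported six-month canine eruption magnitudes) and a smaller
#' global repositioning motion (up to 1 mm / 2 degrees), composed about the
#' tooth centroid in the anatomical frame.
#'
#' @param n number of cases.
#' @param base_spec template [phantom_spec]; per-case seeds replace its seed.
#' @param seed_list integer vector of length `n` (duplicates trigger a
#'   warning).
#' @param max_trans,max_rot per-component motion bounds (mm, degrees).
#' @return list with `pairs` (list of `phantom_pair`) and `truth`
#'   (data.frame of the drawn ground-truth components per case).
#' @export
batch_generate <- function(n, base_spec = phantom_spec(), seed_list = seq_len(n),
                           max_trans = 3, max_rot = 8) {
  if (length(seed_list) != n) stop("seed_list must have length n")
  if (anyDuplicated(seed_list)) warning("duplicate seeds in seed_list")
  pairs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- as.integer(seed_list[i])
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(sd_i)
    tr <- runif(3, -max_trans, max_trans)
    ro <- runif(3, -max_rot, max_rot)
    gtr <- runif(3, -1, 1)
    gro <- runif(3, -2, 2)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    ctr <- drop(transform_points(base_spec$tooth_pose_pre, c(0, 0, 0)))
    frame <- anatomical_frame(diag(3), origin = ctr, side = "left")
    local <- compose_motion(tr[1], tr[2], tr[3], ro[1], ro[2], ro[3],
                            frame = frame, centroid = ctr)
    global <- compose_motion(gtr[1], gtr[2], gtr[3], gro[1], gro[2], gro[3],
                             frame = anatomical_frame(diag(3)),
                             centroid = c(0, 0, 0))
    spec_i <- base_spec
    spec_i$local_motion <- local
    spec_i$global_motion <- global
    spec_i$seed <- sd_i
    if (i == 1L) tooth_mesh <- make_tooth_mesh(base_spec)
    pairs[[i]] <- generate_pair(spec_i, tooth_mesh = tooth_mesh)
    truth[[i]] <- data.frame(case = i, seed = sd_i,
                             dMD = tr[1], dPF = tr[2], dIA = tr[3],
                             pitch = ro[1], roll = ro[2], yaw = ro[3],
                             g_dx = gtr[1], g_dy = gtr[2], g_dz = gtr[3],
                             g_rx = gro[1], g_ry = gro[2], g_rz = gro[3])
  }
  list(pairs = pairs, truth = do.call(rbind, truth))
}
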