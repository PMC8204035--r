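#' Registration settings
#'
#' Defaults: 64-bin joint histogram, 3 pyramid levels with shrink factors
#' 4/2/1, Nelder-Mead optimization of the 6 rigid parameters (axis-angle
#' rotation about the ROI center + translation), full deterministic sampling
#' of the masked voxels, identity initialization (scans of the same patient
#' are roughly aligned). All settings are declared package defaults; the
#' similarity metric itself is mutual information.
#'
#' @param bins joint-histogram bins (>= 8).
#' @param pyramid_levels number of resolution levels (>= 1).
#' @param shrink_factors integer shrink per level, coarsest first.
#' @param max_iterations optimizer iteration cap per level.
#' @param sampling_fraction fraction of masked voxels used (0 < f <= 1);
#'   fractions below 1 are drawn with `seed`.
#' @param seed integer seed for subsampling.
#' @param convergence_tol relative convergence tolerance of the optimizer.
#' @param smooth apply a light separable (1/4, 1/2, 1/4) smoothing to both
#'   volumes at every pyramid level. Without it the large flat bone surfaces
#'   lock onto the voxel grid and the MI surface grows secondary maxima about
#'   one voxel away from the true pose.
#' @param init optional [rigid_transform] initialization.
#' @export
registration_params <- function(bins = 64L, pyramid_levels = 3L,
                                shrink_factors = c(4L, 2L, 1L),
                                max_iterations = c(400L, 400L, 600L),
                                sampling_fraction = 1.0, seed = 0L,
                                convergence_tol = 1e-9, smooth = TRUE,
                                init = NULL) {
  if (bins < 8) stop("bins must be >= 8")
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")
  if (length(shrink_factors) != pyramid_levels)
    shrink_factors <- rep_len(shrink_factors, pyramid_levels)
  if (length(max_iterations) != pyramid_levels)
    max_iterations <- rep_len(max_iterations, pyramid_levels)
  structure(list(bins = as.integer(bins), pyramid_levels = as.integer(pyramid_levels),
                 shrink_factors = as.integer(shrink_factors),
                 max_iterations = as.integer(max_iterations),
                 sampling_fraction = sampling_fraction, seed = as.integer(seed),
                 convergence_tol = convergence_tol, smooth = isTRUE(smooth),
                 init = init),
            class = "registration_params")
}

# separable [1/4, 1/2, 1/4] smoothing along each axis (replicated borders)
.smooth_volume3 <- function(vol) {
  a <- vol$data
  d <- dim(a)
  sm <- function(x, ax) {
    lo <- x; hi <- x
    if (ax == 1) { lo[2:d[1], , ] <- x[1:(d[1] - 1), , ]; hi[1:(d[1] - 1), , ] <- x[2:d[1], , ] }
    if (ax == 2) { lo[, 2:d[2], ] <- x[, 1:(d[2] - 1), ]; hi[, 1:(d[2] - 1), ] <- x[, 2:d[2], ] }
    if (ax == 3) { lo[, , 2:d[3]] <- x[, , 1:(d[3] - 1)]; hi[, , 1:(d[3] - 1)] <- x[, , 2:d[3]] }
    0.25 * lo + 0.5 * x + 0.25 * hi
  }
  vol$data <- sm(sm(sm(a, 1), 2), 3)
  vol
}

# sample moving-image intensities at fixed-space points through t
# (value at fixed point x is moving(t^{-1} x); t maps moving -> fixed)
.sample_moving <- function(moving, t, pts_fixed, fill = NA_real_) {
  q <- transform_points(invert_transform(t), pts_fixed)
  idx0 <- world_to_voxel(moving, q) - 1
  .interp_trilinear(as.numeric(moving$data), dim(moving$data), idx0,
                    if (is.na(fill)) 0 else fill)
}

.mi_bits <- function(fvals, mvals, bins, frange, mrange) {
  fb <- pmin(pmax(ceiling((fvals - frange[1]) / max(frange[2] - frange[1], 1e-12) * bins), 1L), bins)
  mb <- pmin(pmax(ceiling((mvals - mrange[1]) / max(mrange[2] - mrange[1], 1e-12) * bins), 1L), bins)
  joint <- tabulate(fb + bins * (mb - 1L), nbins = bins * bins)
  n <- sum(joint)
  p <- joint[joint > 0] / n
  hj <- -sum(p * log2(p))
  pf <- tabulate(fb, nbins = bins); pf <- pf[pf > 0] / n
  pm <- tabulate(mb, nbins = bins); pm <- pm[pm > 0] / n
  -sum(pf * log2(pf)) - sum(pm * log2(pm)) - hj
}

#' Mutual information between two volumes under a rigid transform
#'
#' Builds the joint histogram of fixed-image intensities (nearest/stored
#' values) against moving-image intensities linearly interpolated at the
#' transformed masked voxel centers, and returns
#' `MI = H(F) + H(M) - H(F, M)` in bits. Voxels mapping outside the moving
#' field of view are excluded; at least 10 percent of the masked voxels must
#' overlap.
#'
#' @param fixed,moving [image_volume]s.
#' @param t [rigid_transform] mapping moving-space points into fixed space.
#' @param bins histogram bins per axis.
#' @param mask optional [roi_box] (in fixed world mm) or logical array over
#'   the fixed grid; default uses every fixed voxel.
#' @return MI in bits (scalar).
#' @export
mutual_information <- function(fixed, moving, t = rigid_transform(), bins = 64L,
                               mask = NULL) {
  pts <- voxel_centers(fixed)
  keep <- if (is.null(mask)) rep(TRUE, nrow(pts))
  else if (inherits(mask, "roi_box"))
    pts[, 1] >= mask$lower[1] & pts[, 1] < mask$upper[1] &
    pts[, 2] >= mask$lower[2] & pts[, 2] < mask$upper[2] &
    pts[, 3] >= mask$lower[3] & pts[, 3] < mask$upper[3]
  else as.logical(mask)
  pts <- pts[keep, , drop = FALSE]
  fvals <- as.numeric(fixed$data)[keep]
  sm <- .sample_moving(moving, t, pts)
  inside <- sm$inside
  overlap <- mean(inside)
  if (overlap < 0.1)
    stop(sprintf("insufficient overlap under the transform (%.1f%% of masked voxels)",
                 100 * overlap))
  .mi_bits(fvals[inside], sm$values[inside], as.integer(bins),
           range(fvals), range(moving$data))
}

#' Rigid registration by mutual-information maximization over a stable ROI
#'
#' Registers `moving` onto `fixed` with a rigid transform that maximizes
#' mutual information computed over the voxels of a region of interest chosen
#' on stable bone (excluding the moving dentition). Multi-resolution
#' Nelder-Mead optimization of axis-angle rotation (about the ROI center) and
#' translation; all numeric settings come from [registration_params].
#'
#' @param fixed,moving [image_volume]s.
#' @param roi [roi_box] inside the fixed volume extent.
#' @param params a [registration_params].
#' @return A [rigid_transform] (class also `rigid_registration`) mapping
#'   moving-space points into fixed space, with convergence metadata in
#'   `attr(, "metadata")`: final MI, optimizer iterations and MI per level.
#' @export
register_rigid_mi <- function(fixed, moving, roi, params = registration_params()) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"),
            inherits(roi, "roi_box"), inherits(params, "registration_params"))
  c0 <- (roi$lower + roi$upper) / 2
  u <- c(0, 0, 0, 0, 0, 0)  # rot deg (axis-angle), trans mm
  if (!is.null(params$init)) {
    R <- params$init[1:3, 1:3]
    ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
    ax <- if (ang < 1e-12) c(0, 0, 0) else {
      v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      v / sqrt(sum(v^2)) * ang
    }
    u[1:3] <- ax * 180 / pi
    u[4:6] <- drop(transform_points(params$init, c0)) - c0
  }
  make_t <- function(u) make_rigid(axis_angle_to_rotation(u[1:3] * pi / 180),
                                   t = u[4:6], center = c0)
  meta <- list(levels = list())
  axis_aligned <- max(abs(fixed$direction - diag(3))) < 1e-12
  for (lev in seq_len(params$pyramid_levels)) {
    f <- params$shrink_factors[lev]
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    if (axis_aligned) {
      d <- dim(fx$data)
      ax_idx <- lapply(1:3, function(ax) {
        coord <- fx$origin[ax] + fx$spacing[ax] * (seq_len(d[ax]) - 1)
        which(coord >= roi$lower[ax] & coord < roi$upper[ax])
      })
      if (any(lengths(ax_idx) == 0))
        stop("ROI does not cover any voxels at pyramid level ", lev)
      ii <- ax_idx[[1]]; jj <- ax_idx[[2]]; kk <- ax_idx[[3]]
      idx <- as.vector(outer(outer(ii, (jj - 1L) * d[1], "+"),
                             (kk - 1L) * d[1] * d[2], "+"))
      pts <- cbind(
        rep(fx$origin[1] + fx$spacing[1] * (ii - 1), times = length(jj) * length(kk)),
        rep(rep(fx$origin[2] + fx$spacing[2] * (jj - 1), each = length(ii)),
            times = length(kk)),
        rep(fx$origin[3] + fx$spacing[3] * (kk - 1),
            each = length(ii) * length(jj)))
      keep <- NULL
    } else {
      pts <- voxel_centers(fx)
      keep <- pts[, 1] >= roi$lower[1] & pts[, 1] < roi$upper[1] &
        pts[, 2] >= roi$lower[2] & pts[, 2] < roi$upper[2] &
        pts[, 3] >= roi$lower[3] & pts[, 3] < roi$upper[3]
      if (!any(keep)) stop("ROI does not cover any voxels at pyramid level ", lev)
      idx <- which(keep)
      pts <- pts[idx, , drop = FALSE]
    }
    if (params$sampling_fraction < 1) {
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(params$seed + lev)
      sub <- sort(sample(length(idx),
                         max(100, round(length(idx) * params$sampling_fraction))))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      idx <- idx[sub]
      pts <- pts[sub, , drop = FALSE]
    }
    pts_l <- pts
    fvals <- as.numeric(fx$data)[idx]
    frange <- range(fvals)
    mrange <- range(mv$data)
    mdat <- as.numeric(mv$data)
    mdim <- dim(mv$data)
    fbin <- pmin(pmax(ceiling((fvals - frange[1]) /
                                max(frange[2] - frange[1], 1e-12) * params$bins), 1L),
                 params$bins)
    S <- t(mv$direction) / mv$spacing  # world -> zero-based index, up to origin
    neg_mi <- function(uu) {
      # soft search bounds: same-patient repositioning is small, so wandering
      # beyond +/-15 deg / 10 mm marks a lost optimizer, not a candidate pose
      if (any(abs(uu[1:3]) > 15) || any(abs(uu[4:6]) > 10))
        return(1 + sum(pmax(abs(uu[1:3]) - 15, 0)) + sum(pmax(abs(uu[4:6]) - 10, 0)))
      tt <- make_t(uu)
      inv <- invert_transform(tt)
      M <- S %*% inv[1:3, 1:3]
      b <- as.numeric(S %*% (inv[1:3, 4] - mv$origin))
      r <- .mi_affine(mdat, mdim, M, b, pts_l, fbin, params$bins,
                      mrange[1], max(mrange[2] - mrange[1], 1e-12))
      if (r[2] < 0.1) return(1)  # insufficient overlap: heavily penalized
      -r[1]
    }
    mi0 <- -neg_mi(u)
    # Nelder-Mead's initial simplex step is 0.1 * parscale: make the first
    # moves about one voxel / one degree-per-voxel at this level
    scale <- rep(10 * fx$spacing[1], 6)
    starts <- list(u)
    if (lev == 1 && max(abs(u)) > 1e-12) starts <- c(starts, list(rep(0, 6)))
    fit <- NULL
    for (st in starts) {
      cand <- optim(st, neg_mi, method = "Nelder-Mead",
                    control = list(maxit = params$max_iterations[lev],
                                   reltol = params$convergence_tol,
                                   parscale = scale))
      if (is.null(fit) || cand$value < fit$value) fit <- cand
    }
    if (lev == params$pyramid_levels) {
      # smoothed-metric polish: the raw-intensity MI of large flat surfaces
      # can lock onto the voxel grid, leaving a shallow secondary maximum
      # about a voxel away from the true pose; a lightly smoothed metric has
      # no such ridge, so a final descent on it walks out of the trap
      if (isTRUE(params$smooth)) {
        fxs <- .smooth_volume3(fx)
        mvs <- .smooth_volume3(mv)
        fvals_s <- as.numeric(fxs$data)[idx]
        frange_s <- range(fvals_s)
        mrange_s <- range(mvs$data)
        fbin_s <- pmin(pmax(ceiling((fvals_s - frange_s[1]) /
                                      max(frange_s[2] - frange_s[1], 1e-12) *
                                      params$bins), 1L), params$bins)
        mdat_s <- as.numeric(mvs$data)
        neg_mi_s <- function(uu) {
          if (any(abs(uu[1:3]) > 15) || any(abs(uu[4:6]) > 10))
            return(1 + sum(pmax(abs(uu[1:3]) - 15, 0)) + sum(pmax(abs(uu[4:6]) - 10, 0)))
          tt <- make_t(uu)
          inv <- invert_transform(tt)
          M <- S %*% inv[1:3, 1:3]
          b <- as.numeric(S %*% (inv[1:3, 4] - mv$origin))
          r <- .mi_affine(mdat_s, mdim, M, b, pts_l, fbin_s, params$bins,
                          mrange_s[1], max(mrange_s[2] - mrange_s[1], 1e-12))
          if (r[2] < 0.1) return(1)
          -r[1]
        }
        fit_s <- optim(fit$par, neg_mi_s, method = "Nelder-Mead",
                       control = list(maxit = params$max_iterations[lev],
                                      reltol = params$convergence_tol,
                                      parscale = scale))
        # simplex restarts with shrinking scale until the pose stops moving;
        # Nelder-Mead alone can stall on noise plateaus of the MI surface
        for (rs in 1:5) {
          fit2 <- optim(fit_s$par, neg_mi_s, method = "Nelder-Mead",
                        control = list(maxit = params$max_iterations[lev],
                                       reltol = params$convergence_tol,
                                       parscale = scale / 8))
          moved <- max(abs(fit2$par - fit_s$par))
          if (fit2$value <= fit_s$value) fit_s <- fit2
          if (moved < 5e-4) break
        }
        fit <- list(par = fit_s$par, value = neg_mi(fit_s$par),
                    counts = fit$counts + fit_s$counts)
      } else {
        # without smoothing, polish on the raw metric instead
        for (rs in 1:6) {
          fit2 <- optim(fit$par, neg_mi, method = "Nelder-Mead",
                        control = list(maxit = params$max_iterations[lev],
                                       reltol = params$convergence_tol,
                                       parscale = scale / if (rs == 1) 2 else 8))
          moved <- max(abs(fit2$par - fit$par))
          if (fit2$value <= fit$value) fit <- fit2
          if (rs > 1 && moved < 5e-4) break
        }
      }
    }
    if (lev == 1 && -fit$value < mi0 - 1e-9)
      stop(sprintf(paste0("optimizer diverged at the coarsest level ",
                          "(MI %.4f -> %.4f bits); supply a better ",
                          "initialization via registration_params(init=)"),
                   mi0, -fit$value))
    u <- fit$par
    meta$levels[[lev]] <- list(shrink = f, mi_initial = mi0, mi_final = -fit$value,
                               evaluations = unname(fit$counts[1]))
  }
  out <- make_t(u)
  meta$final_mi <- meta$levels[[params$pyramid_levels]]$mi_final
  meta$params <- params
  attr(out, "metadata") <- meta
  class(out) <- c("rigid_registration", "rigid_transform")
  out
}

#' @export
print.rigid_registration <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat("Rigid MI registration (moving -> fixed)\n")
  cat(sprintf("final MI: %.4f bits over %d levels\n", meta$final_mi,
              length(meta$levels)))
  for (l in meta$levels)
    cat(sprintf("  shrink %d: MI %.4f -> %.4f (%d evaluations)\n",
                l$shrink, l$mi_initial, l$mi_final, l$evaluations))
  print.rigid_transform(x)
  invisible(x)
}

#' Resample a volume onto a reference grid through a rigid transform
#'
#' Returns `vol` sampled on `reference`'s grid with trilinear interpolation:
#' the output value at reference voxel center x is `vol(t^{-1} x)`. Voxels
#' mapping outside `vol` get `fill`.
#'
#' @param vol [image_volume] to resample (the moving image).
#' @param t [rigid_transform] mapping `vol` space into reference space.
#' @param reference [image_volume] providing the output grid.
#' @param fill out-of-field value.
#' @export
resample <- function(vol, t, reference, fill = 0) {
  stopifnot(inherits(vol, "image_volume"), inherits(reference, "image_volume"))
  pts <- voxel_centers(reference)
  sm <- .sample_moving(vol, t, pts, fill = fill)
  vals <- sm$values
  vals[!sm$inside] <- fill
  out <- reference
  out$data <- array(vals, dim(reference$data))
  out
}
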