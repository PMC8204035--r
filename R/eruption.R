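#' ICP settings
#'
#' @param max_iterations iteration cap.
#' @param tol convergence tolerance in mm: the iteration stops when the
#'   point-to-surface RMS change or the maximum pose-update displacement
#'   falls below it.
#' @param trim fraction of worst correspondences discarded each iteration
#'   (in [0, 0.5)). Trimming adds robustness against local shape change or
#'   outliers but sacrifices the extreme crown points that carry the
#'   long-axis rotation signal, so the default is 0.
#' @param n_samples source vertices used (seeded subsample when the mesh has
#'   more).
#' @param seed integer seed for the subsample.
#' @export
icp_params <- function(max_iterations = 250L, tol = 1e-5, trim = 0,
                       n_samples = 3000L, seed = 0L) {
  if (tol <= 0) stop("tol must be positive")
  if (trim < 0 || trim >= 0.5) stop("trim fraction must be in [0, 0.5)")
  structure(list(max_iterations = as.integer(max_iterations), tol = tol,
                 trim = trim, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "icp_params")
}

# closed-form rigid fit (Kabsch/SVD): R, t minimizing ||R P + t - Q||
.kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- det(s$v %*% t(s$u))
  R <- s$v %*% diag(c(1, 1, sign(d))) %*% t(s$u)
  list(R = R, t = as.numeric(qc - R %*% pc))
}

#' Iterative closest point surface registration
#'
#' Aligns `source` onto `target` with a rigid transform by alternating
#' nearest point-to-surface correspondence (true point-to-triangle distance)
#' with the closed-form SVD/Kabsch rigid fit, optionally trimming the worst
#' correspondences. Assumes a coarse initial alignment (here provided
#' upstream by the voxel-based scan registration).
#'
#' @param source,target [triangle_mesh]es.
#' @param params an [icp_params].
#' @return A [rigid_transform] mapping source onto target, with `rms_history`
#'   (mm) and iteration count in `attr(, "metadata")`. Warns if the final RMS
#'   exceeds 2 mm (probable mis-correspondence); errors if the RMS change has
#'   not converged within `max_iterations`.
#' @export
icp_register <- function(source, target, params = icp_params()) {
  stopifnot(inherits(source, "triangle_mesh"), inherits(target, "triangle_mesh"))
  if (nrow(source$vertices) < 4 || nrow(target$faces) < 4)
    stop("degenerate mesh for ICP")
  P0 <- source$vertices
  if (nrow(P0) > params$n_samples) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(params$seed)
    P0 <- P0[sample.int(nrow(P0), params$n_samples), , drop = FALSE]
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  grid <- .mesh_grid_build(target$vertices, target$faces, -1)
  # warm start: align vertex centroids (removes most of the translation, so
  # the first correspondence search stays local)
  T_cur <- make_rigid(t = colMeans(target$vertices) - colMeans(source$vertices))
  rms <- Inf
  hist <- numeric(0)
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    P <- transform_points(T_cur, P0)
    cp <- .mesh_grid_query(grid, P)
    d <- cp$distance
    keep <- seq_along(d)
    if (params$trim > 0)
      keep <- order(d)[seq_len(ceiling(length(d) * (1 - params$trim)))]
    fit <- .kabsch(P[keep, , drop = FALSE], cp$point[keep, , drop = FALSE])
    upd <- make_rigid(fit$R, fit$t)
    T_cur <- compose_transforms(upd, T_cur)
    new_rms <- sqrt(mean(d[keep]^2))
    hist <- c(hist, new_rms)
    # pose-update displacement: with trimming the trimmed RMS jitters as the
    # kept set changes, so also stop when the pose update itself is negligible
    upd_disp <- sqrt(max(rowSums((transform_points(upd, P) - P)^2)))
    if (is.finite(rms) && (abs(rms - new_rms) < params$tol || upd_disp < params$tol)) {
      converged <- TRUE
      break
    }
    rms <- new_rms
  }
  if (!converged)
    stop(sprintf("ICP did not converge in %d iterations (final RMS %.4f mm)",
                 params$max_iterations, hist[length(hist)]))
  if (hist[length(hist)] > 2)
    warning(sprintf("ICP RMS %.2f mm exceeds 2 mm: probable mis-correspondence",
                    hist[length(hist)]))
  attr(T_cur, "metadata") <- list(rms_history = hist, iterations = length(hist),
                                  rms = hist[length(hist)], params = params)
  T_cur
}

#' Measure tooth eruption between pre- and registered post-operative surfaces
#'
#' The core measurement: registers the pre-operative tooth surface onto the
#' (already scan-registered) post-operative tooth surface with [icp_register],
#' decomposes the recovered rigid motion into the six clinical components with
#' [decompose_motion] about the pre-operative tooth centroid, and reports both
#' tooth volumes.
#'
#' @param pre_tooth [triangle_mesh] of the pre-operative tooth.
#' @param post_tooth [triangle_mesh] of the post-operative tooth, already
#'   mapped into the pre-operative scan space by the upstream registration.
#' @param frame [anatomical_frame] of the tooth.
#' @param params [icp_params].
#' @return An `eruption_measures` object (see [decompose_motion]) with
#'   `volume_pre`, `volume_post` (mm^3), the ICP `transform` and its RMS.
#' @export
assess_eruption <- function(pre_tooth, post_tooth, frame, params = icp_params()) {
  t_icp <- icp_register(pre_tooth, post_tooth, params)
  ctr <- mesh_centroid(pre_tooth)
  m <- decompose_motion(t_icp, frame, ctr)
  m$volume_pre <- mesh_volume(pre_tooth)
  m$volume_post <- mesh_volume(post_tooth)
  m$transform <- t_icp
  m$icp_rms <- attr(t_icp, "metadata")$rms
  m$centroid <- ctr
  m
}

#' @export
coef.eruption_measures <- function(object, ...) {
  c(dMD = object$dMD, dPF = object$dPF, dIA = object$dIA,
    pitch = object$pitch, roll = object$roll, yaw = object$yaw)
}

#' @export
summary.eruption_measures <- function(object, ...) {
  print(object)
  total_t <- sqrt(object$dMD^2 + object$dPF^2 + object$dIA^2)
  cat(sprintf("  total translation %.3f mm; ICP RMS %s mm\n", total_t,
              if (is.null(object$icp_rms)) "n/a" else sprintf("%.4f", object$icp_rms)))
  invisible(object)
}
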