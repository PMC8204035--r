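#' Surface distance map
#'
#' For every vertex of `a`, the unsigned distance to the closest point on any
#' triangle of `b` (true point-to-triangle distance, accelerated by a uniform
#' grid that never changes the values). Distances are attached to `a` as
#' per-vertex scalars for color-map export. Optionally signed distances
#' (negative where the vertex lies on the inner side of the closest triangle)
#' for visualization.
#'
#' @param a,b [triangle_mesh]es; distances are measured from `a` to `b`.
#' @param signed also compute a sign from the closest triangle's orientation.
#' @return `a` with `$scalars` set to the distances (mm).
#' @export
surface_distance_map <- function(a, b, signed = FALSE) {
  stopifnot(inherits(a, "triangle_mesh"), inherits(b, "triangle_mesh"))
  if (nrow(a$vertices) == 0 || nrow(b$faces) == 0) stop("empty mesh")
  cp <- .closest_on_mesh(a$vertices, b$vertices, b$faces)
  d <- cp$distance
  if (signed) {
    f <- b$faces[cp$triangle, , drop = FALSE]
    v1 <- b$vertices[f[, 1], , drop = FALSE]
    v2 <- b$vertices[f[, 2], , drop = FALSE]
    v3 <- b$vertices[f[, 3], , drop = FALSE]
    n <- cbind((v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
               (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
               (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1]))
    s <- sign(rowSums((a$vertices - cp$point) * n))
    d <- d * ifelse(s == 0, 1, s)
  }
  a$scalars <- d
  a
}

#' Mean absolute difference of a distance map
#'
#' MAD is the mean of the absolute surface distances; SD is their standard
#' deviation with the population denominator n.
#' @param distances numeric vector of distances (mm), or a [triangle_mesh]
#'   carrying them as scalars.
#' @return list with `mad` and `sd` (mm) and `n`.
#' @export
mad_sd <- function(distances) {
  if (inherits(distances, "triangle_mesh")) distances <- distances$scalars
  if (is.null(distances) || length(distances) == 0) stop("no distances")
  a <- abs(distances)
  m <- mean(a)
  list(mad = m, sd = sqrt(mean((a - m)^2)), n = length(a))
}

#' Part comparison of two registered scans
#'
#' Registration-accuracy assessment: thresholds both volumes (the baseline
#' scan and the follow-up scan already resampled into baseline space) within
#' the bone intensity band, extracts their surfaces, computes the distance
#' map from the baseline surface to the follow-up surface, and summarizes it
#' as MAD +/- SD. The follow-up must already be resampled into the baseline
#' grid; restrict both volumes to the registration ROI (e.g. with
#' [crop_to_roi]) to compare the surfaces the registration actually used.
#'
#' @param pre_roi,post_registered_roi [image_volume]s on the same grid.
#' @param band length-2 intensity band for [threshold_segment].
#' @return list with `mad`, `sd`, `n` (vertices), `mesh` (baseline surface
#'   carrying the distance map as scalars) and `direction`.
#' @export
part_comparison <- function(pre_roi, post_registered_roi, band) {
  a <- threshold_segment(pre_roi, band[1], band[2])
  b <- threshold_segment(post_registered_roi, band[1], band[2])
  dm <- surface_distance_map(a, b)
  res <- mad_sd(dm)
  list(mad = res$mad, sd = res$sd, n = res$n, mesh = dm,
       direction = "pre -> registered post")
}
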