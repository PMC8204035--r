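#' Decompose a rigid tooth motion into six clinical components
#'
#' Expresses a rigid transform in a tooth's anatomical frame and splits it
#' into the three translations and three rotations used to report eruption:
#' mesiodistal (dMD, + mesial), palatofacial (dPF, + facial) and incisoapical
#' (dIA, + incisal) displacement of the tooth centroid in mm, and pitch, roll
#' and yaw in degrees. Rotations are extrinsic Euler angles in the fixed order
#' pitch (about the M/D axis), then roll (about the P/F axis), then yaw (about
#' the I/A axis); positive angles are counter-clockwise about the axis by the
#' right-hand rule. Translation is the displacement of `centroid` (not the raw
#' translation column), so it does not depend on the rotation's lever arm.
#' For right-side teeth the M/D component sign is flipped so that + mesial is
#' consistent across sides.
#'
#' @param t a [rigid_transform] mapping the pre-operative tooth onto the
#'   (registered) post-operative tooth, in world mm.
#' @param frame an [anatomical_frame].
#' @param centroid length-3 world point (mm) whose displacement is reported;
#'   conventionally the pre-operative tooth centroid.
#' @return A named list of class `eruption_measures` with elements `dMD`,
#'   `dPF`, `dIA` (mm), `pitch`, `roll`, `yaw` (degrees), and a logical
#'   `gimbal_warning` set when |roll| is within 0.5 degrees of 90 (pitch and
#'   yaw become ill-conditioned there).
#' @export
decompose_motion <- function(t, frame, centroid) {
  stopifnot(is_rigid_transform(t), inherits(frame, "anatomical_frame"))
  A <- frame$axes
  R <- t[1:3, 1:3]
  Rp <- A %*% R %*% t(A)
  sy <- max(-1, min(1, -Rp[3, 1]))
  roll <- asin(sy)
  gimbal <- abs(abs(roll) - pi / 2) < 0.5 * pi / 180
  if (!gimbal) {
    pitch <- atan2(Rp[3, 2], Rp[3, 3])
    yaw <- atan2(Rp[2, 1], Rp[1, 1])
  } else {
    # pitch/yaw degenerate: conventionally put all residual rotation in yaw
    pitch <- 0
    yaw <- atan2(-Rp[1, 2], Rp[2, 2])
  }
  c0 <- as.numeric(centroid)
  d <- as.numeric(A %*% (drop(transform_points(t, c0)) - c0))
  if (frame$side == "right") d[1] <- -d[1]
  structure(list(dMD = d[1], dPF = d[2], dIA = d[3],
                 pitch = pitch * 180 / pi, roll = roll * 180 / pi,
                 yaw = yaw * 180 / pi, gimbal_warning = gimbal,
                 side = frame$side,
                 euler_order = "extrinsic pitch(M/D) -> roll(P/F) -> yaw(I/A)"),
            class = "eruption_measures")
}

#' Compose a rigid transform from six clinical motion components
#'
#' Inverse of [decompose_motion]: builds the rigid transform that moves the
#' tooth by the stated translations of its centroid along the anatomical axes
#' and the stated extrinsic pitch/roll/yaw rotations about the centroid.
#'
#' @param dMD,dPF,dIA translations in mm (+ mesial, + facial, + incisal).
#' @param pitch,roll,yaw rotations in degrees about the M/D, P/F and I/A axes.
#' @param frame an [anatomical_frame].
#' @param centroid length-3 rotation center in world mm.
#' @return A [rigid_transform].
#' @export
compose_motion <- function(dMD, dPF, dIA, pitch, roll, yaw, frame, centroid) {
  stopifnot(inherits(frame, "anatomical_frame"))
  A <- frame$axes
  d <- c(dMD, dPF, dIA)
  if (frame$side == "right") d[1] <- -d[1]
  r <- c(pitch, roll, yaw) * pi / 180
  Rp <- rot_z(r[3]) %*% rot_y(r[2]) %*% rot_x(r[1])
  R <- t(A) %*% Rp %*% A
  make_rigid(R, t = as.numeric(t(A) %*% d), center = centroid)
}

#' @export
print.eruption_measures <- function(x, ...) {
  cat("Tooth motion (anatomical frame, ", x$side, " side):\n", sep = "")
  cat(sprintf("  translation  M/D %+.3f  P/F %+.3f  I/A %+.3f  mm\n",
              x$dMD, x$dPF, x$dIA))
  cat(sprintf("  rotation   pitch %+.3f  roll %+.3f  yaw %+.3f  deg  (%s)\n",
              x$pitch, x$roll, x$yaw, x$euler_order))
  if (!is.null(x$volume_pre))
    cat(sprintf("  volume     pre %.2f  post %.2f  mm^3\n",
                x$volume_pre, x$volume_post))
  if (isTRUE(x$gimbal_warning))
    cat("  warning: |roll| within 0.5 deg of 90; pitch/yaw ill-conditioned\n")
  invisible(x)
}

#' @export
as.data.frame.eruption_measures <- function(x, ...) {
  data.frame(dMD = x$dMD, dPF = x$dPF, dIA = x$dIA, pitch = x$pitch,
             roll = x$roll, yaw = x$yaw,
             volume_pre = if (is.null(x$volume_pre)) NA_real_ else x$volume_pre,
             volume_post = if (is.null(x$volume_post)) NA_real_ else x$volume_post)
}
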