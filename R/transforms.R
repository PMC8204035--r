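#' Rigid transforms
#'
#' A rigid transform is stored as a 4x4 homogeneous matrix mapping point
#' coordinates (mm) from a moving space into a fixed space. The rotation block
#' must be a proper rotation (orthonormal, determinant +1) and the bottom row
#' is exactly (0, 0, 0, 1).
#'
#' @param matrix 4x4 numeric homogeneous matrix.
#' @param tol tolerance on orthonormality (Frobenius norm of R'R - I).
#' @return An object of class `rigid_transform` (a 4x4 matrix).
#' @export
rigid_transform <- function(matrix = diag(4), tol = 1e-9) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L))) stop("rigid transform must be a 4x4 matrix")
  if (!all(m[4, ] == c(0, 0, 0, 1)))
    stop("rigid transform bottom row must be exactly (0,0,0,1)")
  R <- m[1:3, 1:3]
  err <- sqrt(sum((crossprod(R) - diag(3))^2))
  if (err >= tol)
    stop(sprintf("rotation block not orthonormal (|R'R - I|_F = %.3g)", err))
  if (det(R) < 0) stop("rotation block has determinant -1 (reflection, not rigid)")
  structure(m, class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (moving -> fixed, mm):\n")
  print(unclass(x))
  ang <- rotation_angle_deg(x)
  cat(sprintf("rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x[1, 4], x[2, 4], x[3, 4]))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Build a rigid transform from a rotation and a translation
#'
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation (mm).
#' @param center optional length-3 rotation center (mm); when given the map is
#'   `x -> R (x - center) + center + t`.
#' @return A `rigid_transform`.
#' @export
make_rigid <- function(R = diag(3), t = c(0, 0, 0), center = NULL) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  tt <- as.numeric(t)
  if (!is.null(center)) {
    c0 <- as.numeric(center)
    tt <- tt + c0 - R %*% c0
  }
  m[1:3, 4] <- tt
  rigid_transform(m)
}

#' Compose rigid transforms (apply `b` first, then `a`)
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) rigid_transform(unclass(a) %*% unclass(b))

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  R <- t[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -crossprod(R, t[1:3, 4])
  rigid_transform(m)
}

#' Apply a rigid transform to points
#' @param t a `rigid_transform`.
#' @param pts N x 3 matrix of points (mm).
#' @return N x 3 matrix of transformed points.
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(t[1:3, 1:3]), 2, t[1:3, 4], "+")
}

#' Rotation matrix from an axis-angle vector
#'
#' The rotation angle is the Euclidean norm of `v` (radians) and the axis its
#' direction (Rodrigues formula). The zero vector gives the identity.
#' @param v length-3 axis-angle vector (radians).
#' @export
axis_angle_to_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-30) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rigid transform in degrees
#' @param t a `rigid_transform` or 3x3 rotation matrix.
#' @export
rotation_angle_deg <- function(t) {
  R <- if (is.matrix(t) && all(dim(t) == c(3, 3))) t else t[1:3, 1:3]
  c_ <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  # atan2 of the skew part keeps full precision for small angles, where
  # acos((tr-1)/2) loses half the significant digits
  s_ <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
               (R[2, 1] - R[1, 2])^2) / 2
  atan2(s_, c_) * 180 / pi
}

#' Closest proper rotation to a 3x3 matrix
#'
#' Projects an arbitrary non-singular 3x3 matrix onto the rotation group via
#' the singular value decomposition: `R = U diag(1, 1, det(U V')) V'`, the
#' closest proper rotation in the Frobenius norm.
#' @param m 3x3 numeric matrix.
#' @export
nearest_rotation <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("expected a 3x3 matrix")
  s <- svd(m)
  if (min(s$d) <= 1e-12 * max(s$d)) stop("matrix is singular; no unique nearest rotation")
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Anatomical frame for a tooth
#'
#' A right-handed orthonormal triad of axes: mesiodistal (+ mesial),
#' palatofacial (+ facial) and incisoapical (+ incisal), plus an origin and a
#' side flag. Axes are given as the rows of `axes` in world (scanner)
#' coordinates and are re-orthonormalized by Gram-Schmidt.
#'
#' @param axes 3x3 matrix, rows = M/D, P/F, I/A directions in world mm.
#' @param origin length-3 world origin (mm).
#' @param side `"left"` or `"right"`. For right-side teeth the sign of the
#'   reported mesiodistal translation is flipped so that + always means mesial.
#' @param cleft logical flag carried through to reports.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(axes = diag(3), origin = c(0, 0, 0),
                             side = c("left", "right"), cleft = FALSE) {
  side <- match.arg(side)
  A <- as.matrix(axes)
  if (!all(dim(A) == c(3L, 3L))) stop("axes must be a 3x3 matrix")
  # Gram-Schmidt on rows
  u1 <- A[1, ] / sqrt(sum(A[1, ]^2))
  u2 <- A[2, ] - sum(A[2, ] * u1) * u1
  if (sum(u2^2) < 1e-20) stop("frame axes are collinear")
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  if (sum(A[3, ] * u3) < 0)
    stop("frame axes are left-handed; expected a right-handed M/D, P/F, I/A triad")
  A <- rbind(u1, u2, u3)
  dimnames(A) <- list(c("MD", "PF", "IA"), NULL)
  structure(list(axes = A, origin = as.numeric(origin), side = side,
                 cleft = isTRUE(cleft)),
            class = "anatomical_frame")
}

#' Anatomical frame from three operator landmarks
#'
#' Builds the tooth frame from the incisal tip and points on the mesial and
#' facial crown surfaces: the mesiodistal axis points from the crown centroid
#' toward the mesial point, the palatofacial axis toward the facial point
#' (orthogonalized), and the incisoapical axis completes the right-handed
#' triad toward the incisal tip.
#' @param incisal_tip,mesial_point,facial_point length-3 world points (mm).
#' @param origin frame origin; defaults to the mean of the three landmarks.
#' @inheritParams anatomical_frame
#' @export
frame_from_landmarks <- function(incisal_tip, mesial_point, facial_point,
                                 origin = NULL, side = "left", cleft = FALSE) {
  ctr <- (incisal_tip + mesial_point + facial_point) / 3
  md <- mesial_point - ctr
  pf <- facial_point - ctr
  ia <- c(md[2] * pf[3] - md[3] * pf[2],
          md[3] * pf[1] - md[1] * pf[3],
          md[1] * pf[2] - md[2] * pf[1])
  if (sum(ia * (incisal_tip - ctr)) < 0) { pf <- -pf }
  f <- anatomical_frame(rbind(md, pf / sqrt(sum(pf^2)), c(0, 0, 1)),
                        origin = if (is.null(origin)) ctr else origin,
                        side = side, cleft = cleft)
  f
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("Anatomical frame (%s side%s), origin (%.2f, %.2f, %.2f) mm\n",
              x$side, if (x$cleft) ", cleft" else "", x$origin[1], x$origin[2],
              x$origin[3]))
  print(round(x$axes, 6))
  invisible(x)
}

#' Read / write a rigid transform as a plain-text 4x4 matrix
#'
#' The file holds four whitespace-separated rows. Reading validates rigidity
#' (orthonormal rotation block, determinant +1) and rejects reflections.
#' @param path file path.
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  rigid_transform(m, tol = 1e-6)
}

#' @rdname read_transform
#' @param t a `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  stopifnot(is_rigid_transform(t))
  lines <- apply(unclass(t), 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
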