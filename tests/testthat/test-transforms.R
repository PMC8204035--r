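test_that("rigid transforms validate their invariants", {
  expect_s3_class(rigid_transform(diag(4)), "rigid_transform")
  bad <- diag(4); bad[4, 1] <- 1
  expect_error(rigid_transform(bad), "bottom row")
  refl <- diag(4); refl[1, 1] <- -1
  expect_error(rigid_transform(refl), "reflection")
  skew <- diag(4); skew[1, 2] <- 0.1
  expect_error(rigid_transform(skew), "orthonormal")
})

test_that("compose, invert and apply are mutually consistent", {
  set.seed(3)
  for (i in 1:20) {
    t1 <- make_rigid(axis_angle_to_rotation(rnorm(3, 0, 0.5)), t = rnorm(3, 0, 4))
    t2 <- make_rigid(axis_angle_to_rotation(rnorm(3, 0, 0.5)), t = rnorm(3, 0, 4))
    p <- matrix(rnorm(15), 5, 3)
    expect_equal(transform_points(compose_transforms(t1, t2), p),
                 transform_points(t1, transform_points(t2, p)), tolerance = 1e-12)
    expect_rigid_close(compose_transforms(t1, invert_transform(t1)),
                       rigid_transform(), 1e-10, 1e-8)
  }
})

test_that("nearest_rotation projects onto proper rotations", {
  R <- axis_angle_to_rotation(c(0.3, -0.2, 0.9))
  expect_equal(nearest_rotation(R), R, tolerance = 1e-12)
  refl <- diag(c(1, 1, -1))
  out <- nearest_rotation(refl)
  expect_equal(det(out), 1, tolerance = 1e-12)
  # noisy orthonormal input: closer in Frobenius norm than random rotations
  set.seed(11)
  M <- R + matrix(rnorm(9, 0, 1e-3), 3, 3)
  Rn <- nearest_rotation(M)
  expect_equal(crossprod(Rn), diag(3), tolerance = 1e-12)
  d0 <- sqrt(sum((M - Rn)^2))
  for (i in 1:20) {
    Rr <- axis_angle_to_rotation(rnorm(3))
    expect_gte(sqrt(sum((M - Rr)^2)), d0)
  }
  expect_error(nearest_rotation(matrix(0, 3, 3)), "singular")
})

test_that("transform files round-trip exactly and reject reflections", {
  tf <- tempfile(fileext = ".txt")
  write_transform(rigid_transform(), tf)
  expect_equal(unclass(read_transform(tf)), diag(4))
  set.seed(5)
  t1 <- make_rigid(axis_angle_to_rotation(rnorm(3)), t = rnorm(3))
  write_transform(t1, tf)
  expect_lt(max(abs(unclass(read_transform(tf)) - unclass(t1))), 1e-12)
  refl <- diag(c(-1, 1, 1, 1))
  writeLines(apply(refl, 1, paste, collapse = " "), tf)
  expect_error(read_transform(tf), "reflection|orthonormal")
})

test_that("anatomical frames are orthonormalized and validated", {
  f <- anatomical_frame(matrix(c(1, 0.1, 0, 0, 1, 0.05, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(f$axes %*% t(f$axes), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det(f$axes), 1, tolerance = 1e-12)
  lh <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  expect_error(anatomical_frame(lh), "left-handed")
  expect_error(anatomical_frame(rbind(c(1, 0, 0), c(2, 0, 0), c(0, 0, 1))),
               "collinear")
})
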