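frame0 <- anatomical_frame(diag(3), origin = c(0, 0, 0), side = "left")

test_that("identity and elementary motions decompose as expected", {
  m <- decompose_motion(rigid_transform(), frame0, c(1, 2, 3))
  expect_equal(unname(coef(m)), rep(0, 6), tolerance = 1e-12)

  t_ia <- make_rigid(t = c(0, 0, 1))
  m <- decompose_motion(t_ia, frame0, c(0, 0, 0))
  expect_equal(unname(coef(m)[1:3]), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(coef(m)[4:6]), rep(0, 3), tolerance = 1e-12)

  yaw90 <- compose_motion(0, 0, 0, 0, 0, 90, frame0, c(0, 0, 0))
  m <- decompose_motion(yaw90, frame0, c(0, 0, 0))
  expect_equal(m$yaw, 90, tolerance = 1e-9)
  expect_equal(c(m$pitch, m$roll, m$dMD, m$dPF, m$dIA), rep(0, 5),
               tolerance = 1e-9)
})

test_that("compose/decompose round-trips 1000 random motions to 1e-9", {
  set.seed(42)
  ctr <- c(2, -1, 3)
  for (i in 1:1000) {
    v <- c(runif(3, -5, 5), runif(2, -80, 80), runif(1, -179, 179))
    # keep roll away from the gimbal zone
    v[5] <- max(min(v[5], 80), -80)
    t <- compose_motion(v[1], v[2], v[3], v[4], v[5], v[6], frame0, ctr)
    m <- decompose_motion(t, frame0, ctr)
    expect_equal(unname(coef(m)), v, tolerance = 1e-9)
  }
})

test_that("translation components are centroid displacements, decoupled from rotation", {
  ctr <- c(4, 5, -2)
  for (i in 1:50) {
    set.seed(i)
    ang <- runif(3, -40, 40)
    t <- compose_motion(0, 0, 0, ang[1], ang[2], ang[3], frame0, ctr)
    m <- decompose_motion(t, frame0, ctr)
    expect_lt(max(abs(c(m$dMD, m$dPF, m$dIA))), 1e-9)
  }
})

test_that("measures are equivariant under a common rigid motion of the scene", {
  set.seed(9)
  ctr <- c(1, 1, 1)
  t <- compose_motion(1.2, -0.7, 2.0, 3, -4, 5, frame0, ctr)
  g <- make_rigid(axis_angle_to_rotation(c(0.4, -0.1, 0.7)), t = c(5, -3, 2))
  # moving the whole scene by g: transform becomes g t g^-1, frame axes and
  # centroid move with g
  t2 <- compose_transforms(g, compose_transforms(t, invert_transform(g)))
  A2 <- frame0$axes %*% t(g[1:3, 1:3])
  f2 <- anatomical_frame(A2, origin = drop(transform_points(g, frame0$origin)))
  m1 <- decompose_motion(t, frame0, ctr)
  m2 <- decompose_motion(t2, f2, drop(transform_points(g, ctr)))
  expect_equal(coef(m1), coef(m2), tolerance = 1e-6)
})

test_that("right-side reporting flips the mesiodistal sign consistently", {
  ctr <- c(0, 0, 0)
  fl <- anatomical_frame(diag(3), side = "left")
  fr <- anatomical_frame(diag(3), side = "right")
  t <- make_rigid(t = c(1.5, 0.3, -0.2))
  ml <- decompose_motion(t, fl, ctr)
  # mirror the scene left<->right (x -> -x): the mirrored translation
  M <- diag(c(-1, 1, 1, 1))
  tm <- rigid_transform(M %*% unclass(t) %*% M)
  mr <- decompose_motion(tm, fr, ctr)
  expect_equal(mr$dMD, ml$dMD, tolerance = 1e-12)
  expect_equal(mr$dPF, ml$dPF, tolerance = 1e-12)
})

test_that("gimbal proximity is flagged", {
  t <- compose_motion(0, 0, 0, 10, 89.8, 20, frame0, c(0, 0, 0))
  m <- decompose_motion(t, frame0, c(0, 0, 0))
  expect_true(m$gimbal_warning)
})
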