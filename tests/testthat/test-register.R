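test_that("mutual information matches closed-form values on binary images", {
  a <- array(0, c(8, 8, 8))
  a[1:4, , ] <- 1  # fair two-level image
  v <- image_volume(a, spacing = c(1, 1, 1))
  expect_equal(mutual_information(v, v), 1, tolerance = 1e-9)

  cst <- image_volume(array(5, c(8, 8, 8)), spacing = c(1, 1, 1))
  expect_equal(mutual_information(v, cst), 0, tolerance = 1e-12)
})

test_that("mutual information is symmetric under grid-aligned transforms", {
  set.seed(21)
  f <- smooth_volume(seed = 1)
  m <- smooth_volume(seed = 2)
  m$data <- m$data + array(rnorm(length(m$data), 0, 5), dim(m$data))
  expect_equal(mutual_information(f, m), mutual_information(m, f),
               tolerance = 1e-9)
  t1 <- make_rigid(t = c(1, 0, 0))  # two whole voxels at 0.5 mm spacing
  expect_equal(mutual_information(f, m, t1),
               mutual_information(m, f, invert_transform(t1)),
               tolerance = 1e-9)
})

test_that("insufficient overlap is refused with the overlap fraction", {
  f <- smooth_volume()
  expect_error(mutual_information(f, f, make_rigid(t = c(500, 0, 0))),
               "overlap")
})

test_that("registering a volume onto itself returns the identity", {
  pair <- generate_pair(fast_spec(seed = 31))
  reg <- register_rigid_mi(pair$pre, pair$pre, pair$roi)
  expect_lt(max(abs(reg[1:3, 4])), 0.02)
  expect_lt(rotation_angle_deg(reg[1:3, 1:3]), 0.1)
})

test_that("a pure grid-aligned translation is recovered almost exactly", {
  spec <- phantom_spec(noise_sd = 0, seed = 1)
  spec$global_motion <- make_rigid(t = c(1, 0, 0))
  pair <- generate_pair(spec)
  reg <- register_rigid_mi(pair$pre, pair$post, pair$roi)
  expect_lt(max(abs(reg[1:3, 4] - c(-1, 0, 0))), 0.05)
  # noise-free MI is piecewise flat, so a small rotational plateau remains
  expect_lt(rotation_angle_deg(reg[1:3, 1:3]), 0.25)
})

test_that("the stable-bone ROI isolates global motion from independent tooth motion", {
  b <- batch_generate(1, fast_spec(), seed_list = 9)
  pair <- b$pairs[[1]]
  reg <- register_rigid_mi(pair$pre, pair$post, pair$roi)
  truth <- invert_transform(pair$truth_global)
  ctr <- c(0, 0, -14)  # inside the registration ROI
  err <- sqrt(sum((transform_points(reg, ctr) - transform_points(truth, ctr))^2))
  expect_lt(err, 0.5 * pair$spec$voxel_mm)
  expect_lt(rotation_angle_deg(reg[1:3, 1:3] %*% t(truth[1:3, 1:3])), 1.0)
  # convergence metadata is attached
  meta <- attr(reg, "metadata")
  expect_length(meta$levels, 3)
  expect_true(all(vapply(meta$levels, function(l) l$mi_final >= l$mi_initial, TRUE)))
})

test_that("the returned optimum beats nearby random perturbations", {
  pair <- generate_pair(fast_spec(seed = 13,
                                  global_motion = make_rigid(t = c(0.5, -0.3, 0.4))))
  reg <- register_rigid_mi(pair$pre, pair$post, pair$roi)
  mi_opt <- mutual_information(pair$pre, pair$post,
                               rigid_transform(unclass(reg)), mask = pair$roi)
  set.seed(77)
  c0 <- (pair$roi$lower + pair$roi$upper) / 2
  for (i in 1:50) {
    pert <- make_rigid(axis_angle_to_rotation(runif(3, -0.5, 0.5) * pi / 180),
                       t = runif(3, -0.5, 0.5), center = c0)
    t2 <- compose_transforms(pert, rigid_transform(unclass(reg)))
    expect_gte(mi_opt + 1e-9,
               mutual_information(pair$pre, pair$post, t2, mask = pair$roi))
  }
})

test_that("registration parameters are validated", {
  expect_error(registration_params(bins = 4), "bins")
  expect_error(registration_params(sampling_fraction = 0), "sampling_fraction")
})
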