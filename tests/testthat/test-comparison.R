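test_that("surface distance maps match analytic configurations", {
  m <- sphere_mesh(r = 3, h = 0.5)
  dm <- surface_distance_map(m, m)
  expect_lt(max(dm$scalars), 1e-9)

  # two parallel squares 0.3 mm apart: every vertex of a projects onto b
  a <- triangle_mesh(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0.3),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  b <- triangle_mesh(cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5), 0),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(surface_distance_map(a, b)$scalars, rep(0.3, 4), tolerance = 1e-12)

  # concentric spheres
  s1 <- sphere_mesh(r = 5, h = 0.4)
  s2 <- sphere_mesh(r = 5.5, h = 0.4)
  d <- surface_distance_map(s1, s2)$scalars
  expect_equal(mean(d), 0.5, tolerance = 0.02)
})

test_that("accelerated distances equal the all-triangles scan exactly", {
  set.seed(12)
  target <- sphere_mesh(r = 2, h = 0.9)
  expect_lte(nrow(target$faces), 500)
  pts <- matrix(rnorm(60, 0, 2.5), 20, 3)
  fast <- .closest_on_mesh(pts, target$vertices, target$faces)$distance
  slow <- brute_point_mesh_dist(pts, target)
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("MAD and SD use absolute distances and the population denominator", {
  expect_equal(mad_sd(c(0, 0, 0)), list(mad = 0, sd = 0, n = 3))
  expect_equal(mad_sd(rep(0.3, 5))$mad, 0.3)
  expect_equal(mad_sd(rep(0.3, 5))$sd, 0)
  r <- mad_sd(c(0.1, 0.3))
  expect_equal(r$mad, 0.2)
  expect_equal(r$sd, 0.1)
  expect_error(mad_sd(numeric(0)), "no distances")
})

test_that("MAD is invariant to a common rigid motion of both meshes", {
  s1 <- sphere_mesh(r = 3, h = 0.5)
  s2 <- sphere_mesh(r = 3.3, h = 0.5, center = c(0.2, 0, 0))
  m0 <- mad_sd(surface_distance_map(s1, s2))$mad
  t1 <- make_rigid(axis_angle_to_rotation(c(0.4, -0.2, 0.6)), t = c(12, -7, 3))
  m1 <- mad_sd(surface_distance_map(transform_mesh(s1, t1),
                                    transform_mesh(s2, t1)))$mad
  expect_equal(m0, m1, tolerance = 1e-9)
})

test_that("part comparison quantifies registration error on phantoms", {
  spec <- fast_spec(noise_sd = 0, global_motion = make_rigid(t = c(0.8, -0.5, 0.6)))
  pair <- generate_pair(spec)
  ints <- spec$intensities
  band <- c((ints["background"] + ints["bone"]) / 2,
            (ints["bone"] + ints["tooth"]) / 2)
  # identical inputs: zero MAD
  pre_roi <- crop_to_roi(pair$pre, pair$roi)
  pc0 <- part_comparison(pre_roi, pre_roi, band)
  expect_lt(pc0$mad, 1e-12)
  # perfect (ground-truth) registration: only resampling quantization remains
  post_reg <- resample(pair$post, invert_transform(pair$truth_global), pair$pre)
  pc1 <- part_comparison(pre_roi, crop_to_roi(post_reg, pair$roi), band)
  expect_lt(pc1$mad, 0.5 * spec$voxel_mm)
  # a 1 mm unregistered shift shows up as 1 mm on the flat bone face
  # (crop-closure faces sit at identical grid positions and dilute the
  # overall MAD, so the check reads the distance map on the flat region)
  shifted <- pair$pre
  shifted$origin <- shifted$origin + c(0, 0, 1)
  pc2 <- part_comparison(pre_roi, crop_to_roi(shifted, pair$roi), band)
  v <- pc2$mesh$vertices
  flat <- abs(v[, 3] + 15.5) < 0.15 & abs(v[, 1]) < 7 & abs(v[, 2]) < 7
  expect_gt(sum(flat), 100)
  expect_equal(mean(pc2$mesh$scalars[flat]), 1, tolerance = 0.05)
})
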