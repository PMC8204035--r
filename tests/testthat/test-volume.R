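test_that("crop_to_roi keeps exactly the voxels whose centers fall in the box", {
  set.seed(8)
  v <- image_volume(array(rnorm(20 * 18 * 16), c(20, 18, 16)),
                    spacing = c(0.3, 0.25, 0.4), origin = c(-2, 1, 0.5))
  full <- roi_box(v$origin - 1, v$origin + dim(v$data) * v$spacing + 1)
  expect_identical(crop_to_roi(v, full)$data, v$data)

  for (i in 1:5) {
    lo <- v$origin + runif(3, 0, 2)
    hi <- lo + runif(3, 1, 3)
    roi <- roi_box(lo, hi)
    vc <- crop_to_roi(v, roi)
    # brute-force center-in-box scan
    ctr <- voxel_centers(v)
    inside <- ctr[, 1] >= lo[1] & ctr[, 1] < hi[1] &
      ctr[, 2] >= lo[2] & ctr[, 2] < hi[2] &
      ctr[, 3] >= lo[3] & ctr[, 3] < hi[3]
    expect_equal(length(vc$data), sum(inside))
    expect_equal(sort(as.vector(vc$data)), sort(as.vector(v$data)[inside]))
  }
})

test_that("cropping preserves world coordinates of every kept voxel", {
  set.seed(9)
  v <- image_volume(array(seq_len(15^3), c(15, 15, 15)),
                    spacing = c(0.2, 0.2, 0.2), origin = c(0, 0, 0))
  roi <- roi_box(c(0.35, 0.5, 0.61), c(2.2, 2.5, 2.8))
  vc <- crop_to_roi(v, roi)
  for (i in 1:100) {
    idx <- c(sample(dim(vc$data)[1], 1), sample(dim(vc$data)[2], 1),
             sample(dim(vc$data)[3], 1))
    w <- voxel_to_world(vc, matrix(idx, 1))
    # the same stored value must sit at the same world position in the parent
    pidx <- round(world_to_voxel(v, w))
    expect_equal(vc$data[idx[1], idx[2], idx[3]],
                 v$data[pidx[1], pidx[2], pidx[3]])
    expect_equal(as.vector(voxel_to_world(v, pidx)), as.vector(w),
                 tolerance = 1e-12)
  }
  expect_error(crop_to_roi(v, roi_box(c(50, 50, 50), c(60, 60, 60))),
               "intersect")
})

test_that("the z-halving crop halves the slice count without moving voxels", {
  v <- image_volume(array(rnorm(10 * 10 * 12), c(10, 10, 12)),
                    spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0))
  ext_hi <- v$origin + (dim(v$data) - 0.5) * v$spacing
  roi <- roi_box(v$origin - 1, c(ext_hi[1] + 1, ext_hi[2] + 1,
                                 v$origin[3] + 6 * 0.5 - 0.25))
  vc <- crop_to_roi(v, roi)
  expect_equal(dim(vc$data), c(10, 10, 6))
  expect_identical(vc$data, v$data[, , 1:6])
  expect_equal(vc$origin, v$origin)
})

test_that("downsampling preserves world placement and block means", {
  v <- image_volume(array(seq_len(8 * 8 * 8), c(8, 8, 8)),
                    spacing = c(0.2, 0.2, 0.2), origin = c(1, 2, 3))
  d <- downsample_volume(v, 2)
  expect_equal(dim(d$data), c(4, 4, 4))
  expect_equal(d$data[1, 1, 1], mean(v$data[1:2, 1:2, 1:2]))
  expect_equal(as.vector(voxel_to_world(d, matrix(c(1, 1, 1), 1))),
               as.vector(colMeans(voxel_to_world(v, as.matrix(expand.grid(1:2, 1:2, 1:2))))),
               tolerance = 1e-12)
})

test_that("resampling: identity copy, constant invariance, interpolation error bound", {
  v <- smooth_volume()
  r0 <- resample(v, rigid_transform(), v)
  expect_equal(r0$data, v$data, tolerance = 1e-12)

  vc <- image_volume(array(7, c(10, 10, 10)), spacing = c(0.5, 0.5, 0.5))
  t1 <- make_rigid(t = c(0.5, -0.5, 1))  # whole-voxel translation
  rc <- resample(vc, t1, vc, fill = 7)
  expect_equal(rc$data, vc$data, tolerance = 1e-12)

  # +0.5 then -0.5 voxel: two linear interpolations smooth the field; the
  # error is bounded by the second difference of the (smooth) volume
  h <- v$spacing[1]
  fwd <- resample(v, make_rigid(t = c(h / 2, 0, 0)), v, fill = NA)
  back <- resample(fwd, make_rigid(t = c(-h / 2, 0, 0)), v, fill = NA)
  inner <- 3:(dim(v$data)[1] - 2)
  err <- abs(back$data[inner, , ] - v$data[inner, , ])
  d2 <- abs(v$data[inner + 1, , ] - 2 * v$data[inner, , ] + v$data[inner - 1, , ])
  expect_lt(mean(err), mean(d2) / 2 + 1e-9)
})

test_that("volume constructor validates geometry", {
  expect_error(image_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)), "spacing")
  expect_error(image_volume(array(0, c(4, 4, 4)),
                            direction = matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1), 3)),
               "orthonormal")
})
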