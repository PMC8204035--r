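test_that("livewire cost terms behave on canonical images", {
  expect_warning(co <- livewire_cost(matrix(5, 20, 20)), "constant")
  expect_lt(max(co) - min(co), 1e-12)

  img <- matrix(0, 30, 30); img[, 16:30] <- 100
  co <- livewire_cost(img)
  interior <- co[5:25, 3:28]
  expect_equal(which.min(colMeans(co[5:25, ])), 15)

  set.seed(1)
  r <- matrix(runif(400, 0, 10), 20, 20)
  p <- livewire_params()
  co <- livewire_cost(r, p)
  expect_gte(min(co), 0)
  expect_lte(max(co), p$w_g + p$w_z + p$w_d + 1e-12)
  expect_error(livewire_params(w_g = -1), "non-negative")
})

test_that("livewire paths are cost-optimal and track circular boundaries", {
  co <- matrix(1, 20, 20)
  p <- livewire_path(co, c(3, 3), c(3, 3))
  expect_equal(nrow(p), 1)

  p <- livewire_path(co, c(3, 4), c(10, 18))
  expect_equal(nrow(p) - 1, max(abs(c(10, 18) - c(3, 4))))  # Chebyshev length

  # cost equals an independent O(V^2) Dijkstra on random grids
  set.seed(14)
  for (i in 1:4) {
    co <- matrix(runif(20 * 20, 0.1, 1), 20, 20)
    s <- c(sample(20, 1), sample(20, 1)); g <- c(sample(20, 1), sample(20, 1))
    pp <- livewire_path(co, s, g)
    expect_equal(attr(pp, "cost"), brute_dijkstra_cost(co, s, g),
                 tolerance = 1e-12)
  }

  # synthetic disk with a sharp edge: path follows the circle
  n <- 80; cx <- 40.5; cy <- 40.5; r <- 30
  img <- outer(1:n, 1:n, function(i, j) ifelse((i - cx)^2 + (j - cy)^2 <= r^2, 100, 0))
  set.seed(3)
  img <- img + matrix(rnorm(n * n, 0, 2), n, n)
  co <- livewire_cost(img)
  pth <- livewire_path(co, c(round(cx + r), round(cy)), c(round(cx - r), round(cy)))
  d <- abs(sqrt((pth[, 1] - cx)^2 + (pth[, 2] - cy)^2) - r)
  expect_gte(mean(d <= 1), 0.95)
})

test_that("contours close, normalize orientation, and reject self-intersections", {
  segs <- list(rbind(c(2, 2), c(2, 3), c(2, 4)), rbind(c(2, 4), c(3, 4), c(4, 4)),
               rbind(c(4, 4), c(4, 3), c(4, 2)), rbind(c(4, 2), c(3, 2), c(2, 2)))
  meta <- list(axis = "axial", index = 5L, origin = c(0, 0), spacing = c(1, 1))
  cc <- close_contour(segs, meta)
  expect_s3_class(cc, "slice_contour")
  expect_equal(abs(erupt3d:::.shoelace(cc$points)), 4)
  # reversed segment order and direction give the same polygon
  cc2 <- close_contour(rev(lapply(segs, function(s) s[nrow(s):1, ])), meta)
  expect_equal(erupt3d:::.shoelace(cc2$points), erupt3d:::.shoelace(cc$points))

  expect_error(slice_contour("axial", 1, rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
               "self-intersecting")
  expect_error(close_contour(list(segs[[1]], segs[[3]]), meta), "chain")
})

test_that("a livewire-traced disk contour recovers the disk area", {
  n <- 80; cx <- 40.5; cy <- 40.5; r <- 25
  img <- outer(1:n, 1:n, function(i, j) ifelse((i - cx)^2 + (j - cy)^2 <= r^2, 100, 0))
  co <- livewire_cost(img)
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  anchors <- cbind(round(cx + r * cos(ang)), round(cy + r * sin(ang)))
  segs <- lapply(1:8, function(a)
    livewire_path(co, anchors[a, ], anchors[if (a == 8) 1 else a + 1, ]))
  cc <- close_contour(segs, list(axis = "axial", index = 1L, origin = c(0, 0),
                                 spacing = c(1, 1)))
  expect_equal(abs(erupt3d:::.shoelace(cc$points)), pi * r^2, tolerance = 0.03)
})

test_that("shape-based interpolation reconstructs and constrains as specified", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- function(r, c0 = c(5, 5)) cbind(c0[1] + r * cos(th), c0[2] + r * sin(th))
  tgt <- image_volume(array(0, c(60, 60, 12)), spacing = c(0.2, 0.2, 0.2))

  # identical circles: every intermediate slice reproduces the input disk
  cons <- list(slice_contour("axial", 1, circ(3)), slice_contour("axial", 9, circ(3)))
  m <- interpolate_contours(cons, tgt)
  ref <- m$data[, , 1]
  for (k in 2:8) {
    dice <- 2 * sum(m$data[, , k] & ref) / (sum(m$data[, , k]) + sum(ref))
    expect_gte(dice, 0.98)
  }
  expect_equal(sum(m$data[, , 10:12]), 0)  # contraction beyond the last slice

  # linear radius interpolation: r = 1 and r = 2 mm meet at 1.5 mm mid-way
  cons2 <- list(slice_contour("axial", 1, circ(1)), slice_contour("axial", 11, circ(2)))
  m2 <- interpolate_contours(cons2, tgt)
  r_mid <- sqrt(sum(m2$data[, , 6]) * prod(tgt$spacing[1:2]) / pi)
  expect_equal(r_mid, 1.5, tolerance = 0.2 / 1.5)

  # an orthogonal constraint can only shrink the result
  cons3 <- c(cons2, list(slice_contour("sagittal", 25,
                                       cbind(5 + cos(th), 1.2 + sin(th)))))
  m3 <- interpolate_contours(cons3, tgt)
  expect_lte(sum(m3$data), sum(m2$data))

  expect_error(interpolate_contours(cons2[1], tgt), "at least two")
  expect_error(interpolate_contours(c(cons2, cons2[1]), tgt), "same slice")
})

test_that("threshold segmentation recovers phantom volumes", {
  spec0 <- fast_spec(noise_sd = 0)
  pair0 <- generate_pair(spec0)
  ints <- spec0$intensities
  band <- c((ints["bone"] + ints["tooth"]) / 2, Inf)
  mesh0 <- auto_segment(pair0$pre, band)
  truth_vol <- mesh_volume(pair0$truth_tooth_pre)
  expect_equal(mesh_volume(mesh0), truth_vol, tolerance = 0.03)

  pair5 <- generate_pair(fast_spec(noise_sd = 0.05 * ints["bone"], seed = 2))
  mesh5 <- auto_segment(pair5$pre, band)
  expect_equal(mesh_volume(mesh5), truth_vol, tolerance = 0.05)

  expect_error(auto_segment(pair0$pre, c(1e6, Inf)), "empty selection")
  expect_error(threshold_segment(pair0$pre, 10, 5), "lo < hi")
})

test_that("anchor-jittered livewire segmentation stays volume-accurate", {
  spec <- phantom_spec(seed = 4)  # clinical 0.2 mm voxels
  pair <- generate_pair(spec)
  ints <- spec$intensities
  mesh <- segment_tooth_livewire(pair$pre,
                                 c((ints["bone"] + ints["tooth"]) / 2, Inf),
                                 seed = 5)
  expect_true(edge_census(mesh)$closed)
  expect_equal(mesh_volume(mesh), tooth_volume_analytic(spec), tolerance = 0.05)
})
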