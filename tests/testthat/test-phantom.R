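test_that("tooth solid volume has the right closed form", {
  # sphere limit: exponent 2, no root
  ssp <- phantom_spec(crown_radius = 5, crown_exponent = 2, root_length = 0)
  expect_equal(tooth_volume_analytic(ssp), 4 / 3 * pi * 125, tolerance = 1e-12)
  mesh <- make_tooth_mesh(ssp)
  expect_equal(mesh_volume(mesh), 523.5988, tolerance = 0.02)
  expect_true(edge_census(mesh)$closed)
})

test_that("the default canine-like tooth brackets reported canine volumes", {
  spec <- phantom_spec()
  va <- tooth_volume_analytic(spec)
  expect_gt(va, 300)
  expect_lt(va, 600)
  mesh <- make_tooth_mesh(spec)
  expect_equal(mesh_volume(mesh), va, tolerance = 0.02)
  expect_true(edge_census(mesh)$closed)
})

test_that("degenerate tooth parameters are rejected", {
  expect_error(phantom_spec(crown_radius = 0), "positive")
  expect_error(phantom_spec(root_taper = 2), "root")
  expect_error(phantom_spec(intensities = c(background = 100, bone = 50, tooth = 160)),
               "ordered")
})

test_that("generate_pair is deterministic and consistent with its ground truth", {
  spec <- fast_spec(seed = 7)
  p1 <- generate_pair(spec)
  p2 <- generate_pair(spec)
  expect_identical(p1$pre$data, p2$pre$data)
  expect_identical(p1$post$data, p2$post$data)

  # identity motions without noise give identical scans
  p0 <- generate_pair(fast_spec(noise_sd = 0))
  expect_identical(p0$pre$data, p0$post$data)

  # tooth voxel volume within 5 percent of the analytic solid volume
  ints <- spec$intensities
  nt <- sum(p1$pre$data > (ints["bone"] + ints["tooth"]) / 2)
  expect_equal(nt * spec$voxel_mm^3, tooth_volume_analytic(spec), tolerance = 0.05)

  # truth meshes: local then global motion maps pre onto post exactly
  moved <- transform_mesh(p1$truth_tooth_pre,
                          compose_transforms(p1$truth_global, p1$truth_local))
  expect_lt(max(abs(moved$vertices - p1$truth_tooth_post$vertices)), 1e-9)
})

test_that("a tooth pushed out of the grid is refused with the offending pose", {
  spec <- fast_spec()
  spec$local_motion <- make_rigid(t = c(0, 0, 40))
  expect_error(generate_pair(spec), "leaves the grid")
})

test_that("batch generation draws distinct motions and a coherent truth table", {
  expect_equal(length(batch_generate(0, fast_spec(), integer(0))$pairs), 0)
  b <- batch_generate(3, fast_spec(), seed_list = 1:3)
  expect_length(b$pairs, 3)
  tr <- vapply(b$pairs, function(p) p$truth_local[1, 4], 0)
  expect_equal(length(unique(tr)), 3)
  expect_true(all(abs(b$truth[, c("dMD", "dPF", "dIA")]) <= 3))
  expect_true(all(abs(b$truth[, c("pitch", "roll", "yaw")]) <= 8))
  # the drawn components reproduce the truth transform through compose_motion
  for (i in 1:3) {
    ctr <- drop(transform_points(b$pairs[[i]]$spec$tooth_pose_pre, c(0, 0, 0)))
    t <- compose_motion(b$truth$dMD[i], b$truth$dPF[i], b$truth$dIA[i],
                        b$truth$pitch[i], b$truth$roll[i], b$truth$yaw[i],
                        anatomical_frame(diag(3), origin = ctr), ctr)
    expect_lt(max(abs(unclass(t) - unclass(b$pairs[[i]]$truth_local))), 1e-12)
  }
  # truth table round-trips through CSV
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(b$truth, tf, row.names = FALSE)
  back <- utils::read.csv(tf)
  expect_equal(back$dIA, b$truth$dIA, tolerance = 1e-12)
  expect_warning(batch_generate(2, fast_spec(), seed_list = c(5, 5)), "duplicate")
})
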