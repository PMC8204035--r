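coarse_tooth <- function() make_tooth_mesh(phantom_spec(), resolution = 0.5)

test_that("ICP returns the identity for identical meshes", {
  m <- coarse_tooth()
  t <- icp_register(m, m)
  expect_rigid_close(t, rigid_transform(), 1e-6, 1e-5)
})

test_that("ICP recovers known rigid motions on clean meshes", {
  m <- coarse_tooth()
  frame <- anatomical_frame(diag(3))
  set.seed(23)
  for (i in 1:3) {
    truth <- compose_motion(runif(1, -3, 3), runif(1, -3, 3), runif(1, -3, 3),
                            runif(1, -8, 8), runif(1, -8, 8), runif(1, -8, 8),
                            frame, mesh_centroid(m))
    tgt <- transform_mesh(m, truth)
    est <- icp_register(m, tgt)
    expect_rigid_close(est, truth, 1e-3, 0.01)
  }
})

test_that("trimmed ICP withstands local vertex corruption", {
  m <- coarse_tooth()
  frame <- anatomical_frame(diag(3))
  truth <- compose_motion(1.0, -0.8, 1.5, 3, -2, 4, frame, mesh_centroid(m))
  tgt <- transform_mesh(m, truth)
  set.seed(24)
  nbad <- round(0.2 * nrow(tgt$vertices))
  bad <- sample(nrow(tgt$vertices), nbad)
  dirs <- matrix(rnorm(3 * nbad), nbad, 3)
  tgt$vertices[bad, ] <- tgt$vertices[bad, ] +
    dirs / sqrt(rowSums(dirs^2))
  est <- icp_register(m, tgt, icp_params(trim = 0.25))
  expect_rigid_close(est, truth, 0.05, 0.1)
})

test_that("ICP reports its convergence and refuses hopeless budgets", {
  m <- coarse_tooth()
  rot <- compose_motion(0.5, 0, 0, 8, 6, 5, anatomical_frame(diag(3)),
                        mesh_centroid(m))
  tgt <- transform_mesh(m, rot)
  expect_error(icp_register(m, tgt, icp_params(max_iterations = 2L)),
               "did not converge")
  est <- icp_register(m, tgt)
  meta <- attr(est, "metadata")
  expect_true(length(meta$rms_history) == meta$iterations)
  expect_lt(meta$rms, 0.01)
})

test_that("assess_eruption returns all-zero measures for an unmoved tooth", {
  m <- coarse_tooth()
  frame <- anatomical_frame(diag(3), origin = mesh_centroid(m))
  res <- assess_eruption(m, m, frame)
  expect_lt(max(abs(coef(res))), 1e-5)
  expect_equal(res$volume_pre, res$volume_post)
  expect_s3_class(res, "eruption_measures")
  df <- as.data.frame(res)
  expect_named(df, c("dMD", "dPF", "dIA", "pitch", "roll", "yaw",
                     "volume_pre", "volume_post"))
})

test_that("assess_eruption matches the composed ground truth on clean meshes", {
  m <- coarse_tooth()
  frame <- anatomical_frame(diag(3), origin = mesh_centroid(m))
  ctr <- mesh_centroid(m)
  truth <- c(1.4, 1.4, 2.4, 4.5, 6.3, 6.0)
  t <- compose_motion(truth[1], truth[2], truth[3], truth[4], truth[5],
                      truth[6], frame, ctr)
  res <- assess_eruption(m, transform_mesh(m, t), frame)
  expect_equal(unname(coef(res)), truth, tolerance = 0.02)
})
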