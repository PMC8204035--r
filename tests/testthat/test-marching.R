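test_that("marching tetrahedra surfaces a voxelized sphere accurately", {
  h <- 0.2; r <- 5
  n <- ceiling(2 * (r + 2) / h)
  g0 <- -(n - 1) * h / 2
  vol <- image_volume(array(0, c(n, n, n)), spacing = rep(h, 3),
                      origin = rep(g0, 3))
  pts <- voxel_centers(vol)
  vol$data[] <- as.numeric(rowSums(pts^2) <= r^2)
  mesh <- mesh_from_mask(vol)
  expect_true(edge_census(mesh)$closed)
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_equal(mesh_centroid(mesh), c(0, 0, 0), tolerance = 1e-6)
})

test_that("a single voxel meshes to a closed solid of half a voxel volume", {
  # the 6-tet decomposition of the single-cube neighbourhood cuts the voxel
  # cell to exactly half its volume (octahedron-like solid over edge midpoints)
  sv <- array(0, c(5, 5, 5)); sv[3, 3, 3] <- 1
  m <- mesh_from_mask(image_volume(sv, spacing = c(0.3, 0.3, 0.3)))
  expect_true(edge_census(m)$closed)
  expect_equal(mesh_volume(m), 0.5 * 0.3^3, tolerance = 1e-9)
})

test_that("gray-value isosurfacing places vertices subvoxel-accurately", {
  m <- sphere_mesh(r = 4, h = 0.4)
  expect_true(edge_census(m)$closed)
  radii <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(radii - 4)), 0.05)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 64, tolerance = 0.01)
})

test_that("largest-component selection and empty masks behave", {
  a <- array(0, c(12, 12, 12))
  a[2:9, 2:9, 2:9] <- 1      # big block
  a[11, 11, 11] <- 1         # lone voxel
  m <- mesh_from_mask(image_volume(a, spacing = c(1, 1, 1)))
  # the lone voxel (center at world (10,10,10)) must not be surfaced
  expect_lt(max(m$vertices), 9.1)
  expect_equal(mesh_volume(m), 8^3, tolerance = 0.02)
  expect_error(mesh_from_mask(image_volume(array(0, c(4, 4, 4)))), "empty")
})

test_that("mesh volume is rigid-motion invariant and requires closedness", {
  m <- sphere_mesh(r = 2, h = 0.4)
  v0 <- mesh_volume(m)
  t1 <- make_rigid(axis_angle_to_rotation(c(0.3, 0.1, -0.4)), t = c(10, -5, 2))
  expect_equal(mesh_volume(transform_mesh(m, t1)), v0, tolerance = 1e-9)
  open_mesh <- triangle_mesh(m$vertices, m$faces[-1, , drop = FALSE])
  expect_error(mesh_volume(open_mesh), "boundary")
})
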