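test_that("extracted sphere surface recovers the closed-form volume", {
  vol <- ball_volume(11, 0.4)
  mesh <- extract_surface(vol, "globe")
  expect_true(mesh_is_watertight(mesh))
  vt <- 4 / 3 * pi * 11^3
  expect_lt(abs(mesh_volume(mesh) - vt) / vt, 0.02)
})

test_that("degenerate and multi-piece masks are handled per contract", {
  a <- array(0L, c(9, 9, 9))
  a[5, 5, 5] <- 1L
  vol <- label_volume(a, 0.4, label_map = c(globe = 1L))
  mesh <- extract_surface(vol, "globe")
  expect_true(mesh_is_watertight(mesh))
  vv <- 0.4^3
  expect_gt(mesh_volume(mesh), vv / 2 - 1e-12)
  expect_lt(mesh_volume(mesh), vv * 2)

  # empty component errors rather than returning an empty mesh
  b <- array(0L, c(9, 9, 9))
  volb <- label_volume(b, 0.4, label_map = c(globe = 1L))
  expect_error(extract_surface(volb, "globe"), class = "bq_missing_component")

  # two disjoint balls: largest_only keeps the big one
  n <- 61
  ax <- (seq_len(n) - 1) * 0.4
  r2a <- outer(outer((ax - 6)^2, (ax - 6)^2, "+"), (ax - 6)^2, "+")
  r2b <- outer(outer((ax - 18)^2, (ax - 18)^2, "+"), (ax - 18)^2, "+")
  two <- array(as.integer(r2a <= 4^2 | r2b <= 2^2), c(n, n, n))
  volc <- label_volume(two, 0.4, label_map = c(globe = 1L))
  expect_error(extract_surface(volc, "globe"), class = "bq_topology")
  mesh <- extract_surface(volc, "globe", largest_only = TRUE)
  vt <- 4 / 3 * pi * 4^3
  expect_lt(abs(mesh_volume(mesh) - vt) / vt, 0.05)
})

test_that("smoothing preserves volume, identity at zero iterations, bounded displacement", {
  vol <- ball_volume(8, 0.4)
  mesh <- extract_surface(vol, "globe")
  sm <- smooth_fit(mesh)
  expect_true(mesh_is_watertight(sm))
  expect_lt(abs(mesh_volume(sm) - mesh_volume(mesh)) / mesh_volume(mesh), 0.01)

  expect_identical(smooth_fit(mesh, iterations = 0L), mesh)

  cube <- array(0L, c(19, 19, 19))
  cube[5:15, 5:15, 5:15] <- 1L
  cv <- label_volume(cube, 0.5, label_map = c(globe = 1L))
  cm <- extract_surface(cv, "globe")
  cs <- smooth_fit(cm)
  disp <- sqrt(rowSums((cs$vertices - cm$vertices)^2))
  expect_lt(max(disp), 2 * 0.5)
})

test_that("voxelization recovers analytic volumes and converges with resolution", {
  # axis-aligned unit cube
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- triangle_mesh(v, f, component = "cube")
  vx <- voxelize_mesh(cube, 0.1)
  expect_lt(abs(sum(vx$voxels) * 0.1^3 - 1), 0.005)

  sph <- icosphere(5, subdiv = 4)
  vt <- 4 / 3 * pi * 125
  vol01 <- sum(voxelize_mesh(sph, 0.1)$voxels) * 0.1^3
  vol02 <- sum(voxelize_mesh(sph, 0.2)$voxels) * 0.2^3
  mv <- mesh_volume(sph)
  expect_lt(abs(vol01 - vt) / vt, 0.005)
  expect_lte(abs(vol01 - mv), abs(vol02 - mv))

  expect_error(voxelize_mesh(cube, -0.1), class = "bq_input")
  open_mesh <- structure(list(vertices = v, faces = f[-1, , drop = FALSE],
                              component = "open"), class = "triangle_mesh")
  expect_error(voxelize_mesh(open_mesh, 0.1), class = "bq_topology")
})

test_that("voxelize(extract_surface(mask)) round trip is near-lossless", {
  ph <- make_phantom(small_phantom_spec())
  for (comp in c("globe", "inner_bleb", "outer_bleb")) {
    mesh <- extract_surface(ph$volume, comp, largest_only = TRUE)
    back <- voxelize_mesh(mesh, ph$volume$spacing[1])
    ref <- ph$volume
    ref$voxels <- array(as.integer(component_mask(ph$volume, comp)),
                        dim(ph$volume$voxels))
    expect_gte(dice_between(ref, back), 0.98)
  }
})

test_that("surface and voxel volumes of phantom components agree at fine resolution", {
  ph <- make_phantom(small_phantom_spec())
  mesh <- extract_surface(ph$volume, "inner_bleb", largest_only = TRUE)
  vx <- voxelize_mesh(mesh, 0.1)
  vol_vox <- sum(vx$voxels) * 0.1^3
  expect_lt(abs(vol_vox - mesh_volume(mesh)) / mesh_volume(mesh), 0.01)
})

test_that("PLY round trip preserves geometry, NIfTI round trip preserves the volume", {
  mesh <- icosphere(3, subdiv = 2)
  ply <- tempfile(fileext = ".ply")
  write_ply(mesh, ply)
  back <- read_ply(ply)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$faces, mesh$faces)

  vol <- ball_volume(4, 0.5)
  nii <- tempfile(fileext = ".nii.gz")
  write_label_volume(vol, nii)
  rt <- read_label_volume(nii)
  expect_identical(rt$voxels, vol$voxels)
  expect_equal(rt$spacing, vol$spacing)
  expect_equal(rt$origin, vol$origin)
  expect_identical(rt$label_map, vol$label_map)
})
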