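test_that("ground-truth volumes are additive and deterministic", {
  sp <- small_phantom_spec()
  ph <- make_phantom(sp)
  tr <- ph$truth
  expect_identical(tr$volume_total,
                   tr$volume_inner + tr$volume_outer + tr$volume_plate)
  expect_gte(tr$height, sp$plate_extent[3])
  ph2 <- make_phantom(sp)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
  expect_identical(ph$truth, ph2$truth)
})

test_that("apex height is the thickness sum for a 2+1+2 mm stack", {
  sp <- small_phantom_spec()  # inner 2, plate 1, outer 2
  ph <- make_phantom(sp)
  expect_equal(ph$truth$height_apex, 5.0)
  # the curved-shell maximum span can only exceed the apex sum
  expect_gte(ph$truth$height, ph$truth$height_apex)
})

test_that("plate carries exactly the requested number of fenestration channels", {
  sp <- small_phantom_spec(fenestration_count = 4L)
  ph <- make_phantom(sp)
  vol <- ph$volume
  geo <- blebquant:::.phantom_geometry(sp)
  ax <- lapply(1:3, function(a)
    vol$origin[a] + (seq_len(dim(vol$voxels)[a]) - 1) * vol$spacing[a])
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  # bleb-labelled voxels inside the plate's radial band are the channels
  chan <- (vol$voxels == 3L | vol$voxels == 4L) & r > geo$R2 & r <= geo$R3
  lab <- blebquant:::.label_components6(chan, dim(chan))
  expect_identical(attr(lab, "n_components"), 4L)
})

test_that("non-merged blebs only touch through fenestrations; merged blebs touch at the rim", {
  ph <- make_phantom(small_phantom_spec(merged = FALSE))
  expect_false(as.logical(detect_merged(ph$volume)))
  phm <- make_phantom(small_phantom_spec(merged = TRUE))
  expect_true(as.logical(detect_merged(phm$volume)))
  expect_true(phm$truth$merged)
})

test_that("undersized grids fail with the violating dimension named", {
  sp <- small_phantom_spec(grid_shape = c(81, 81, 21))
  expect_error(make_phantom(sp), "z", class = "bq_sizing")
  expect_error(phantom_spec(globe_radius = -1), class = "bq_input")
  expect_error(phantom_spec(fenestration_count = -2), class = "bq_input")
})

test_that("mesh-pathway volume converges to ground truth as spacing shrinks", {
  err_at <- function(h) {
    ph <- make_phantom(small_phantom_spec(voxel_spacing = h))
    mesh <- extract_surface(ph$volume, "globe")
    vt <- 4 / 3 * pi * 8^3
    abs(mesh_volume(mesh) - vt) / vt
  }
  e_fine <- err_at(0.4)
  e_coarse <- err_at(0.8)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 0.02)
})

test_that("cohort simulation matches its distributional targets", {
  spec <- cohort_sim_spec(n_diplopia = 2000, n_control = 2000, seed = 42)
  co <- simulate_cohort(spec)
  med_d <- median_iqr(co$volume_total[co$diplopia])$median
  med_c <- median_iqr(co$volume_total[!co$diplopia])$median
  expect_lt(abs(med_d - 1023.3) / 1023.3, 0.05)
  expect_lt(abs(med_c - 804.6) / 804.6, 0.05)
  # restriction frequencies within binomial 99% bounds at n = 2000
  for (g in 1:2) {
    p <- spec$restriction_probability_by_group[g]
    obs <- mean(co$restricted[if (g == 1) co$diplopia else !co$diplopia])
    half <- 2.576 * sqrt(p * (1 - p) / 2000)
    expect_lt(abs(obs - p), half + 1e-12)
  }
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
})

test_that("infeasible cohort parameters are rejected", {
  expect_error(cohort_sim_spec(volume_iqr_by_group =
                                 list(c(1750, 875), c(755, 923))),
               class = "bq_input")
  expect_error(cohort_sim_spec(restriction_probability_by_group = c(1.2, 0.3)),
               class = "bq_input")
  expect_error(cohort_sim_spec(n_diplopia = 0), class = "bq_input")
})
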