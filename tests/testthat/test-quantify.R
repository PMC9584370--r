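test_that("gap closure fills narrow gaps, leaves wide gaps, matches the brute-force oracle", {
  # two slabs 0.2 mm apart at 0.1 mm spacing: gap filled, halves split
  a <- array(0L, c(20, 20, 20))
  a[5:16, 5:16, 5:8] <- 1L
  a[5:16, 5:16, 11:14] <- 2L
  v <- label_volume(a, 0.1, label_map = c(globe = 1L, plate = 2L))
  cg <- close_gaps(v, 0.3)
  expect_identical(unique(as.vector(cg$voxels[5:16, 5:16, 9])), 1L)
  expect_identical(unique(as.vector(cg$voxels[5:16, 5:16, 10])), 2L)
  # labelled voxels never reassigned
  expect_identical(cg$voxels[a > 0L], a[a > 0L])

  # 1 mm gap stays open
  b <- array(0L, c(26, 26, 26))
  b[5:22, 5:22, 5:8] <- 1L
  b[5:22, 5:22, 19:22] <- 2L
  vb <- label_volume(b, 0.1, label_map = c(globe = 1L, plate = 2L))
  expect_identical(close_gaps(vb, 0.3)$voxels, b)

  # oracle equivalence on random small grids
  set.seed(61)
  for (case in 1:5) {
    g <- array(0L, c(14, 14, 14))
    ctrs <- matrix(runif(9, 3, 12), 3)
    ax <- seq_len(14)
    for (l in 1:3) {
      d2 <- outer(outer((ax - ctrs[l, 1])^2, (ax - ctrs[l, 2])^2, "+"),
                  (ax - ctrs[l, 3])^2, "+")
      g[d2 <= runif(1, 2, 3.5)^2 & g == 0L] <- l
    }
    gv <- label_volume(g, 0.2, label_map = c(a = 1L, b = 2L, c = 3L))
    expect_identical(close_gaps(gv, 0.5)$voxels,
                     oracle_fill_gaps(gv, 0.5)$voxels)
  }
})

test_that("gap closure is idempotent on gap-free phantoms and validates arguments", {
  ph <- make_phantom(small_phantom_spec())
  once <- close_gaps(ph$volume, 0.45)
  twice <- close_gaps(once, 0.45)
  expect_identical(twice$voxels, once$voxels)

  expect_error(close_gaps(ph$volume, -0.1), class = "bq_input")
  expect_warning(out <- close_gaps(ph$volume, 0.2), "below the voxel spacing")
  expect_identical(out$voxels, ph$volume$voxels)
})

test_that("component volumes count voxels and demand isotropy", {
  a <- array(0L, c(14, 14, 14))
  a[3:12, 3:12, 3:12] <- 1L
  v <- label_volume(a, 0.1, label_map = c(globe = 1L, plate = 2L))
  vols <- component_volumes(v)
  expect_equal(unname(vols["globe"]), 1.0)
  expect_equal(unname(vols["plate"]), 0.0)

  empty <- label_volume(array(0L, c(5, 5, 5)), 0.1)
  expect_equal(unname(component_volumes(empty)), rep(0, 4))

  aniso <- label_volume(a, c(0.1, 0.1, 0.2), label_map = c(globe = 1L))
  expect_error(component_volumes(aniso), "resample", class = "bq_anisotropic")

  ph <- make_phantom(small_phantom_spec())
  mv <- component_volumes(ph$volume)
  expect_equal(unname(mv["inner_bleb"]), ph$truth$volume_inner)
  expect_equal(unname(mv["plate"]), ph$truth$volume_plate)
})

test_that("plate plane normal matches slab symmetry, applied rotations, and patch mid-radial direction", {
  slab <- function(normal, half_th = 0.5, half_w = 5, h = 0.25) {
    n <- 61
    ax <- (seq_len(n) - 1) * h - (n - 1) / 2 * h
    x <- outer(outer(ax, rep(1, n), "*"), rep(1, n), "*")
    y <- outer(outer(rep(1, n), ax, "*"), rep(1, n), "*")
    z <- outer(outer(rep(1, n), rep(1, n), "*"), ax, "*")
    tproj <- x * normal[1] + y * normal[2] + z * normal[3]
    m <- abs(tproj) <= half_th & x^2 + y^2 + z^2 <= half_w^2
    arr <- array(0L, c(n, n, n))
    arr[m] <- 2L
    label_volume(arr, h, origin = rep(-(n - 1) / 2 * h, 3),
                 label_map = c(globe = 1L, plate = 2L))
  }
  pl <- fit_plate_plane(slab(c(0, 0, 1)), globe_center = c(0, 0, -10))
  expect_gt(abs(sum(pl$normal * c(0, 0, 1))), 0.999)
  expect_gt(sum(pl$normal * c(0, 0, 1)), 0)   # oriented away from the globe

  th <- 30 * pi / 180
  nr <- c(0, -sin(th), cos(th))
  pl2 <- fit_plate_plane(slab(nr), globe_center = -10 * nr)
  ang <- acos(min(abs(sum(pl2$normal * nr)), 1)) * 180 / pi
  expect_lt(ang, 1)

  # spherical patch subtending ~60 degrees: normal near the patch axis
  sp <- small_phantom_spec(plate_extent = c(16, 16, 1),
                           plate_offset_angle = 25, plate_azimuth = 40)
  ph <- make_phantom(sp)
  geo <- blebquant:::.phantom_geometry(sp)
  pl3 <- fit_plate_plane(ph$volume)
  ang3 <- acos(min(abs(sum(pl3$normal * geo$u)), 1)) * 180 / pi
  expect_lt(ang3, 5)
  expect_gt(sum(pl3$normal * geo$u), 0)

  few <- array(0L, c(6, 6, 6)); few[1:2, 1, 1] <- 2L
  vf <- label_volume(few, 0.5, label_map = c(globe = 1L, plate = 2L))
  expect_error(fit_plate_plane(vf, c(0, 0, 0)), class = "bq_degenerate")
})

test_that("complex height adds thicknesses for coaxial stacks and is rotation invariant", {
  h <- 0.2
  stack_vol <- function(normal) {
    n <- 81
    ax <- (seq_len(n) - 1) * h - (n - 1) / 2 * h
    x <- outer(outer(ax, rep(1, n), "*"), rep(1, n), "*")
    y <- outer(outer(rep(1, n), ax, "*"), rep(1, n), "*")
    z <- outer(outer(rep(1, n), rep(1, n), "*"), ax, "*")
    tp <- x * normal[1] + y * normal[2] + z * normal[3]
    lat2 <- x^2 + y^2 + z^2 - tp^2
    arr <- array(0L, c(n, n, n))
    arr[lat2 <= 16 & tp > -2.5 & tp <= -0.5] <- 3L   # inner, 2 mm
    arr[lat2 <= 16 & tp > -0.5 & tp <= 0.5] <- 2L    # plate, 1 mm
    arr[lat2 <= 16 & tp > 0.5 & tp <= 2.5] <- 4L     # outer, 2 mm
    label_volume(arr, h, origin = rep(-(n - 1) / 2 * h, 3))
  }
  v1 <- stack_vol(c(0, 0, 1))
  ht1 <- complex_height(v1, fit_plate_plane(v1, globe_center = c(0, 0, -10)))
  expect_lt(abs(ht1 - 5), 2 * h)

  th <- 25 * pi / 180
  nr <- c(sin(th), 0, cos(th))
  v2 <- stack_vol(nr)
  ht2 <- complex_height(v2, fit_plate_plane(v2, globe_center = -10 * nr))
  expect_lt(abs(ht2 - ht1), 2 * h)

  # phantom recovery against analytic construction
  ph <- make_phantom(small_phantom_spec(voxel_spacing = 0.3))
  m_h <- complex_height(ph$volume)
  expect_lt(abs(m_h - ph$truth$height), 2 * 0.3)

  # merged single-bleb convention: one bleb plays both roles
  single <- v1
  single$voxels[single$voxels == 4L] <- 3L
  ht3 <- complex_height(single,
                        fit_plate_plane(single, globe_center = c(0, 0, -10)))
  expect_lt(abs(ht3 - 5), 2 * h)

  # components side by side instead of stacked: geometry error
  side <- array(0L, c(30, 30, 30))
  side[2:9, 2:29, 2:29] <- 3L
  side[21:28, 2:29, 2:29] <- 4L
  side[12:18, 2:29, 2:29] <- 2L
  vs <- label_volume(side, 0.2)
  plane <- structure(list(point = c(3, 3, 3), normal = c(0, 0, 1)),
                     class = "plate_plane")
  expect_error(complex_height(vs, plane), class = "bq_geometry")
})

test_that("merged detection distinguishes rim contact from fenestration contact", {
  # plate fully separating: never merged
  a <- array(0L, c(20, 20, 20))
  a[3:18, 3:18, 3:6] <- 3L
  a[3:18, 3:18, 7:10] <- 2L
  a[3:18, 3:18, 11:14] <- 4L
  v <- label_volume(a, 0.2)
  attr(v, "fenestrations") <- list(center = c(0, 0, 0),
                                   directions = matrix(c(0, 0, 1), 1),
                                   radius = 0.4)
  expect_false(as.logical(detect_merged(v)))

  # direct contact without fenestration info: any-contact fallback, flagged
  b <- a
  b[3:18, 3:18, 7:10] <- 4L   # replace plate with outer bleb: contact
  vb <- label_volume(b, 0.2)
  expect_warning(res <- detect_merged(vb), "any-contact")
  expect_true(as.logical(res))
  expect_identical(attr(res, "rule"), "any_contact")

  expect_error(detect_merged(v <- label_volume(array(0L, c(4, 4, 4)), 0.2)),
               class = "bq_missing_component")
})

test_that("large-bleb classification applies the strict 1100 mm^3 rule", {
  expect_true(classify_large_bleb(1736.5))
  expect_false(classify_large_bleb(1100.0))
  expect_false(classify_large_bleb(804.6))
  expect_error(classify_large_bleb(-5), class = "bq_input")
})

test_that("measure composes the stages deterministically and stably across resolutions", {
  ph <- make_phantom(small_phantom_spec(voxel_spacing = 0.3))
  m1 <- measure(ph$volume)
  m2 <- measure(ph$volume)
  expect_identical(m1, m2)
  expect_lt(abs(m1$volume_inner - ph$truth$volume_inner) /
              ph$truth$volume_inner, 0.01)
  expect_lt(abs(m1$height - ph$truth$height), 2 * 0.3)
  expect_identical(m1$merged, ph$truth$merged)
  expect_identical(m1$large_bleb, m1$volume_total > 1100)

  # re-voxelized at half the grid spacing through the mesh pathway
  mr <- measure(ph$volume, measure_config(resolution = 0.15))
  expect_lt(abs(mr$volume_total - m1$volume_total) / m1$volume_total, 0.01)
  expect_equal(mr$resolution_used, 0.15)

  # stage failures carry the stage name
  broken <- ph$volume
  broken$voxels[broken$voxels == 2L] <- 0L
  err <- tryCatch(measure(broken), error = identity)
  expect_s3_class(err, "bq_stage")
  expect_match(conditionMessage(err), "fit_plate_plane")
})

test_that("inflating bleb thickness strictly increases measured volume and height", {
  cfg <- measure_config(max_gap = 0.45)
  thin <- measure(make_phantom(small_phantom_spec(
    inner_bleb_thickness = 1.5, outer_bleb_thickness = 1.5))$volume, cfg)
  thick <- measure(make_phantom(small_phantom_spec(
    inner_bleb_thickness = 2.5, outer_bleb_thickness = 2.5))$volume, cfg)
  expect_gt(thick$volume_total, thin$volume_total)
  expect_gt(thick$height, thin$height)
})
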