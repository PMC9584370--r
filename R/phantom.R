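#' Specification of a synthetic orbital phantom
#'
#' The phantom emulates the geometry the segmentation pipeline sees on 3D MR
#' images of an eye with a Baerveldt implant: a spherical globe, a curved
#' silicone plate conforming to the sclera (modelled as a spherical-shell
#' patch concentric with the globe, with fenestration holes), an inner bleb
#' shell between globe and plate and an outer bleb shell on top of the plate.
#' When `merged = TRUE` the bleb shells extend past the plate rim and touch at
#' the edges, mimicking the one-large-bleb configuration seen in 6/30 study
#' patients.
#'
#' Defaults correspond to a typical adult eye (globe radius 11.5 mm) with a
#' 350 mm^2-class implant plate (arc extent 32 x 14 mm, 1 mm thick, 4
#' fenestrations) at the imaging study's reconstruction resolution of 0.4 mm.
#'
#' @param globe_radius Globe radius, mm.
#' @param plate_extent `c(width, length, thickness)` in mm; width and length
#'   are arc lengths of the plate patch at its mid radius.
#' @param plate_offset_angle Polar angle of the plate-patch axis away from the
#'   grid +z axis, degrees.
#' @param plate_azimuth Azimuth of that axis, degrees.
#' @param inner_bleb_thickness,outer_bleb_thickness Radial shell thicknesses, mm.
#' @param fenestration_count Number of fenestration holes in the plate.
#' @param fenestration_radius Hole radius, mm.
#' @param merged Should the blebs touch around the plate rim?
#' @param voxel_spacing Isotropic voxel edge, mm.
#' @param grid_shape Integer triple; `NULL` sizes the grid to fit the geometry
#'   with a 2 mm margin.
#' @param bleb_footprint Bleb angular footprint as a fraction of the plate's
#'   (values > 1 only make sense together with `merged = TRUE`).
#' @param seed Recorded for provenance; construction itself is deterministic.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(globe_radius = 11.5,
                         plate_extent = c(32, 14, 1),
                         plate_offset_angle = 30,
                         plate_azimuth = 0,
                         inner_bleb_thickness = 2,
                         outer_bleb_thickness = 2,
                         fenestration_count = 4L,
                         fenestration_radius = 0.5,
                         merged = FALSE,
                         voxel_spacing = 0.4,
                         grid_shape = NULL,
                         bleb_footprint = if (merged) 1.25 else 0.85,
                         seed = 1L) {
  spec <- list(globe_radius = globe_radius, plate_extent = plate_extent,
               plate_offset_angle = plate_offset_angle,
               plate_azimuth = plate_azimuth,
               inner_bleb_thickness = inner_bleb_thickness,
               outer_bleb_thickness = outer_bleb_thickness,
               fenestration_count = as.integer(fenestration_count),
               fenestration_radius = fenestration_radius,
               merged = isTRUE(merged), voxel_spacing = voxel_spacing,
               grid_shape = grid_shape, bleb_footprint = bleb_footprint,
               seed = as.integer(seed))
  lengths_pos <- c(globe_radius, plate_extent, inner_bleb_thickness,
                   outer_bleb_thickness, fenestration_radius, voxel_spacing,
                   bleb_footprint)
  if (any(!is.finite(lengths_pos)) || any(lengths_pos <= 0))
    .stop2("all phantom lengths must be positive", class = "bq_input")
  if (spec$fenestration_count < 0)
    .stop2("fenestration_count must be >= 0", class = "bq_input")
  class(spec) <- "phantom_spec"
  spec
}

.phantom_geometry <- function(spec) {
  R1 <- spec$globe_radius
  R2 <- R1 + spec$inner_bleb_thickness
  R3 <- R2 + spec$plate_extent[3]
  R4 <- R3 + spec$outer_bleb_thickness
  rmid <- (R2 + R3) / 2
  # plate angular half-extents from arc lengths at the mid radius
  aw <- spec$plate_extent[1] / (2 * rmid)   # along e1 (width)
  al <- spec$plate_extent[2] / (2 * rmid)   # along e2 (length)
  if (max(aw, al) * spec$bleb_footprint >= pi / 2)
    .stop2("bleb footprint reaches the equator; shrink plate_extent or bleb_footprint",
           class = "bq_input")
  pol <- spec$plate_offset_angle * pi / 180
  azi <- spec$plate_azimuth * pi / 180
  u <- c(sin(pol) * cos(azi), sin(pol) * sin(azi), cos(pol))
  # tangent frame: e1 = width direction, e2 = length direction
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(R1 = R1, R2 = R2, R3 = R3, R4 = R4, rmid = rmid,
       aw = aw, al = al, u = u, e1 = e1, e2 = e2)
}

.fenestration_directions <- function(spec, geo) {
  k <- spec$fenestration_count
  if (k == 0L) return(NULL)
  psi <- pi / 4 + 2 * pi * (seq_len(k) - 1) / k
  t(vapply(psi, function(p) {
    # polar boundary angle of the plate footprint ellipse at azimuth p
    tmax <- 1 / sqrt((cos(p) / geo$aw)^2 + (sin(p) / geo$al)^2)
    th <- 0.45 * tmax
    d <- cos(th) * geo$u +
      sin(th) * (cos(p) * geo$e1 + sin(p) * geo$e2)
    d / sqrt(sum(d^2))
  }, numeric(3)))
}

#' Analytic ground truth of a generated phantom
#'
#' Volumes are exact voxel counts of the generated label map times the voxel
#' volume, so volume additivity holds exactly by construction.  `height` is
#' the analytic value of the measurement definition (largest column-wise
#' outer-surface to outer-surface span perpendicular to the plate), which for
#' a curved shell is attained at the bleb footprint edge:
#' `sqrt(R4^2 - R1^2 sin^2(tb)) - R1 cos(tb)` with `tb` the largest bleb
#' half-angle.  `height_apex` is the plain thickness sum
#' inner + plate + outer along the patch axis; the two coincide as the
#' footprint narrows.
#'
#' @name phantom_ground_truth
NULL

#' Generate a synthetic orbital phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (a [label_volume()] carrying the
#'   fenestration geometry as an attribute) and `truth` (ground-truth volumes
#'   in mm^3, heights in mm, and the merged flag).
#' @seealso [phantom_ground_truth]
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- .phantom_geometry(spec)
  h <- spec$voxel_spacing
  need <- geo$R4 + 2                         # geometry + 2 mm margin
  if (is.null(spec$grid_shape)) {
    n <- 2L * as.integer(ceiling(need / h)) + 1L
    dims <- c(n, n, n)
  } else {
    dims <- as.integer(spec$grid_shape)
    half <- (dims - 1) / 2 * h
    short <- which(half < need)
    if (length(short))
      .stop2("grid too small along %s: half-extent %.1f mm < required %.1f mm",
             paste(c("x", "y", "z")[short], collapse = ","),
             min(half[short]), need, class = "bq_sizing")
  }
  origin <- -(dims - 1) / 2 * h              # globe center on the lattice at 0
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * h)

  # memory-conscious staging: only r and the footprint coordinate survive
  dot <- outer(outer(geo$u[1] * ax[[1]], geo$u[2] * ax[[2]], "+"),
               geo$u[3] * ax[[3]], "+")
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  rho <- sqrt(pmax(r^2 - dot^2, 0))
  phi <- acos(pmin(pmax(dot / pmax(r, 1e-12), -1), 1))
  rm(dot); gc(FALSE)
  # squared elliptical footprint coordinate: <= 1 inside the plate footprint,
  # <= bleb_footprint^2 inside the bleb footprint
  p1 <- outer(outer(geo$e1[1] * ax[[1]], geo$e1[2] * ax[[2]], "+"),
              geo$e1[3] * ax[[3]], "+")
  ell <- (p1 / geo$aw)^2
  rm(p1); gc(FALSE)
  p2 <- outer(outer(geo$e2[1] * ax[[1]], geo$e2[2] * ax[[2]], "+"),
              geo$e2[3] * ax[[3]], "+")
  ell <- ell + (p2 / geo$al)^2
  rm(p2); gc(FALSE)
  ell <- ell * (phi / pmax(rho, 1e-12))^2
  ell[rho < 1e-9] <- 0
  rm(phi, rho); gc(FALSE)

  eta2 <- spec$bleb_footprint^2
  lab <- array(0L, dims)
  lab[r <= geo$R1] <- 1L                                     # globe
  lab[r > geo$R1 & r <= geo$R2 & ell <= eta2] <- 3L          # inner bleb
  lab[r > geo$R3 & r <= geo$R4 & ell <= eta2] <- 4L          # outer bleb

  plate_band <- r > geo$R2 & r <= geo$R3
  in_plate <- plate_band & ell <= 1
  fen <- .fenestration_directions(spec, geo)
  hole <- array(FALSE, dims)
  if (!is.null(fen)) {
    idx <- which(in_plate)
    if (length(idx)) {
      ai <- arrayInd(idx, dims)
      xs <- origin[1] + (ai[, 1] - 1) * h
      ys <- origin[2] + (ai[, 2] - 1) * h
      zs <- origin[3] + (ai[, 3] - 1) * h
      rr2 <- xs^2 + ys^2 + zs^2
      inhole <- rep(FALSE, length(idx))
      for (kk in seq_len(nrow(fen))) {
        proj <- xs * fen[kk, 1] + ys * fen[kk, 2] + zs * fen[kk, 3]
        d2 <- rr2 - proj^2
        inhole <- inhole | (proj > 0 & d2 <= spec$fenestration_radius^2)
      }
      hole[idx[inhole]] <- TRUE
    }
  }
  lab[in_plate & !hole] <- 2L                                # plate
  # fenestration channels and (if merged) the rim band carry bleb labels:
  # the lower half of the plate band joins the inner bleb, the upper half the
  # outer bleb, so fibrous-channel contact exists by construction
  rmid_cut <- (geo$R2 + geo$R3) / 2
  fill <- (in_plate & hole) |
    (spec$merged & plate_band & ell > 1 & ell <= eta2)
  lab[fill & r <= rmid_cut] <- 3L
  lab[fill & r > rmid_cut] <- 4L
  rm(r, ell, plate_band, in_plate, hole, fill)
  gc(FALSE)

  lm <- default_label_map()
  vol <- label_volume(lab, spacing = h, origin = origin, label_map = lm)
  attr(vol, "fenestrations") <- if (is.null(fen)) NULL else
    list(center = c(0, 0, 0), directions = fen,
         radius = spec$fenestration_radius)
  attr(vol, "phantom_spec") <- spec

  counts <- tabulate(lab, nbins = 4L)
  vv <- h^3
  tb <- spec$bleb_footprint * max(geo$aw, geo$al)
  tb <- min(tb, pi / 2)
  truth <- list(
    volume_inner = counts[3] * vv,
    volume_outer = counts[4] * vv,
    volume_plate = counts[2] * vv,
    volume_total = sum(counts[2:4]) * vv,
    volume_globe = counts[1] * vv,
    height = sqrt(geo$R4^2 - geo$R1^2 * sin(tb)^2) - geo$R1 * cos(tb),
    height_apex = spec$inner_bleb_thickness + spec$plate_extent[3] +
      spec$outer_bleb_thickness,
    merged = spec$merged)
  list(volume = vol, truth = truth)
}

#' Write a phantom to disk
#'
#' NIfTI label map plus a JSON ground-truth sidecar, optionally PLY meshes.
#'
#' @param phantom Result of [make_phantom()].
#' @param dir Output directory (created if needed).
#' @param meshes Also extract and write per-component PLY surfaces.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, meshes = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_volume(phantom$volume, file.path(dir, "phantom.nii.gz"))
  jsonlite::write_json(phantom$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (meshes) {
    ms <- phantom_to_meshes(phantom$volume)
    for (nm in names(ms)) write_ply(ms[[nm]], file.path(dir, paste0(nm, ".ply")))
  }
  invisible(dir)
}

#' Random phantom specification
#'
#' Draws geometry within clinically plausible ranges (globe radius 11-12 mm,
#' bleb shells 1-3 mm, plate patches of 300-400 mm^2 class implants, random
#' plate orientation, ~1 in 5 merged, matching the study's 6/30).
#'
#' @param seed Integer seed.
#' @param voxel_spacing Voxel edge, mm.
#' @param merged Force the merged flag; `NULL` draws it with probability 0.2.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, voxel_spacing = 0.25, merged = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  merged <- merged %||% (runif(1) < 0.2)
  phantom_spec(
    globe_radius = runif(1, 11, 12),
    plate_extent = c(runif(1, 26, 34), runif(1, 12, 16), runif(1, 0.8, 1.2)),
    plate_offset_angle = runif(1, 0, 60),
    plate_azimuth = runif(1, 0, 360),
    inner_bleb_thickness = runif(1, 1, 3),
    outer_bleb_thickness = runif(1, 1, 3),
    fenestration_count = 4L,
    fenestration_radius = runif(1, 0.4, 0.6),
    merged = merged,
    voxel_spacing = voxel_spacing,
    seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
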