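#' Default component labelling
#'
#' Integer codes used for the four segmented components of an eye with a
#' Baerveldt implant: the globe, the silicone plate, the inner bleb (fluid
#' between globe and plate) and the outer bleb (fluid on top of the plate).
#' Background is always 0.
#'
#' @return Named integer vector mapping component names to label values.
#' @export
default_label_map <- function() {
  c(globe = 1L, plate = 2L, inner_bleb = 3L, outer_bleb = 4L)
}

#' Labelled 3D segmentation volume
#'
#' A `label_volume` is the substrate of all morphometry in this package: a 3D
#' integer array of component labels on a regular grid with physical voxel
#' spacing in mm.  World coordinates follow the voxel-center convention,
#' `world = origin + (index - 1) * spacing` with 1-based indices.
#'
#' @param voxels 3D integer array of labels (0 = background).
#' @param spacing Voxel spacing in mm, scalar or length-3.
#' @param origin World coordinate of the center of voxel (1,1,1), mm.
#' @param label_map Named integer vector, see [default_label_map()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         label_map = default_label_map()) {
  if (length(dim(voxels)) != 3L)
    .stop2("voxels must be a 3D array", class = "bq_input")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0))
    .stop2("spacing must be > 0 on all axes", class = "bq_input")
  if (anyDuplicated(label_map) || any(label_map <= 0))
    .stop2("label_map values must be distinct positive integers",
           class = "bq_input")
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         label_map = label_map),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  counts <- tabulate(x$voxels, nbins = max(x$label_map))
  for (nm in names(x$label_map))
    cat(sprintf("  %-12s label %d: %d voxels\n", nm, x$label_map[[nm]],
                counts[x$label_map[[nm]]]))
  invisible(x)
}

.is_isotropic <- function(vol, tol = 1e-6) {
  diff(range(vol$spacing)) <= tol * mean(vol$spacing)
}

.require_isotropic <- function(vol, what) {
  if (!.is_isotropic(vol))
    .stop2("%s requires isotropic voxel spacing (got %s); resample first",
           what, paste(signif(vol$spacing, 4), collapse = " x "),
           class = "bq_anisotropic")
  vol$spacing[1]
}

.axis_coords <- function(vol) {
  d <- dim(vol$voxels)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Binary mask of one component
#'
#' @param vol A [label_volume()].
#' @param component Component name (must be present in `vol$label_map`).
#' @param largest_only Keep only the largest 6-connected piece.
#' @return Logical 3D array.
#' @export
component_mask <- function(vol, component, largest_only = FALSE) {
  if (!component %in% names(vol$label_map))
    .stop2("component '%s' is not in the label map", component,
           class = "bq_missing_component")
  mask <- vol$voxels == vol$label_map[[component]]
  if (largest_only && any(mask)) {
    lab <- .label_components6(mask, dim(mask))
    keep <- which.max(tabulate(lab, attr(lab, "n_components")))
    mask <- lab == keep
  }
  mask
}

#' World coordinates of mask voxels
#'
#' @param mask Logical 3D array.
#' @param vol The [label_volume()] the mask came from (for spacing/origin).
#' @return n x 3 matrix of voxel-center coordinates in mm.
#' @export
mask_coordinates <- function(mask, vol) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read / write NIfTI label maps
#'
#' Label volumes are stored as integer NIfTI with voxel spacing in the pixdim
#' header; the label map travels in a small JSON sidecar (`<path>.labels.json`)
#' written next to the image.
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_label_volume` returns `path` invisibly; `read_label_volume`
#'   returns a [label_volume()].
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(list(label_map = as.list(vol$label_map),
                            origin = vol$origin),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @param label_map Used when no JSON sidecar is found next to `path`.
#' @export
read_label_volume <- function(path, label_map = default_label_map()) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    label_map <- vapply(meta$label_map, as.integer, integer(1))
    origin <- as.numeric(meta$origin)
  }
  label_volume(array(as.integer(img), dim = dim(img)), spacing, origin,
               label_map)
}
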