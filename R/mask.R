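#' Voxel masks
#'
#' A `voxel_mask` is a 3D logical occupancy grid with anisotropic voxel
#' spacing in millimetres. It is the carrier for every segmentation in the
#' package: phantom muscles, fossae, and anything read from NIfTI. The axis
#' convention is x = medial to lateral, y = anterior to posterior,
#' z = inferior to superior; voxel centres are placed symmetrically about
#' the grid centre.
#'
#' @param data a 3D logical or 0/1 numeric array.
#' @param spacing_mm numeric length-3, per-axis voxel size in mm; the slice
#'   axis spacing should already include any interslice gap.
#' @param meta optional named list of metadata (e.g. the analytic volume of
#'   a phantom) stored alongside the voxel data.
#'
#' @return A `voxel_mask` object.
#' @export
#' @examples
#' m <- voxel_mask(array(TRUE, c(4, 4, 4)), spacing_mm = c(1, 1, 1))
#' mask_volume_cm3(m)
voxel_mask <- function(data, spacing_mm, meta = list()) {
  if (length(dim(data)) != 3L) abort("voxel_mask data must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("spacing_mm must be three positive finite numbers")
  }
  if (any(dim(data) < 1L)) abort("all mask dimensions must be >= 1")
  storage.mode(data) <- "logical"
  structure(data,
            spacing_mm = spacing_mm, meta = meta,
            class = c("voxel_mask", "array"))
}

#' @rdname voxel_mask
#' @param x an object.
#' @export
is_voxel_mask <- function(x) inherits(x, "voxel_mask")

#' @rdname voxel_mask
#' @export
mask_spacing <- function(x) {
  stopifnot(is_voxel_mask(x))
  attr(x, "spacing_mm")
}

#' @rdname voxel_mask
#' @export
mask_meta <- function(x) {
  stopifnot(is_voxel_mask(x))
  attr(x, "meta") %||% list()
}

#' Raw voxel-count volume of a mask
#'
#' Foreground voxel count times the voxel volume, in cm^3. This is the
#' discretized volume of the object itself, independent of any slice-stack
#' integration convention.
#'
#' @param mask a [voxel_mask()].
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  sum(mask) * prod(mask_spacing(mask)) / 1000
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x)
  sp <- mask_spacing(x)
  cat(sprintf(
    "<voxel_mask> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d foreground (%.3f cm^3)\n",
    d[1], d[2], d[3], sp[1], sp[2], sp[3], sum(x), mask_volume_cm3(x)))
  invisible(x)
}

# voxel-centre coordinates along one axis, centred on 0
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Extract a 2D slice from a mask
#'
#' Returns the binary slice perpendicular to `axis` at position `index`,
#' as a logical matrix carrying its in-plane pixel spacing (the spacings of
#' the two remaining axes, in order) as attribute `pixel_spacing_mm`.
#'
#' @param mask a [voxel_mask()].
#' @param axis slice axis, 1..3 or "x"/"y"/"z".
#' @param index 1-based slice index along `axis`.
#' @return logical matrix with attribute `pixel_spacing_mm`.
#' @export
mask_slice <- function(mask, axis, index) {
  stopifnot(is_voxel_mask(mask))
  ax <- .axis_index(axis)
  n <- dim(mask)[ax]
  if (index < 1 || index > n) {
    abort(sprintf("slice index %d out of range 1..%d on axis %d",
                  index, n, ax))
  }
  sl <- switch(ax,
               `1` = mask[index, , , drop = TRUE],
               `2` = mask[, index, , drop = TRUE],
               `3` = mask[, , index, drop = TRUE])
  sl <- matrix(as.logical(sl), nrow = dim(mask)[setdiff(1:3, ax)][1])
  attr(sl, "pixel_spacing_mm") <- mask_spacing(mask)[setdiff(1:3, ax)]
  sl
}

#' Translate a mask by whole voxels along one axis
#'
#' Rigid integer-voxel shift; voxel count is conserved. Errors if any
#' foreground voxel would be pushed outside the grid.
#'
#' @inheritParams mask_slice
#' @param voxels signed integer shift (positive = towards higher indices).
#' @return the shifted [voxel_mask()].
#' @export
translate_mask <- function(mask, voxels, axis = "x") {
  stopifnot(is_voxel_mask(mask))
  ax <- .axis_index(axis)
  k <- as.integer(round(voxels))
  if (k == 0L) return(mask)
  d <- dim(mask)
  idx <- which(apply(mask, ax, any))
  if (length(idx) &&
      (min(idx) + k < 1L || max(idx) + k > d[ax])) {
    abort("translation pushes foreground voxels outside the grid")
  }
  out <- array(FALSE, d)
  src <- seq_len(d[ax])
  keep <- src + k >= 1L & src + k <= d[ax]
  pick <- function(i) switch(ax,
                             `1` = mask[i, , , drop = FALSE],
                             `2` = mask[, i, , drop = FALSE],
                             `3` = mask[, , i, drop = FALSE])
  for (i in src[keep]) {
    j <- i + k
    if (ax == 1L) out[j, , ] <- pick(i)
    else if (ax == 2L) out[, j, ] <- pick(i)
    else out[, , j] <- pick(i)
  }
  voxel_mask(out, mask_spacing(mask), mask_meta(mask))
}

#' Read and write masks as NIfTI
#'
#' Masks are written as NIfTI-1 volumes with the voxel spacing stored in the
#' header (`pixdim`, mm). Reading recovers the voxel data exactly and the
#' spacing to NIfTI header (single float) precision.
#'
#' @param mask a [voxel_mask()].
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   [voxel_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_voxel_mask(mask))
  arr <- array(as.integer(mask), dim(mask))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, mask_spacing(mask))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("mask file not found: '%s'", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    abort(sprintf("malformed NIfTI file '%s': %s",
                                  path, conditionMessage(e)))
                  })
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  voxel_mask(arr != 0, RNifti::pixdim(img)[1:3])
}
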