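#' Locate the Y-view slice
#'
#' In the clinic the Y-view is the most lateral oblique-sagittal slice on
#' which scapular spine, coracoid and clavicle form a "Y". Phantoms carry
#' no bony landmarks, so the controlled analogue is parametric: the
#' constant-x plane `yview_offset_mm` medial to the most lateral slice
#' containing fossa.
#'
#' @param fossa fossa [voxel_mask()].
#' @param yview_offset_mm offset medial to the lateral fossa edge, mm; by
#'   default taken from the fossa metadata.
#' @return 1-based slice index along x.
#' @export
select_y_view <- function(fossa,
                          yview_offset_mm =
                            mask_meta(fossa)$yview_offset_mm) {
  stopifnot(is_voxel_mask(fossa))
  if (is.null(yview_offset_mm) || !is.finite(yview_offset_mm) ||
      yview_offset_mm < 0) {
    abort("yview_offset_mm must be a non-negative number")
  }
  present <- which(apply(fossa, 1, any))
  if (!length(present)) abort("fossa mask is empty")
  sx <- mask_spacing(fossa)[1]
  idx <- max(present) - as.integer(round(yview_offset_mm / sx))
  if (idx < min(present)) {
    abort(sprintf(
      "yview_offset_mm = %g reaches beyond the medial fossa edge",
      yview_offset_mm))
  }
  idx
}

#' Y-view occupation ratio
#'
#' The occupation ratio (OR) is the quotient of the muscle cross-sectional
#' surface area and the fossa area on the single Y-view slice. Long/short
#' axes and their cross-products are reported for both regions as
#' auxiliary measurements; the OR itself is always computed from traced
#' areas. The Thomazeau atrophy stage implied by the OR is attached.
#'
#' @param muscle,fossa [voxel_mask()]s on the same grid.
#' @param yview_index Y-view slice index along x; derived from
#'   `yview_offset_mm` when `NULL`.
#' @param yview_offset_mm used (with [select_y_view()]) when
#'   `yview_index` is `NULL`; defaults to the fossa metadata.
#' @return one-row tibble: `yview_index`, `muscle_area_mm2`,
#'   `fossa_area_mm2`, `or_value`, `muscle_cp_mm2`, `fossa_cp_mm2`,
#'   `or_cp` (auxiliary CP-based ratio), `stage`.
#' @export
occupation_ratio <- function(muscle, fossa, yview_index = NULL,
                             yview_offset_mm =
                               mask_meta(fossa)$yview_offset_mm) {
  stopifnot(is_voxel_mask(muscle), is_voxel_mask(fossa))
  if (!identical(dim(muscle), dim(fossa)) ||
      !isTRUE(all.equal(mask_spacing(muscle), mask_spacing(fossa)))) {
    abort("muscle and fossa masks must share grid and spacing")
  }
  if (is.null(yview_index)) {
    yview_index <- select_y_view(fossa, yview_offset_mm)
  }
  msl <- mask_slice(muscle, 1, yview_index)
  fsl <- mask_slice(fossa, 1, yview_index)
  fa <- slice_area(fsl)
  if (fa <= 0) {
    abort(sprintf("fossa area is zero on Y-view slice %d; cannot form OR",
                  yview_index))
  }
  ma <- slice_area(msl)
  fax <- long_short_axes(fsl)
  if (any(msl)) {
    max_ <- long_short_axes(msl)
    mcp <- cross_product(max_[["long_mm"]], max_[["short_mm"]])
  } else {
    mcp <- 0
  }
  fcp <- cross_product(fax[["long_mm"]], fax[["short_mm"]])
  or <- ma / fa
  tibble(yview_index = yview_index,
         muscle_area_mm2 = ma, fossa_area_mm2 = fa, or_value = or,
         muscle_cp_mm2 = mcp, fossa_cp_mm2 = fcp,
         or_cp = mcp / fcp,
         stage = thomazeau_stage(or))
}

#' Thomazeau atrophy stage from an occupation ratio
#'
#' Stage I (normal or mildly atrophied) for OR of 0.60 and above, stage II
#' (moderate atrophy) for OR in `[0.40, 0.60)`, stage III (severe) below
#' 0.40. The upper bound of each band is inclusive, so OR = 0.60 is stage
#' I and OR = 0.40 is stage II; ratios above 1 (muscle traced beyond the
#' fossa outline) remain stage I.
#'
#' @param or_value numeric vector of occupation ratios, >= 0.
#' @return factor with levels `"I"`, `"II"`, `"III"`.
#' @export
#' @examples
#' thomazeau_stage(c(0.72, 0.54, 0.40, 0.39))
thomazeau_stage <- function(or_value) {
  if (any(!is.finite(or_value)) || any(or_value < 0)) {
    abort("occupation ratios must be finite and >= 0")
  }
  factor(ifelse(or_value >= 0.60, "I",
                ifelse(or_value >= 0.40, "II", "III")),
         levels = c("I", "II", "III"))
}
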