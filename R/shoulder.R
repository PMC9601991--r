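#' Shoulder phantom specification
#'
#' Couples a muscle spindle to a static fossa envelope. The fossa is built
#' from `fossa_basis` (by default the muscle itself; in cohort simulations
#' the nominal, pre-atrophy spindle) by sweeping it medially through the
#' retraction range and dilating the swept solid by a ball of radius
#' `fossa_margin_mm`. The fossa therefore never moves: it is the bony
#' container, and a retracted or atrophied muscle occupies less of it.
#' Retraction is a rigid medial translation of the muscle only, quantized
#' to whole voxels along x, which isolates the medialization mechanism
#' from any shape change and conserves the voxel-count volume exactly.
#'
#' Partial-thickness tendon defects alter only the lateral 10% of the
#' muscle length (the tendon end), scaling the radius there by
#' `1 - fraction`; the belly is never medialized for partial tears.
#'
#' @param muscle a [spindle_spec()] for the actual (possibly atrophied)
#'   muscle.
#' @param fossa_basis a [spindle_spec()] from which the fossa envelope is
#'   dilated; defaults to `muscle`.
#' @param fossa_margin_mm radial clearance of the fossa around the basis
#'   spindle, mm.
#' @param yview_offset_mm distance of the Y-view plane medial to the most
#'   lateral fossa slice, mm.
#' @param retraction_mm medial translation of the muscle belly, mm
#'   (0 for intact and partial tears).
#' @param tendon_defect `NULL`, or a list with `kind` one of
#'   `"partial"`/`"full"`, plus `fraction` (partial, fraction of tendon
#'   diameter) and/or `depth_mm`, and `stump_position` (full).
#' @return a `shoulder_spec` list.
#' @export
shoulder_spec <- function(muscle, fossa_basis = NULL,
                          fossa_margin_mm = 1.5, yview_offset_mm = 22,
                          retraction_mm = 0, tendon_defect = NULL) {
  stopifnot(inherits(muscle, "spindle_spec"))
  fossa_basis <- fossa_basis %||% muscle
  stopifnot(inherits(fossa_basis, "spindle_spec"))
  if (!is.finite(retraction_mm) || retraction_mm < 0) {
    abort("retraction_mm must be >= 0")
  }
  if (!is.finite(fossa_margin_mm) || fossa_margin_mm <= 0) {
    abort("fossa_margin_mm must be > 0")
  }
  lat_edge_to_medial <- fossa_basis$length_mm + 2 * fossa_margin_mm +
    retraction_mm
  if (!is.finite(yview_offset_mm) || yview_offset_mm < 0 ||
      yview_offset_mm >= lat_edge_to_medial) {
    abort("yview_offset_mm must lie within the fossa extent")
  }
  structure(list(muscle = muscle, fossa_basis = fossa_basis,
                 fossa_margin_mm = fossa_margin_mm,
                 yview_offset_mm = yview_offset_mm,
                 retraction_mm = retraction_mm,
                 tendon_defect = tendon_defect),
            class = "shoulder_spec")
}

# muscle radius profile with an optional partial-thickness defect carved
# into the lateral 10% of the length
muscle_radius_at <- function(x, spec) {
  r <- spindle_radius(x, spec$muscle)
  td <- spec$tendon_defect
  if (!is.null(td) && identical(td$kind, "partial")) {
    frac <- td$fraction %||% 0
    zone <- x > 0.4 * spec$muscle$length_mm   # lateral 10% of [-L/2, L/2]
    r[zone] <- r[zone] * (1 - frac)
  }
  r
}

# fossa radius profile on positions x: the basis spindle swept medially
# through [0, retraction] then dilated by a ball of radius margin.
fossa_radius_at <- function(x, spec, retract_mm) {
  b <- spec$fossa_basis
  m <- spec$fossa_margin_mm
  hl <- b$length_mm / 2
  # swept profile: unimodal max over medial shifts d in [0, retract]
  swept <- function(xx) {
    out <- numeric(length(xx))
    lo <- -hl - retract_mm
    inside <- xx >= lo & xx <= hl
    xs <- xx[inside]
    r <- ifelse(xs >= 0, spindle_radius(xs, b),
                ifelse(xs >= -retract_mm, b$max_radius_mm,
                       spindle_radius(xs + retract_mm, b)))
    out[inside] <- r
    out[!inside] <- NA_real_
    out
  }
  # dilation: max over |t| <= m of swept(x - t) + sqrt(m^2 - t^2)
  t <- seq(-m, m, length.out = 65L)
  cap <- sqrt(pmax(0, m^2 - t^2))
  vapply(x, function(xi) {
    s <- swept(xi - t)
    v <- s + cap
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  }, numeric(1))
}

#' Build a shoulder phantom (muscle + fossa masks)
#'
#' Rasterizes the muscle and its static fossa envelope on a shared grid.
#' The muscle is shifted medially by `retraction_mm` quantized to whole
#' voxels; the fossa accommodates the full retraction range, so the muscle
#' is always contained in the fossa.
#'
#' @param spec a [shoulder_spec()].
#' @param grid optional shared [grid_spec()]; auto-fitted when `NULL`.
#' @param spacing_mm grid spacing used when `grid` is `NULL`.
#' @return list with elements `muscle` and `fossa`, both [voxel_mask()]s.
#'   The fossa mask records the Y-view offset and the lateral fossa edge in
#'   its metadata.
#' @export
#' @examples
#' ph <- build_shoulder(shoulder_spec(spindle_spec(40)),
#'                      spacing_mm = c(1, 3.3, 1))
#' mask_volume_cm3(ph$muscle)
build_shoulder <- function(spec, grid = NULL,
                           spacing_mm = c(0.52, 3.3, 0.52)) {
  stopifnot(inherits(spec, "shoulder_spec"))
  b <- spec$fossa_basis
  m <- spec$fossa_margin_mm
  if (is.null(grid)) {
    # symmetric grid generous enough for the asymmetric (medially swept)
    # fossa extent [-L/2 - retract - m, L/2 + m]
    ext_x <- b$length_mm + 2 * m + 2 * spec$retraction_mm
    ext_r <- 2 * (max(b$max_radius_mm, spec$muscle$max_radius_mm) + m)
    grid <- fit_grid(c(ext_x, ext_r, ext_r), spacing_mm)
  }
  sx <- grid$spacing_mm[1]
  k <- as.integer(round(spec$retraction_mm / sx))
  retract_q <- k * sx
  fx <- function(x) fossa_radius_at(x, spec, retract_q)
  fossa_arr <- voxelize_profile(
    fx, grid, center_mm = c(0, 0, 0),
    extent_x = c(-b$length_mm / 2 - retract_q - m, b$length_mm / 2 + m))
  # muscle centred on the basis, then shifted medially by k whole voxels
  mus <- function(x) muscle_radius_at(x, spec)
  muscle_arr <- voxelize_profile(
    mus, grid, center_mm = c(-retract_q, 0, 0),
    extent_x = c(-1, 1) * spec$muscle$length_mm / 2)
  if (any(muscle_arr & !fossa_arr)) {
    abort("internal error: muscle not contained in fossa")
  }
  sp <- grid$spacing_mm
  analytic <- spec$muscle$volume_cm3
  td <- spec$tendon_defect
  if (!is.null(td) && identical(td$kind, "partial")) {
    # defect removes pi r^2 (1 - (1-f)^2) over the lateral 10% of length
    f <- td$fraction %||% 0
    hl <- spec$muscle$length_mm / 2
    lost <- integrate(function(x) {
      pi * spindle_radius(x, spec$muscle)^2 * (1 - (1 - f)^2)
    }, 0.4 * spec$muscle$length_mm, hl)$value / 1000
    analytic <- analytic - lost
  }
  list(
    muscle = voxel_mask(muscle_arr, sp,
                        meta = list(analytic_volume_cm3 = analytic,
                                    retraction_mm = retract_q,
                                    spec = spec)),
    fossa = voxel_mask(fossa_arr, sp,
                       meta = list(yview_offset_mm = spec$yview_offset_mm,
                                   fossa_margin_mm = m))
  )
}

#' Sweep a phantom through retraction values
#'
#' Builds the same shoulder phantom at a series of medial retractions of
#' the muscle belly and measures, at each step, the muscle volume (which a
#' rigid translation leaves unchanged) and the Y-view occupation ratio
#' (which falls as the belly moves away from the fixed Y-view plane). This
#' is the package's direct probe of the medialization mechanism.
#'
#' @param muscle a [spindle_spec()] for the muscle (also the fossa basis).
#' @param retractions_mm numeric vector of retractions to evaluate.
#' @param spacing_mm grid spacing.
#' @param fossa_margin_mm,yview_offset_mm forwarded to [shoulder_spec()].
#' @return tibble: `retraction_mm`, `volume_cm3`, `or_value`,
#'   `muscle_area_mm2`, `fossa_area_mm2`.
#' @export
retraction_sweep <- function(muscle, retractions_mm,
                             spacing_mm = c(0.52, 3.3, 0.52),
                             fossa_margin_mm = 1.5, yview_offset_mm = 22) {
  stopifnot(inherits(muscle, "spindle_spec"))
  # one shared grid for the whole sweep so that the Y-view plane sits at
  # the same lattice position for every retraction
  ext_x <- muscle$length_mm + 2 * fossa_margin_mm +
    2 * max(retractions_mm)
  ext_r <- 2 * (muscle$max_radius_mm + fossa_margin_mm)
  grid <- fit_grid(c(ext_x, ext_r, ext_r), spacing_mm)
  purrr::map_dfr(retractions_mm, function(d) {
    sp <- shoulder_spec(muscle, fossa_margin_mm = fossa_margin_mm,
                        yview_offset_mm = yview_offset_mm,
                        retraction_mm = d)
    ph <- build_shoulder(sp, grid = grid)
    orm <- occupation_ratio(ph$muscle, ph$fossa,
                            yview_offset_mm = yview_offset_mm)
    tibble(retraction_mm = d,
           volume_cm3 = mask_volume_cm3(ph$muscle),
           or_value = orm$or_value,
           muscle_area_mm2 = orm$muscle_area_mm2,
           fossa_area_mm2 = orm$fossa_area_mm2)
  })
}
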