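#' Voxel grid specification
#'
#' Describes the sampling lattice on which phantoms are rasterized. The
#' default spacing reproduces the acquisition geometry of a clinical
#' shoulder protocol: 0.52 mm in-plane resolution and 3 mm slices with a
#' 0.3 mm interslice gap, stacked along the anterior-posterior (y) axis,
#' so the y spacing is the effective slab pitch 3.3 mm.
#'
#' @param shape integer length-3, voxel counts per axis (x, y, z).
#' @param spacing_mm numeric length-3, voxel size per axis in mm; the slice
#'   axis entry is slice thickness plus interslice gap.
#' @return a `grid_spec` list.
#' @export
#' @examples
#' grid_spec(c(100, 20, 60))
grid_spec <- function(shape, spacing_mm = c(0.52, 3.3, 0.52)) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    abort("shape must be three integers >= 1")
  }
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("spacing_mm must be three positive numbers")
  }
  structure(list(shape = shape, spacing_mm = spacing_mm),
            class = "grid_spec")
}

# smallest grid (plus padding) that contains a box of the given mm extents
fit_grid <- function(extent_mm, spacing_mm = c(0.52, 3.3, 0.52),
                     pad_voxels = 2L) {
  shape <- ceiling(extent_mm / spacing_mm) + 2L * pad_voxels
  grid_spec(shape, spacing_mm)
}

#' Spindle (solid-of-revolution) muscle model
#'
#' The phantom muscle is a solid of revolution about the medial-lateral
#' (x) axis with radius profile
#' `r(x) = R * (1 - (2 x / L)^2)^p` for `x` in `[-L/2, L/2]`,
#' where `R` is the maximum radius, `L` the length and `p > 0` the taper
#' exponent (p = 1 gives a paraboloid-like belly that tapers to pointed
#' tendon ends, mimicking a fusiform muscle). Its volume has the closed
#' form `V = pi R^2 (L/2) B(1/2, 2p + 1)` (Euler beta function), which
#' serves as the exact ground truth replacing physical water-displacement
#' volumetry.
#'
#' Either give `length_mm` and `max_radius_mm` directly, or give
#' `target_volume_cm3` (optionally with `aspect_ratio` = length/diameter,
#' default 3) and the dimensions are solved so the closed-form volume
#' equals the target exactly. If all three are given the spindle is scaled
#' uniformly to hit the target volume.
#'
#' @param target_volume_cm3 desired analytic volume in cm^3.
#' @param length_mm spindle length along x.
#' @param max_radius_mm maximum (belly) radius.
#' @param shape_exponent taper power p (> 0).
#' @param aspect_ratio length / diameter used when solving dimensions from
#'   a target volume.
#' @return a `spindle_spec` list with fields `length_mm`, `max_radius_mm`,
#'   `shape_exponent`, `volume_cm3`.
#' @export
#' @examples
#' sp <- spindle_spec(target_volume_cm3 = 50)
#' sp$volume_cm3
spindle_spec <- function(target_volume_cm3 = NULL, length_mm = NULL,
                         max_radius_mm = NULL, shape_exponent = 1,
                         aspect_ratio = 3) {
  p <- shape_exponent
  if (!is.finite(p) || p <= 0) abort("shape_exponent must be > 0")
  if (is.null(length_mm) != is.null(max_radius_mm)) {
    abort("give both length_mm and max_radius_mm, or neither")
  }
  if (is.null(length_mm)) {
    if (is.null(target_volume_cm3)) {
      abort("give target_volume_cm3 or explicit dimensions")
    }
    if (!is.finite(target_volume_cm3) || target_volume_cm3 <= 0) {
      abort("target_volume_cm3 must be positive")
    }
    if (!is.finite(aspect_ratio) || aspect_ratio <= 0) {
      abort("aspect_ratio must be positive")
    }
    # V = pi * aspect * B(1/2, 2p+1) * R^3  with  L = 2 * aspect * R
    R <- (target_volume_cm3 * 1000 /
            (pi * aspect_ratio * beta(0.5, 2 * p + 1)))^(1 / 3)
    length_mm <- 2 * aspect_ratio * R
    max_radius_mm <- R
  } else {
    if (!is.finite(length_mm) || length_mm <= 0 ||
        !is.finite(max_radius_mm) || max_radius_mm <= 0) {
      abort("length_mm and max_radius_mm must be positive")
    }
    if (!is.null(target_volume_cm3)) {
      s <- (target_volume_cm3 /
              spindle_volume_cm3(length_mm, max_radius_mm, p))^(1 / 3)
      length_mm <- length_mm * s
      max_radius_mm <- max_radius_mm * s
    }
  }
  structure(list(length_mm = length_mm, max_radius_mm = max_radius_mm,
                 shape_exponent = p,
                 volume_cm3 = spindle_volume_cm3(length_mm, max_radius_mm, p)),
            class = "spindle_spec")
}

#' @rdname spindle_spec
#' @export
spindle_volume_cm3 <- function(length_mm, max_radius_mm, shape_exponent = 1) {
  pi * max_radius_mm^2 * (length_mm / 2) *
    beta(0.5, 2 * shape_exponent + 1) / 1000
}

#' @rdname spindle_spec
#' @param x positions along the spindle axis, mm, relative to the belly
#'   centre.
#' @param spec a `spindle_spec`.
#' @export
spindle_radius <- function(x, spec) {
  u <- 2 * x / spec$length_mm
  r <- spec$max_radius_mm * pmax(0, 1 - u^2)^spec$shape_exponent
  r[abs(u) > 1] <- 0
  r
}

# rasterize a radius profile r(x) as a solid of revolution about the x axis.
# rule: a voxel belongs to the solid iff its centre is inside the surface.
voxelize_profile <- function(radius_at, grid, center_mm = c(0, 0, 0),
                             extent_x) {
  n <- grid$shape
  sp <- grid$spacing_mm
  x <- axis_coords(n[1], sp[1]) - center_mm[1]
  y <- axis_coords(n[2], sp[2]) - center_mm[2]
  z <- axis_coords(n[3], sp[3]) - center_mm[3]
  half <- n * sp / 2
  if (extent_x[1] + center_mm[1] < -half[1] ||
      extent_x[2] + center_mm[1] > half[1]) {
    abort("object extent exceeds grid along x")
  }
  r <- radius_at(x)
  if (max(r) > min(half[2] - abs(center_mm[2]),
                   half[3] - abs(center_mm[3]))) {
    abort("object radius exceeds grid extent in-plane")
  }
  rho2 <- outer(y^2, z^2, `+`)
  m <- array(FALSE, n)
  for (i in which(r > 0)) m[i, , ] <- rho2 <= r[i]^2
  m
}

#' Rasterize a spindle phantom
#'
#' Converts a [spindle_spec()] to a [voxel_mask()] on the given grid. A
#' voxel is foreground iff its centre lies inside the continuous spindle
#' surface, so the voxel-count volume converges to the closed-form volume
#' as the spacing shrinks. The analytic volume is attached as metadata.
#'
#' @param spec a [spindle_spec()].
#' @param grid a [grid_spec()]; if `NULL`, a grid that fits the spindle
#'   (with two voxels of padding) is constructed at `spacing_mm`.
#' @param spacing_mm spacing used when `grid` is `NULL`.
#' @param center_mm spindle centre in grid coordinates (mm, grid centre
#'   is the origin).
#' @return a [voxel_mask()] with `meta$analytic_volume_cm3` and
#'   `meta$spec`.
#' @export
#' @examples
#' m <- make_spindle(spindle_spec(10), spacing_mm = c(1, 1, 1))
#' c(analytic = mask_meta(m)$analytic_volume_cm3, voxel = mask_volume_cm3(m))
make_spindle <- function(spec, grid = NULL,
                         spacing_mm = c(0.52, 3.3, 0.52),
                         center_mm = c(0, 0, 0)) {
  stopifnot(inherits(spec, "spindle_spec"))
  if (is.null(grid)) {
    grid <- fit_grid(c(spec$length_mm,
                       2 * spec$max_radius_mm, 2 * spec$max_radius_mm),
                     spacing_mm)
  }
  m <- voxelize_profile(function(x) spindle_radius(x, spec), grid,
                        center_mm,
                        extent_x = c(-1, 1) * spec$length_mm / 2)
  voxel_mask(m, grid$spacing_mm,
             meta = list(analytic_volume_cm3 = spec$volume_cm3,
                         spec = spec))
}

#' Generate a set of specimen phantoms
#'
#' One spindle phantom per requested volume, each carrying its exact
#' closed-form volume as ground truth; the digital analogue of a series of
#' physical muscle specimens measured by water displacement.
#'
#' @param volumes_cm3 positive volumes, cm^3.
#' @param grid optional shared [grid_spec()]; by default each phantom gets
#'   the smallest grid that fits it at `spacing_mm`.
#' @inheritParams make_spindle
#' @param shape_exponent,aspect_ratio forwarded to [spindle_spec()].
#' @return list of [voxel_mask()]s.
#' @export
make_specimen_set <- function(volumes_cm3, grid = NULL,
                              spacing_mm = c(0.52, 3.3, 0.52),
                              shape_exponent = 1, aspect_ratio = 3) {
  if (length(volumes_cm3) == 0) return(list())
  if (any(!is.finite(volumes_cm3)) || any(volumes_cm3 <= 0)) {
    abort("all specimen volumes must be positive")
  }
  lapply(volumes_cm3, function(v) {
    make_spindle(spindle_spec(v, shape_exponent = shape_exponent,
                              aspect_ratio = aspect_ratio),
                 grid = grid, spacing_mm = spacing_mm)
  })
}
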