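test_that("slice areas are pixel count times pixel area", {
  empty <- matrix(FALSE, 5, 5)
  expect_equal(slice_area(empty, c(1, 1)), 0)
  expect_equal(slice_area(rect_slice(10, 10)), 100)
  # anisotropic pixels
  expect_equal(slice_area(rect_slice(10, 10, spacing = c(0.5, 2))), 100)
  d <- disk_slice(20, 1)
  expect_lt(abs(slice_area(d) - pi * 400) / (pi * 400), 0.01)
})

test_that("long axis of a filled square is its diagonal", {
  ax <- long_short_axes(rect_slice(10, 10))
  expect_equal(unname(ax[["long_mm"]]), sqrt(200), tolerance = 1e-9)
  expect_equal(unname(ax[["short_mm"]]), sqrt(200), tolerance = 1e-9)
})

test_that("a single pixel measures as its own diagonal", {
  px <- rect_slice(1, 1)
  ax <- long_short_axes(px)
  expect_equal(unname(ax[["long_mm"]]), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(ax[["short_mm"]]), sqrt(2), tolerance = 1e-9)
})

test_that("digitized disk axes approach the diameter", {
  d <- disk_slice(10, 1)
  ax <- long_short_axes(d)
  # corner-polygon Feret overshoots by up to about one pixel diagonal
  expect_lt(abs(ax[["long_mm"]] - 20), 1.5)
  expect_lt(abs(ax[["short_mm"]] - 20), 1.5)
  expect_error(long_short_axes(matrix(FALSE, 4, 4),
                               pixel_spacing_mm = c(1, 1)), "empty")
})

test_that("axes agree with independent caliper oracles", {
  for (seed in 1:6) {
    blob <- random_blob(seed = seed)
    pts <- corner_points(blob)
    ax <- long_short_axes(blob)
    expect_equal(unname(ax[["long_mm"]]), feret_bruteforce(pts),
                 tolerance = 1e-9)
    expect_equal(unname(ax[["long_mm"]]), feret_sweep(pts),
                 tolerance = 1e-3)
    # reported short axis is the region extent perpendicular to the
    # reported long-axis direction
    dir <- attr(ax, "direction")
    expect_equal(unname(ax[["short_mm"]]),
                 extent_along(pts, dir + pi / 2), tolerance = 1e-9)
    expect_gte(ax[["long_mm"]], ax[["short_mm"]] - 1e-9)
  }
})

test_that("cross products multiply axes and validate inputs", {
  expect_equal(cross_product(sqrt(200), sqrt(200)), 200, tolerance = 1e-9)
  expect_equal(cross_product(0, 0), 0)
  expect_error(cross_product(-1, 0), "non-negative")
})

test_that("CP/area of a fine disk approaches 4/pi", {
  d <- disk_slice(20, 0.15)
  ax <- long_short_axes(d)
  cp <- cross_product(ax[["long_mm"]], ax[["short_mm"]])
  expect_lt(abs(cp / slice_area(d) - 4 / pi) / (4 / pi), 0.02)
})

test_that("slice-stack volume follows the thickness + gap arithmetic", {
  arr <- array(FALSE, c(12, 1, 12))
  arr[2:11, 1, 2:11] <- TRUE          # one slice, 100 px at 1 mm
  m <- voxel_mask(arr, c(1, 3.3, 1))
  vr <- muscle_volume(m, slice_axis = "y", thickness_mm = 3, gap_mm = 0.3)
  expect_equal(vr$volume_cm3, 0.33, tolerance = 1e-12)
  expect_equal(nrow(vr$slice_measures), 1)
  # gap flag: integrating with bare thickness
  expect_equal(muscle_volume(m, "y", 3, 0)$volume_cm3, 0.3,
               tolerance = 1e-12)
})

test_that("axis-aligned boxes integrate exactly", {
  arr <- array(FALSE, c(10, 6, 8))
  arr[2:9, 2:5, 2:7] <- TRUE          # 8 x 4 x 6 voxel box
  m <- voxel_mask(arr, c(1, 3.3, 1))
  vr <- muscle_volume(m, slice_axis = "y")
  expect_equal(vr$volume_cm3, 8 * 6 * 4 * 3.3 / 1000, tolerance = 1e-12)
})

test_that("volumes are conserved under whole-voxel translation", {
  m <- make_spindle(spindle_spec(10), spacing_mm = c(1, 3.3, 1))
  # re-rasterize with 4 voxels of padding so a shift fits
  g <- grid_spec(dim(m) + 8L, mask_spacing(m))
  m <- make_spindle(spindle_spec(10), grid = g)
  shifted <- translate_mask(m, 3, "x")
  expect_equal(muscle_volume(shifted, "y")$volume_cm3,
               muscle_volume(m, "y")$volume_cm3, tolerance = 1e-12)
  expect_equal(sum(shifted), sum(m))
})

test_that("volume is additive over disjoint masks and monotone", {
  a <- array(FALSE, c(10, 4, 10)); a[2:4, 2:3, 2:9] <- TRUE
  b <- array(FALSE, c(10, 4, 10)); b[6:9, 2:3, 2:9] <- TRUE
  sp <- c(1, 3.3, 1)
  va <- muscle_volume(voxel_mask(a, sp), "y")$volume_cm3
  vb <- muscle_volume(voxel_mask(b, sp), "y")$volume_cm3
  vu <- muscle_volume(voxel_mask(a | b, sp), "y")$volume_cm3
  expect_equal(vu, va + vb, tolerance = 1e-12)
  expect_lte(va, vu)
})

test_that("phantom recovery sits inside the reference accuracy band", {
  m <- make_spindle(spindle_spec(10))
  pct <- 100 * muscle_volume(m, "y")$volume_cm3 / 10
  expect_gte(pct, 97.40)
  expect_lte(pct, 102.70)
})

test_that("convex phantom slices satisfy the CP >= area bound", {
  m <- make_spindle(spindle_spec(30), spacing_mm = c(1, 3.3, 1))
  tr <- slice_measures(m, "y", with_axes = TRUE)
  expect_true(all(tr$cp_mm2 >= tr$area_mm2))
})

test_that("empty masks give zero volume and an empty trace", {
  m <- voxel_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  vr <- muscle_volume(m, "y")
  expect_equal(vr$volume_cm3, 0)
  expect_equal(nrow(vr$slice_measures), 0)
})
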