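# small synthetic muscle/fossa pair: concentric cylinders along x
cyl_pair <- function(nx = 50, r_muscle = 5, r_fossa = 8, spacing = 1) {
  n_in <- 2 * r_fossa + 5
  arr_m <- array(FALSE, c(nx, n_in, n_in))
  arr_f <- array(FALSE, c(nx, n_in, n_in))
  cx <- (seq_len(n_in) - (n_in + 1) / 2) * spacing
  rho2 <- outer(cx^2, cx^2, `+`)
  for (i in seq_len(nx)) {
    arr_m[i, , ] <- rho2 <= r_muscle^2
    arr_f[i, , ] <- rho2 <= r_fossa^2
  }
  sp <- c(spacing, spacing, spacing)
  list(muscle = voxel_mask(arr_m, sp), fossa = voxel_mask(arr_f, sp))
}

test_that("the Y-view plane is located by offset from the lateral edge", {
  p <- cyl_pair(nx = 50, spacing = 1)
  expect_equal(select_y_view(p$fossa, 0), 50)
  expect_equal(select_y_view(p$fossa, 10), 40)
  expect_error(select_y_view(p$fossa, 50), "beyond")
  expect_error(select_y_view(p$fossa, -1), "non-negative")
})

test_that("occupation ratio is the muscle/fossa area quotient", {
  p <- cyl_pair()
  orm <- occupation_ratio(p$muscle, p$fossa, yview_index = 25)
  a_m <- slice_area(mask_slice(p$muscle, 1, 25))
  a_f <- slice_area(mask_slice(p$fossa, 1, 25))
  expect_equal(orm$or_value, a_m / a_f)
  expect_true(orm$or_value > 0 && orm$or_value < 1)
  # muscle == fossa -> OR exactly 1
  orm2 <- occupation_ratio(p$fossa, p$fossa, yview_index = 25)
  expect_equal(orm2$or_value, 1)
  # empty fossa slice -> division error with diagnostics
  empty <- voxel_mask(array(FALSE, dim(p$fossa)), mask_spacing(p$fossa))
  expect_error(occupation_ratio(p$muscle, empty, yview_index = 25),
               "empty|zero")
})

test_that("OR is invariant under uniform in-plane rescaling", {
  p1 <- cyl_pair(spacing = 1)
  p2 <- cyl_pair(spacing = 1)
  # double the in-plane (y, z) spacing of both masks
  rescale <- function(m) {
    sp <- mask_spacing(m)
    voxel_mask(unclass(m), c(sp[1], 2 * sp[2], 2 * sp[3]))
  }
  o1 <- occupation_ratio(p1$muscle, p1$fossa, yview_index = 20)
  o2 <- occupation_ratio(rescale(p2$muscle), rescale(p2$fossa),
                         yview_index = 20)
  expect_equal(o1$or_value, o2$or_value)
})

test_that("Thomazeau stages partition the OR axis with inclusive tops", {
  expect_equal(as.character(thomazeau_stage(c(0.72, 1.0, 0.60))),
               c("I", "I", "I"))
  expect_equal(as.character(thomazeau_stage(c(0.59, 0.40))), c("II", "II"))
  expect_equal(as.character(thomazeau_stage(c(0.39, 0))), c("III", "III"))
  expect_error(thomazeau_stage(-0.1), "0")
  ors <- seq(0, 1, by = 0.005)
  st <- thomazeau_stage(ors)
  expect_true(all(!is.na(st)))            # total
  expect_equal(as.vector(table(st)),
               c(sum(ors >= 0.6), sum(ors >= 0.4 & ors < 0.6),
                 sum(ors < 0.4)))          # mutually exclusive
})

test_that("retraction suppresses the OR but not the volume", {
  sw <- retraction_sweep(spindle_spec(57), c(0, 3.3, 6.6, 9.9, 19.8),
                         spacing_mm = c(0.52, 3.3, 0.52))
  # pure translation: voxel-count volume is bit-identical
  expect_equal(sw$volume_cm3, rep(sw$volume_cm3[1], nrow(sw)))
  expect_true(all(diff(sw$or_value) <= 0))
  # strict decrease once the shift exceeds one slice spacing
  expect_lt(sw$or_value[2], sw$or_value[1])
  expect_lt(sw$or_value[5], sw$or_value[2])
  # the fossa is static across the sweep
  expect_equal(sw$fossa_area_mm2, rep(sw$fossa_area_mm2[1], nrow(sw)))
})

test_that("full retraction example: OR at 20 mm is below OR at 0 mm", {
  mus <- spindle_spec(40)
  ph0 <- build_shoulder(shoulder_spec(mus, retraction_mm = 0),
                        spacing_mm = c(0.52, 3.3, 0.52))
  ph20 <- build_shoulder(shoulder_spec(mus, retraction_mm = 20),
                         spacing_mm = c(0.52, 3.3, 0.52))
  o0 <- occupation_ratio(ph0$muscle, ph0$fossa)
  o20 <- occupation_ratio(ph20$muscle, ph20$fossa)
  expect_lt(o20$or_value, o0$or_value)
  # and the muscle volume budget moved by construction not at all
  expect_equal(mask_volume_cm3(ph20$muscle), mask_volume_cm3(ph0$muscle),
               tolerance = 0.01)
})
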