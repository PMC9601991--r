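test_that("masks round-trip through NIfTI with spacing intact", {
  m <- make_spindle(spindle_spec(10), spacing_mm = c(0.52, 0.52, 3.3))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  m2 <- read_mask(f)
  expect_equal(dim(m2), dim(m))
  expect_true(all(m2 == m))
  # NIfTI stores pixdim as single floats
  expect_equal(mask_spacing(m2), c(0.52, 0.52, 3.3), tolerance = 1e-6)
  expect_error(read_mask(file.path(tempdir(), "nope.nii.gz")),
               "nope.nii.gz")
})

test_that("small ex vivo run recovers volumes and correlates", {
  res <- run_exvivo(volumes_cm3 = c(10, 50, 100))
  expect_equal(nrow(res$table), 3)
  expect_equal(res$table$percent,
               100 * res$table$measured_volume_cm3 /
                 res$table$true_volume_cm3)
  expect_true(all(abs(res$table$percent - 100) < 5))
  expect_gte(res$r, 0.95)
  # deterministic: a rerun reproduces the table exactly
  expect_identical(res$table, run_exvivo(c(10, 50, 100))$table)
})

test_that("experiment drivers write deterministic output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- cohort_spec(n_intact = 4, n_partial = 4, n_full = 4)
  r1 <- run_cohort(spec, spacing_mm = c(1.04, 3.3, 1.04), seed = 9,
                   out_dir = d1)
  r2 <- run_cohort(spec, spacing_mm = c(1.04, 3.3, 1.04), seed = 9,
                   out_dir = d2)
  for (f in c("cohort.csv", "group_summary.csv", "correlations.csv",
              "overestimation.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(r1$correlations, r2$correlations)
  expect_equal(nrow(r1$cohort), 12)
})

test_that("cohort results carry the full measurement chain", {
  spec <- cohort_spec(n_intact = 5, n_partial = 5, n_full = 5)
  res <- run_cohort(spec, spacing_mm = c(1.04, 3.3, 1.04), seed = 2)
  expect_s3_class(res$overestimation, "overestimation")
  expect_equal(nrow(res$group_summary), 3)
  expect_true(all(c("or_value", "stage", "measured_volume_cm3") %in%
                    names(res$cohort)))
  expect_true(all(res$cohort$or_value > 0))
  # measured volumes track the analytic subject volumes
  rel <- with(res$cohort, abs(measured_volume_cm3 - volume_cm3) /
                volume_cm3)
  expect_lt(max(rel), 0.06)
  g <- glance(res)
  expect_true(all(c("r_intact", "r_partial", "r_full",
                    "inter_reader_r") %in% names(g)))
})

test_that("YAML configs drive the experiment front end", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("experiment: exvivo", "seed: 1", "params:",
               "  volumes_cm3: [20, 60]"), cfg)
  res <- run_config(cfg)
  expect_s3_class(res, "exvivo_result")
  expect_equal(res$table$true_volume_cm3, c(20, 60))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("experiment: nonsense", bad)
  expect_error(run_config(bad), "exvivo | cohort")
  expect_error(run_config("missing.yaml"), "not found")
})

test_that("bundled reference tables load and are consistent", {
  ev <- exvivo_reference()
  expect_equal(nrow(ev), 10)
  expect_equal(ev$percent,
               round_half_up(100 * ev$software_ml /
                               ev$water_displacement_ml, 2))
  counts <- cohort_reference_counts()
  expect_equal(sum(counts$n[counts$category == "tendon_group"]), 149)
  orr <- or_reference()
  expect_equal(orr$stage_I_n + orr$stage_II_n + orr$stage_III_n, orr$n)
  expect_true(surface_ratio_reference() > 0 &&
                surface_ratio_reference() < 1)
})
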