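#' Bundled reference measurements
#'
#' Small plain-text tables shipped with the package, taken from the
#' clinical validation series the package models:
#'
#' * `exvivo_reference()` — ten muscle specimens measured both by physical
#'   water-displacement volumetry and by software slice-stack volumetry
#'   (mL), with the recovery percentage.
#' * `cohort_reference_counts()` — the cohort composition: tendon-status
#'   group sizes and tear-grade counts (Ellman grades for partial tears,
#'   Patte grades for full-thickness tears).
#' * `or_reference()` — per-group occupation-ratio means, observed
#'   ranges, Thomazeau stage counts, and group mean 3D muscle volumes.
#' * `surface_ratio_reference()` — the reported Y-view muscle surface of
#'   full-thickness tears relative to intact tendons (a plain ratio).
#'
#' These are used as worked-example inputs and as comparison points for
#' the phantom experiments; they are measurements, not simulation output.
#'
#' @return a tibble (or a single number for
#'   `surface_ratio_reference()`).
#' @export
exvivo_reference <- function() {
  as_tibble(read.csv(ref_path("exvivo_reference_volumes.csv")))
}

#' @rdname exvivo_reference
#' @export
cohort_reference_counts <- function() {
  as_tibble(read.csv(ref_path("cohort_reference_counts.csv")))
}

#' @rdname exvivo_reference
#' @export
or_reference <- function() {
  as_tibble(read.csv(ref_path("or_reference_by_group.csv")))
}

#' @rdname exvivo_reference
#' @export
surface_ratio_reference <- function() {
  jsonlite::read_json(ref_path("reference_ratios.json"),
                      simplifyVector = TRUE)$yview_surface_ratio_full_vs_intact
}

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "orbias")
  if (p == "") abort(sprintf("bundled reference file missing: %s", file))
  p
}
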