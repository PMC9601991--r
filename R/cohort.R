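#' Cohort specification
#'
#' Describes a synthetic shoulder cohort with the group structure of a
#' clinical series: intact tendons, partial-thickness tears graded by
#' Ellman, and full-thickness tears graded by Patte retraction (default
#' sizes 39/75/35 with Ellman 45/19/11 and Patte 19/10/6). Each subject
#' carries a nominal (pre-morbid) spindle muscle whose envelope defines
#' the bony fossa, an occupation/atrophy factor that scales the muscle
#' radius (volume scales linearly with it, the belly length is
#' preserved), and — for full-thickness tears only — a medial belly
#' retraction drawn by Patte grade.
#'
#' Distribution defaults (see the package vignette for the rationale):
#' nominal volume lognormal around 62 cm^3 (sdlog 0.10); atrophy factor
#' truncated normal per group, 0.93/0.74/0.55 means; belly retraction
#' normal per Patte grade with means 3.5/9/16 mm (floored at 0.6 mm).
#'
#' @param n_intact,n_partial,n_full group sizes.
#' @param ellman_counts length-3 counts of Ellman grades I/II/III among
#'   partial tears; used exactly when they sum to `n_partial`, otherwise
#'   as sampling weights.
#' @param patte_counts length-3 counts of Patte grades 1/2/3 among
#'   full-thickness tears (same convention).
#' @param volume_meanlog,volume_sdlog lognormal parameters of the nominal
#'   muscle volume (cm^3).
#' @param atrophy named list of per-group `c(mean, sd, lo, hi)` truncated
#'   normal parameters for the atrophy factor.
#' @param retraction_by_patte list with `mean`, `sd` (length 3, mm, per
#'   Patte grade) and scalar `min`.
#' @param ellman_depth_ranges 3 x 2 matrix of uniform tear-depth ranges
#'   (mm) per Ellman grade; the defaults stay strictly inside each
#'   grade's band so grading round-trips exactly.
#' @param aspect_ratio,shape_exponent spindle geometry shared by all
#'   subjects.
#' @param fossa_margin_mm,yview_offset_mm phantom morphometry parameters.
#' @param reader_sigma lognormal sigma of per-reader multiplicative area
#'   noise.
#' @param seed optional default seed for [sample_cohort()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_intact = 39, n_partial = 75, n_full = 35,
                        ellman_counts = c(45, 19, 11),
                        patte_counts = c(19, 10, 6),
                        volume_meanlog = log(62) - 0.10^2 / 2,
                        volume_sdlog = 0.10,
                        atrophy = list(
                          intact = c(mean = 0.93, sd = 0.15,
                                     lo = 0.50, hi = 1.10),
                          partial = c(mean = 0.74, sd = 0.16,
                                      lo = 0.35, hi = 1.05),
                          full = c(mean = 0.55, sd = 0.10,
                                   lo = 0.30, hi = 0.85)),
                        retraction_by_patte = list(
                          mean = c(3.5, 9, 16), sd = c(2, 3, 4),
                          min = 0.6),
                        ellman_depth_ranges = rbind(c(0.5, 2.9),
                                                    c(3.0, 6.0),
                                                    c(6.2, 9.5)),
                        aspect_ratio = 3, shape_exponent = 1,
                        fossa_margin_mm = 1.5, yview_offset_mm = 22,
                        reader_sigma = 0.05, seed = NULL) {
  ns <- c(n_intact, n_partial, n_full)
  if (any(ns < 0) || any(ns != round(ns))) {
    abort("group sizes must be non-negative integers")
  }
  if (length(ellman_counts) != 3L || any(ellman_counts < 0) ||
      length(patte_counts) != 3L || any(patte_counts < 0)) {
    abort("ellman_counts and patte_counts must be three counts >= 0")
  }
  ok <- vapply(atrophy, function(a) {
    all(is.finite(a)) && a[["sd"]] >= 0 && a[["lo"]] < a[["hi"]]
  }, logical(1))
  if (!all(ok)) abort("invalid atrophy distribution parameters")
  if (!all(is.finite(unlist(retraction_by_patte)))) {
    abort("invalid retraction distribution parameters")
  }
  structure(list(
    n_intact = as.integer(n_intact), n_partial = as.integer(n_partial),
    n_full = as.integer(n_full),
    ellman_counts = ellman_counts, patte_counts = patte_counts,
    volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
    atrophy = atrophy, retraction_by_patte = retraction_by_patte,
    ellman_depth_ranges = ellman_depth_ranges,
    aspect_ratio = aspect_ratio, shape_exponent = shape_exponent,
    fossa_margin_mm = fossa_margin_mm, yview_offset_mm = yview_offset_mm,
    reader_sigma = reader_sigma, seed = seed), class = "cohort_spec")
}

# truncated normal by resampling
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

# draw grades: exact multiset when counts sum to n, weighted otherwise
draw_grades <- function(n, counts) {
  if (n == 0L) return(integer(0))
  if (sum(counts) == n) {
    sample(rep.int(1:3, counts))
  } else {
    sample(1:3, n, replace = TRUE, prob = counts / sum(counts))
  }
}

#' Sample a synthetic cohort
#'
#' Draws per-subject phantom parameters under a [cohort_spec()]. Sampling
#' is fully reproducible from `seed` (the caller's RNG state is left
#' untouched). Intact and partial-tear subjects always have zero belly
#' retraction; full-thickness subjects draw a retraction by Patte grade.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (defaults to `spec$seed`, then 1).
#' @return tibble, one row per subject: `subject_id`, `group`,
#'   `nominal_volume_cm3`, `atrophy_factor`, `volume_cm3` (analytic),
#'   `ellman_grade`, `tear_depth_mm`, `patte_grade`, `stump_position`,
#'   `retraction_mm`.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_spec(), seed = 1)
#' dplyr::count(cohort, group)
sample_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed %||% 1L
  withr::with_seed(as.integer(seed), {
    groups <- rep(c("intact", "partial", "full"),
                  c(spec$n_intact, spec$n_partial, spec$n_full))
    n <- length(groups)
    nominal <- rlnorm(n, spec$volume_meanlog, spec$volume_sdlog)
    atrophy <- numeric(n)
    for (g in c("intact", "partial", "full")) {
      sel <- groups == g
      a <- spec$atrophy[[g]]
      atrophy[sel] <- rnorm_trunc(sum(sel), a[["mean"]], a[["sd"]],
                                  a[["lo"]], a[["hi"]])
    }
    eg <- draw_grades(spec$n_partial, spec$ellman_counts)
    depth <- runif(spec$n_partial,
                   spec$ellman_depth_ranges[eg, 1],
                   spec$ellman_depth_ranges[eg, 2])
    pg <- draw_grades(spec$n_full, spec$patte_counts)
    rb <- spec$retraction_by_patte
    retr <- pmax(rb$min, rnorm(spec$n_full, rb$mean[pg], rb$sd[pg]))
    ellman_grade <- rep(NA_character_, n)
    ellman_grade[groups == "partial"] <- c("I", "II", "III")[eg]
    tear_depth <- rep(NA_real_, n)
    tear_depth[groups == "partial"] <- depth
    patte <- rep(NA_integer_, n)
    patte[groups == "full"] <- pg
    stump <- rep(NA_character_, n)
    stump[groups == "full"] <-
      c("insertion", "humeral_dome", "glenoid")[pg]
    retraction <- rep(0, n)
    retraction[groups == "full"] <- retr
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = factor(groups, levels = c("intact", "partial", "full")),
      nominal_volume_cm3 = nominal,
      atrophy_factor = atrophy,
      volume_cm3 = nominal * atrophy,
      ellman_grade = factor(ellman_grade, levels = c("I", "II", "III")),
      tear_depth_mm = tear_depth,
      patte_grade = patte,
      stump_position = stump,
      retraction_mm = retraction)
  })
}

#' Phantom specification for one cohort subject
#'
#' Translates a row of [sample_cohort()] output into a [shoulder_spec()]:
#' the nominal spindle defines the fossa basis; the muscle is the nominal
#' spindle with its radius scaled by `sqrt(atrophy_factor)` (so the
#' analytic volume is `nominal * atrophy`); partial tears carve a tendon
#' defect from the Ellman depth; full tears retract the belly.
#'
#' @param subject one-row data frame (a cohort row).
#' @param spec the [cohort_spec()] the cohort was sampled from.
#' @return a [shoulder_spec()].
#' @export
subject_shoulder_spec <- function(subject, spec = cohort_spec()) {
  nominal <- spindle_spec(subject$nominal_volume_cm3,
                          shape_exponent = spec$shape_exponent,
                          aspect_ratio = spec$aspect_ratio)
  muscle <- spindle_spec(length_mm = nominal$length_mm,
                         max_radius_mm = nominal$max_radius_mm *
                           sqrt(subject$atrophy_factor),
                         shape_exponent = spec$shape_exponent)
  defect <- NULL
  if (subject$group == "partial") {
    # depth expressed as fraction of the local tendon diameter at the
    # middle of the defect zone
    diam <- 2 * spindle_radius(0.45 * muscle$length_mm, muscle)
    defect <- list(kind = "partial",
                   depth_mm = subject$tear_depth_mm,
                   fraction = min(1, subject$tear_depth_mm / diam))
  } else if (subject$group == "full") {
    defect <- list(kind = "full",
                   stump_position = subject$stump_position)
  }
  shoulder_spec(muscle, fossa_basis = nominal,
                fossa_margin_mm = spec$fossa_margin_mm,
                yview_offset_mm = spec$yview_offset_mm,
                retraction_mm = subject$retraction_mm,
                tendon_defect = defect)
}
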