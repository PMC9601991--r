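#' Ellman grading of partial-thickness tears
#'
#' Grades a partial-thickness tendon tear by depth: grade I below 3 mm,
#' grade II for 3-6 mm (both bounds inclusive), grade III above 6 mm.
#' When only the fraction of the tendon diameter is known, the paired
#' criterion applies: grade I below 1/4, grade II from 1/4 up to (but not
#' including) 1/2, grade III from 1/2 up (a tie at exactly one half goes
#' to the more severe grade). If both depth and fraction are supplied,
#' depth is the primary criterion and wins.
#'
#' @param depth_mm tear depth in mm (vector; `NA` to fall back on
#'   `fraction`).
#' @param fraction tear depth as fraction of tendon diameter, in `[0, 1]`.
#' @return factor with levels `"I"`, `"II"`, `"III"`.
#' @export
#' @examples
#' ellman_grade(c(2, 4, 7))
#' ellman_grade(fraction = c(0.2, 0.3, 0.6))
ellman_grade <- function(depth_mm = NULL, fraction = NULL) {
  if (is.null(depth_mm) && is.null(fraction)) {
    abort("give depth_mm and/or fraction")
  }
  n <- max(length(depth_mm), length(fraction))
  d <- rep_len(depth_mm %||% NA_real_, n)
  f <- rep_len(fraction %||% NA_real_, n)
  if (any(is.na(d) & is.na(f))) {
    abort("each tear needs a depth or a fraction")
  }
  if (any(!is.na(d) & d < 0)) abort("depth_mm must be >= 0")
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    abort("fraction must be in [0, 1]")
  }
  by_depth <- ifelse(d < 3, "I", ifelse(d <= 6, "II", "III"))
  by_frac <- ifelse(f < 0.25, "I", ifelse(f < 0.5, "II", "III"))
  factor(ifelse(is.na(d), by_frac, by_depth),
         levels = c("I", "II", "III"))
}

#' Patte grading of full-thickness tear retraction
#'
#' Grades a full-thickness tear by the position of the proximal tendon
#' stump: grade 1 near the bony insertion, grade 2 at the level of the
#' dome of the humeral head, grade 3 at (or medial to) the glenoid level.
#'
#' @param stump_position character vector; one of `"insertion"`,
#'   `"humeral_dome"`, `"glenoid"`.
#' @return integer grade 1/2/3.
#' @export
#' @examples
#' patte_grade(c("insertion", "glenoid"))
patte_grade <- function(stump_position) {
  g <- match(stump_position, c("insertion", "humeral_dome", "glenoid"))
  if (any(is.na(g))) {
    bad <- unique(stump_position[is.na(g)])
    abort(sprintf("unknown stump position: %s",
                  paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  g
}
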