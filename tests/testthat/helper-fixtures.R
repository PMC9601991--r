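# shared fixtures: small rasterized shapes and independent geometry oracles

# filled axis-aligned rectangle of a x b pixels inside a padded slice
rect_slice <- function(a, b, spacing = c(1, 1), pad = 2) {
  m <- matrix(FALSE, a + 2 * pad, b + 2 * pad)
  m[pad + seq_len(a), pad + seq_len(b)] <- TRUE
  attr(m, "pixel_spacing_mm") <- spacing
  m
}

# digitized disk: pixel centres within radius_mm of the centre
disk_slice <- function(radius_mm, pixel_mm = 1, pad = 2) {
  n <- 2 * ceiling(radius_mm / pixel_mm) + 2 * pad + 1
  cx <- ((seq_len(n)) - (n + 1) / 2) * pixel_mm
  m <- outer(cx^2, cx^2, `+`) <= radius_mm^2
  attr(m, "pixel_spacing_mm") <- c(pixel_mm, pixel_mm)
  m
}

# corner vertices of all foreground pixels (same convention as the
# package, rebuilt independently)
corner_points <- function(mask_slice, spacing = attr(mask_slice,
                                                     "pixel_spacing_mm")) {
  idx <- which(mask_slice, arr.ind = TRUE)
  xs <- c(idx[, 1] - 1, idx[, 1], idx[, 1] - 1, idx[, 1]) * spacing[1]
  ys <- c(idx[, 2] - 1, idx[, 2] - 1, idx[, 2], idx[, 2]) * spacing[2]
  unique(cbind(xs, ys))
}

# oracle 1: brute-force maximum pairwise distance over all corner points
feret_bruteforce <- function(pts) {
  d2 <- outer(pts[, 1], pts[, 1], `-`)^2 +
    outer(pts[, 2], pts[, 2], `-`)^2
  sqrt(max(d2))
}

# oracle 2: caliper extent swept over a fine grid of directions;
# the maximum over directions is the Feret diameter
feret_sweep <- function(pts, n_angles = 1800) {
  th <- seq(0, pi, length.out = n_angles)
  ext <- vapply(th, function(a) {
    p <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  max(ext)
}

# caliper extent of the point set along a fixed direction (radians)
extent_along <- function(pts, angle) {
  p <- pts[, 1] * cos(angle) + pts[, 2] * sin(angle)
  max(p) - min(p)
}

# small random blob slices for property tests
random_blob <- function(n = 12, seed = 1, spacing = c(1, 1)) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, n, n)
    k <- sample(3:8, 1)
    ctr <- cbind(runif(k, 3, n - 2), runif(k, 3, n - 2))
    r <- runif(k, 1, 3)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (any((ctr[, 1] - i)^2 + (ctr[, 2] - j)^2 <= r^2)) m[i, j] <- TRUE
    }
    attr(m, "pixel_spacing_mm") <- spacing
    m
  })
}
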