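# Fixture builders and independent oracles used across the suite. Oracles are
# deliberately written as plain, explicit computations (loops, closed-form
# sums) so they share no code path with the package implementation.

make_vol <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     sequence_id = "map", intensity_range = NULL) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  mq_volume(data, aff, sequence_id = sequence_id,
            intensity_range = intensity_range)
}

# Two-segment (codes II and V) toy label map on an axis-aligned grid.
make_toy_labels <- function(dim3 = c(32L, 32L, 8L), spacing = c(1.5, 1.5, 3),
                            origin = c(0, 0, 0)) {
  arr <- array(0, dim3)
  arr[5:16, 5:28, ] <- liver_label_scheme[["II"]]
  arr[17:28, 5:28, ] <- liver_label_scheme[["V"]]
  arr[14:18, 14:18, ] <- liver_label_scheme[["portal_vessels"]]
  as_label_map(make_vol(arr, spacing, origin, sequence_id = "labels"))
}

# Brute-force reference: per-voxel world-coordinate label lookup with its own
# exhaustive slice matching. NA where the world point leaves the source
# in-plane extent.
oracle_transfer <- function(labels, map_vol) {
  dm <- dim(map_vol$data)
  dl <- dim(labels$data)
  Ainv <- solve(labels$affine)
  out <- array(NA_integer_, dm)
  src_centers <- t(vapply(seq_len(dl[3]) - 1L, function(s)
    (labels$affine %*% c((dl[1] - 1) / 2, (dl[2] - 1) / 2, s, 1))[1:3],
    numeric(3)))
  for (k in seq_len(dm[3]) - 1L) {
    cm <- (map_vol$affine %*% c((dm[1] - 1) / 2, (dm[2] - 1) / 2, k, 1))[1:3]
    dists <- sqrt(colSums((t(src_centers) - cm)^2))
    s <- which.min(dists) - 1L
    for (i in seq_len(dm[1]) - 1L) {
      for (j in seq_len(dm[2]) - 1L) {
        w <- map_vol$affine %*% c(i, j, k, 1)
        v <- Ainv %*% w
        ix <- floor(v[1] + 0.5); iy <- floor(v[2] + 0.5)
        if (ix >= 0 && ix < dl[1] && iy >= 0 && iy < dl[2])
          out[i + 1, j + 1, k + 1] <- labels$data[ix + 1, iy + 1, s + 1]
      }
    }
  }
  out
}

# Reference ICC(1,1) through stats::aov (a different route than the
# implementation's explicit mean squares).
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)))
  tab <- summary(stats::aov(v ~ subj, data = df))[[1]]
  msb <- tab["subj", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# Reference histogram entropy by direct -sum(p log2 p).
oracle_entropy <- function(values, bins, lo, hi) {
  edges <- seq(lo, hi, length.out = bins + 1)
  counts <- integer(bins)
  for (v in values) {
    b <- min(max(1L, findInterval(v, edges, rightmost.closed = TRUE)), bins)
    counts[b] <- counts[b] + 1L
  }
  p <- counts[counts > 0] / length(values)
  -sum(p * log2(p))
}

# Reference bilinear interpolation + zero-normalized cross-correlation.
oracle_bilinear <- function(slice, x, y) {
  x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
  (1 - fx) * (1 - fy) * slice[cbind(x0 + 1, y0 + 1)] +
    fx * (1 - fy) * slice[cbind(x0 + 2, y0 + 1)] +
    (1 - fx) * fy * slice[cbind(x0 + 1, y0 + 2)] +
    fx * fy * slice[cbind(x0 + 2, y0 + 2)]
}

oracle_ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Small phantom used by the optimizer tests: segments IVa/IVb land in
# [50, 75) transferred voxels and III/VII below 100, so the minimum-size
# thresholds 50/75/100 discriminate by construction.
small_phantom_spec <- function(seed, ...) {
  phantom_spec(seed = seed,
               source_dim = c(96L, 96L, 48L), source_pixel = 1.19,
               map_dim = c(48L, 48L, 4L), map_pixel = 1.88,
               map_spacing = 20, map_z0 = 41.5,
               liver_semiaxes = c(20, 17, 45), vessel_radius = 3,
               ...)
}

# One-segment, one-slice exam with exactly n ROI voxels of near-constant
# values: source, labels and map share one identity-spacing grid.
tiny_exam <- function(n, dim2 = c(12L, 12L), value_lo = 830, value_hi = 840,
                      seed = 1) {
  stopifnot(n <= prod(dim2))
  arr <- array(0, c(dim2, 1L))
  arr[seq_len(n)] <- liver_label_scheme[["V"]]
  labels <- as_label_map(make_vol(arr, sequence_id = "labels"))
  vals <- array(0, c(dim2, 1L))
  vals[seq_len(n)] <- with_seed_runif(seed, n, value_lo, value_hi)
  map <- make_vol(vals, sequence_id = "t1_pre", intensity_range = c(0, 4095))
  list(source = map, labels = labels, map = map)
}

with_seed_runif <- function(seed, n, lo, hi) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  runif(n, lo, hi)
}
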