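# Quality control for transferred ROIs. Five configurable measures:
#   1. ROI erosion        — strips potentially ambiguous boundary voxels
#   2. source-slice subselection — NCC-based breathing compensation
#   3. voxel outlier removal     — total-liver median +/- k * MAD band
#   4. high-entropy detection    — omits ROIs dominated by noise/artifact
#   5. minimum ROI size          — omits insignificant regions
# Applied in that order, so the final voxel count reflects every removal.

.entropy_variants <- list(
  # thresholds in bits; the 32-bin variants scale the 64-bin thresholds by
  # log2(32)/log2(64) so "strict"/"lenient" mean the same fraction of the
  # maximal achievable entropy. Calibration defaults, exposed in the config.
  strict64  = list(bins = 64L, threshold = 4.5),
  lenient64 = list(bins = 64L, threshold = 5.5),
  strict32  = list(bins = 32L, threshold = 4.5 * 5 / 6),
  lenient32 = list(bins = 32L, threshold = 5.5 * 5 / 6)
)

#' Quality-control configuration
#'
#' Bundles the five ROI quality-control hyperparameters. The optimization
#' grid spans erosion none/small/large, minimum ROI sizes 50/75/100 voxels,
#' outlier removal off or median +/- 3 MAD, four entropy-detection variants
#' (32 or 64 histogram bins, strict or lenient threshold) or off, and
#' source-slice subselection off or with a neighborhood of 2 or 3 slices.
#'
#' @param erosion `"none"`, `"small"` (1 iteration) or `"large"` (2
#'   iterations) of per-slice 2D erosion with a 3x3 cross.
#' @param min_roi_size Minimum number of analyzed voxels for a measurement;
#'   a count equal to the threshold passes.
#' @param outlier `"mad3"` (total-liver median +/- `outlier_k` * MAD) or
#'   `"off"`.
#' @param outlier_k MAD multiplier (default 3).
#' @param entropy One of `"strict64"`, `"lenient64"`, `"strict32"`,
#'   `"lenient32"`, or `"off"`.
#' @param entropy_bins,entropy_threshold Override the variant's bin count /
#'   threshold (bits); `NULL` takes the variant defaults.
#' @param subselection Enable NCC source-slice subselection.
#' @param neighborhood Subselection neighborhood half-width in source slices
#'   (2 or 3 in the optimization grid).
#' @return An object of class `mq_qc_config`.
#' @export
qc_config <- function(erosion = c("none", "small", "large"),
                      min_roi_size = 50L,
                      outlier = c("mad3", "off"),
                      outlier_k = 3,
                      entropy = c("strict64", "lenient64", "strict32", "lenient32", "off"),
                      entropy_bins = NULL,
                      entropy_threshold = NULL,
                      subselection = FALSE,
                      neighborhood = 2L) {
  erosion <- match.arg(erosion)
  outlier <- match.arg(outlier)
  entropy <- match.arg(entropy)
  stopifnot(min_roi_size >= 1, outlier_k > 0)
  if (entropy != "off") {
    v <- .entropy_variants[[entropy]]
    if (is.null(entropy_bins)) entropy_bins <- v$bins
    if (is.null(entropy_threshold)) entropy_threshold <- v$threshold
    stopifnot(entropy_bins >= 2, entropy_threshold > 0)
  }
  if (subselection) stopifnot(neighborhood >= 1)
  structure(list(erosion = erosion,
                 min_roi_size = as.integer(min_roi_size),
                 outlier = outlier,
                 outlier_k = outlier_k,
                 entropy = entropy,
                 entropy_bins = entropy_bins,
                 entropy_threshold = entropy_threshold,
                 subselection = isTRUE(subselection),
                 neighborhood = as.integer(neighborhood)),
            class = "mq_qc_config")
}

#' The published best configuration
#'
#' Minimum ROI size of 50 analyzed voxels, voxel outlier removal by total
#' liver median +/- 3 * MAD, and high entropy detection; no erosion and no
#' source-slice subselection.
#'
#' @return An `mq_qc_config`.
#' @export
qc_config_optimized <- function() {
  qc_config(erosion = "none", min_roi_size = 50L, outlier = "mad3",
            entropy = "strict64", subselection = FALSE)
}

#' Read a QC configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file whose keys are [qc_config()]
#'   arguments.
#' @return An `mq_qc_config`.
#' @export
read_qc_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  lst <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(qc_config, lst)
}

#' @export
print.mq_qc_config <- function(x, ...) {
  cat(sprintf("<mq_qc_config> erosion=%s min_size=%d outlier=%s entropy=%s subselection=%s\n",
              x$erosion, x$min_roi_size,
              if (x$outlier == "mad3") sprintf("median+/-%g*MAD", x$outlier_k) else "off",
              x$entropy,
              if (x$subselection) sprintf("nbhd %d", x$neighborhood) else "off"))
  invisible(x)
}

# ---- erosion ----------------------------------------------------------------

# One iteration of 2D binary erosion with the 3x3 cross; outside the image
# counts as background, so voxels on the image border are eroded.
.erode_once_2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & up & dn & lf & rt
}

#' Erode an ROI mask
#'
#' Per-slice 2D binary erosion with a 3x3 cross structuring element:
#' `"none"` leaves the mask unchanged, `"small"` applies one iteration and
#' `"large"` two. Erosion never grows the mask; thin structures may vanish
#' entirely (the downstream minimum-size gate handles empty results).
#'
#' @param mask An `mq_roi_mask` or a 3D (or 2D) logical array.
#' @param level `"none"`, `"small"` or `"large"`.
#' @return Same type as `mask`.
#' @export
erode_roi <- function(mask, level = c("none", "small", "large")) {
  level <- match.arg(level)
  iters <- c(none = 0L, small = 1L, large = 2L)[[level]]
  if (inherits(mask, "mq_roi_mask")) {
    mask$mask <- erode_roi(mask$mask, level)
    return(mask)
  }
  if (iters == 0L) return(mask)
  if (is.matrix(mask)) {
    for (i in seq_len(iters)) mask <- .erode_once_2d(mask)
    return(mask)
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  for (k in seq_len(dim(mask)[3]))
    for (i in seq_len(iters))
      mask[, , k] <- .erode_once_2d(mask[, , k])
  mask
}

# ---- gates ------------------------------------------------------------------

qc_outcome <- function(passed, reason, voxels_before, voxels_after) {
  stopifnot(passed == (reason == "ok"), voxels_after <= voxels_before)
  structure(list(passed = passed, reason = reason,
                 voxels_before = as.integer(voxels_before),
                 voxels_after = as.integer(voxels_after)),
            class = "mq_qc_outcome")
}

#' Minimum ROI size gate
#'
#' Passes iff the ROI contains at least `threshold` analyzed voxels (a count
#' equal to the threshold passes: "minimally N analyzed voxels").
#'
#' @param mask An `mq_roi_mask`, logical array, or a plain voxel count.
#' @param threshold Minimum voxel count.
#' @return An `mq_qc_outcome`.
#' @export
min_size_gate <- function(mask, threshold) {
  n <- if (inherits(mask, "mq_roi_mask")) sum(mask$mask)
       else if (is.array(mask) || is.logical(mask)) sum(mask)
       else as.integer(mask)
  if (n >= threshold) qc_outcome(TRUE, "ok", n, n)
  else qc_outcome(FALSE, "below_min_size", n, n)
}

#' Remove voxel outliers by the total-liver median/MAD band
#'
#' Retains values v with |v - liver_median| <= k * liver_MAD, where the
#' median and the (raw, unscaled) median absolute deviation are computed over
#' the union of all segmental ROI voxels on that map, before any per-segment
#' removal. A zero MAD (e.g. constant or heavily quantized maps) disables the
#' band and retains everything.
#'
#' @param values Numeric ROI voxel values (ms).
#' @param liver_median,liver_mad Total-liver statistics (ms).
#' @param k Band multiplier (default 3).
#' @return The retained values.
#' @export
remove_outliers <- function(values, liver_median, liver_mad, k = 3) {
  if (!length(values)) return(values)
  if (liver_mad == 0) return(values)
  values[abs(values - liver_median) <= k * liver_mad]
}

#' Total-liver median and raw MAD
#'
#' @param values Voxel values pooled over all segmental ROIs of one map.
#' @return List with `median` and `mad` (raw median absolute deviation, no
#'   normal-consistency factor).
#' @export
liver_stats <- function(values) {
  med <- stats::median(values)
  list(median = med, mad = stats::median(abs(values - med)))
}

#' Histogram Shannon entropy of ROI intensities
#'
#' Entropy (in bits) of the normalized intensity histogram of the ROI voxels
#' over `value_range`, with `bins` equal-width bins; empty bins contribute 0.
#' Values outside the range are clamped into the terminal bins. High entropy
#' inside an ROI indicates areas of poor data quality (noise, artifacts).
#'
#' @param values Numeric ROI voxel values; must be nonempty.
#' @param bins Number of histogram bins (>= 2).
#' @param value_range `(lo, hi)` histogram support, typically the sequence's
#'   full intensity range.
#' @return Entropy in bits.
#' @export
spatial_entropy <- function(values, bins, value_range) {
  if (!length(values))
    stop("spatial entropy is undefined for an empty ROI", call. = FALSE)
  stopifnot(bins >= 2, value_range[2] > value_range[1])
  b <- floor((values - value_range[1]) / diff(value_range) * bins)
  b <- pmin(pmax(b, 0), bins - 1)
  p <- tabulate(b + 1L, nbins = bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' High-entropy gate
#'
#' Fails (reason `high_entropy`) iff the ROI's spatial entropy exceeds the
#' configured threshold.
#'
#' @param values Nonempty numeric ROI voxel values.
#' @param config An `mq_qc_config` (its `entropy*` fields are used); with
#'   entropy `"off"` the gate always passes.
#' @param value_range Histogram support `(lo, hi)`.
#' @return An `mq_qc_outcome`.
#' @export
entropy_gate <- function(values, config, value_range) {
  n <- length(values)
  if (config$entropy == "off") return(qc_outcome(TRUE, "ok", n, n))
  h <- spatial_entropy(values, config$entropy_bins, value_range)
  if (h > config$entropy_threshold) qc_outcome(FALSE, "high_entropy", n, n)
  else qc_outcome(TRUE, "ok", n, n)
}

# ---- NCC source-slice subselection ------------------------------------------

# Bilinear sample of a 2D slice at continuous 0-based coordinates; NA outside.
.bilinear_sample <- function(slice, x, y) {
  nr <- nrow(slice); nc <- ncol(slice)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= nr - 1 & y <= nc - 1
  # clamp the upper corner so points exactly on the far edge interpolate
  x1 <- pmin(pmax(x0 + 1, 0), nr - 1); y1 <- pmin(pmax(y0 + 1, 0), nc - 1)
  x0 <- pmin(pmax(x0, 0), nr - 1); y0 <- pmin(pmax(y0, 0), nc - 1)
  v <- (1 - fx) * (1 - fy) * slice[cbind(x0 + 1, y0 + 1)] +
       fx       * (1 - fy) * slice[cbind(x1 + 1, y0 + 1)] +
       (1 - fx) * fy       * slice[cbind(x0 + 1, y1 + 1)] +
       fx       * fy       * slice[cbind(x1 + 1, y1 + 1)]
  v[!ok] <- NA_real_
  v
}

# Zero-normalized cross-correlation; -Inf when undefined for the candidate.
.zncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2) return(-Inf)
  a <- a[ok] - mean(a[ok]); b <- b[ok] - mean(b[ok])
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) return(-Inf)
  sum(a * b) / (sa * sb)
}

#' NCC-based source-slice subselection
#'
#' The stringently matched source slice may be anatomically wrong when the
#' patient breathed between acquisitions. Among the source slices within
#' `neighborhood` of the matched index, returns the one maximizing the
#' zero-normalized cross-correlation between the map slice intensities inside
#' the ROI and the candidate source slice intensities resampled (bilinearly)
#' at the same world positions. Ties break to the smallest offset magnitude,
#' then the lower index. If the ROI has zero intensity variance on the map
#' slice, NCC is undefined and the matched index is returned.
#'
#' @param map_vol Parametric map `mq_volume`.
#' @param source_vol Source anatomical `mq_volume`.
#' @param mask_slice Logical in-plane mask of the ROI on map slice `map_k`.
#' @param map_k Map slice index (0-based).
#' @param matched_index Matched source slice index (0-based).
#' @param neighborhood Half-width of the candidate window in source slices.
#' @return Selected source slice index (0-based).
#' @export
subselect_source_slice <- function(map_vol, source_vol, mask_slice, map_k,
                                   matched_index, neighborhood) {
  if (neighborhood <= 0 || !any(mask_slice)) return(matched_index)
  nz <- dim(source_vol$data)[3]
  offs <- c(0L, as.vector(rbind(-seq_len(neighborhood), seq_len(neighborhood))))
  cand <- matched_index + offs
  keep <- cand >= 0L & cand < nz
  cand <- cand[keep]
  if (length(cand) <= 1L) return(matched_index)

  ij <- which(mask_slice, arr.ind = TRUE) - 1L
  map_vals <- map_vol$data[, , map_k + 1L][mask_slice]
  if (stats::var(map_vals) == 0) return(matched_index)

  w <- map_vol$affine %*% rbind(t(ij), map_k, 1)
  sv <- solve(source_vol$affine) %*% w   # continuous source voxel coords
  best <- matched_index; best_ncc <- -Inf
  for (s in cand) {
    samp <- .bilinear_sample(source_vol$data[, , s + 1L], sv[1, ], sv[2, ])
    ncc <- .zncc(map_vals, samp)
    if (ncc > best_ncc) { best_ncc <- ncc; best <- s }
  }
  if (!is.finite(best_ncc)) matched_index else best
}
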