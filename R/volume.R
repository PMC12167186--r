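#' Couinaud label scheme
#'
#' Integer codes used for the twelve-category liver labeling: background (0),
#' the nine Couinaud parenchymal segments (I, II, III, IVa, IVb, V, VI, VII,
#' VIII), and the two vessel classes (portal and hepatic veins). Vessel voxels
#' are never quantified; they are carved out of every segmental ROI.
#'
#' @format Named integer vector mapping category name to label code.
#' @export
liver_label_scheme <- c(
  background      = 0L,
  I    = 1L, II   = 2L, III  = 3L,
  IVa  = 4L, IVb  = 5L,
  V    = 6L, VI   = 7L, VII  = 8L, VIII = 9L,
  portal_vessels  = 10L,
  hepatic_vessels = 11L
)

#' Names of the nine Couinaud parenchymal segments
#' @export
liver_segments <- function() {
  setdiff(names(liver_label_scheme),
          c("background", "portal_vessels", "hepatic_vessels"))
}

vessel_labels <- function() liver_label_scheme[c("portal_vessels", "hepatic_vessels")]

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) || !is.numeric(affine))
    stop("affine must be a numeric 4x4 matrix", call. = FALSE)
  if (!all(is.finite(affine)))
    stop("affine contains non-finite entries", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("non-invertible affine", call. = FALSE)
  invisible(affine)
}

#' Construct a volume
#'
#' A volume is a 3D intensity array together with the 4x4 affine mapping
#' homogeneous 0-based voxel indices (i, j, k) to scanner world coordinates in
#' mm, plus acquisition metadata. Parametric maps carry relaxation times in ms;
#' anatomical acquisitions carry arbitrary units.
#'
#' @param data 3D numeric array, dimension (nx, ny, nz).
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param sequence_id Free-text sequence tag, e.g. `"t1_pre"`, `"t2"`,
#'   `"dixon_ip"`.
#' @param pixel_spacing In-plane (row, col) spacing in mm; derived from the
#'   affine column norms when `NULL`.
#' @param slice_thickness Slice thickness in mm (metadata only).
#' @param slice_spacing Center-to-center slice spacing in mm; derived from the
#'   affine third column norm when `NULL`.
#' @param intensity_range Optional `(lo, hi)` full intensity range of the
#'   sequence, used as the histogram support for entropy gating.
#' @return An object of class `mq_volume`.
#' @export
mq_volume <- function(data, affine, sequence_id = "unknown",
                      pixel_spacing = NULL, slice_thickness = NA_real_,
                      slice_spacing = NULL, intensity_range = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D payload: data must be a 3D array", call. = FALSE)
  if (dim(data)[3] < 1L)
    stop("volume must contain at least one slice", call. = FALSE)
  .check_affine(affine)
  if (is.null(pixel_spacing))
    pixel_spacing <- c(sqrt(sum(affine[1:3, 1]^2)), sqrt(sum(affine[1:3, 2]^2)))
  if (is.null(slice_spacing))
    slice_spacing <- sqrt(sum(affine[1:3, 3]^2))
  if (any(pixel_spacing <= 0) || slice_spacing <= 0)
    stop("pixel_spacing and slice_spacing must be positive", call. = FALSE)
  structure(list(
    data            = data,
    affine          = unname(affine),
    pixel_spacing   = as.numeric(pixel_spacing),
    slice_thickness = as.numeric(slice_thickness),
    slice_spacing   = as.numeric(slice_spacing),
    sequence_id     = sequence_id,
    intensity_range = if (is.null(intensity_range)) NULL else as.numeric(intensity_range)
  ), class = "mq_volume")
}

#' @export
print.mq_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mq_volume '%s'> %d x %d x %d voxels, pixel %.2f x %.2f mm, slice spacing %.2f mm\n",
              x$sequence_id, d[1], d[2], d[3],
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_spacing))
  invisible(x)
}

#' Promote a volume to a label map
#'
#' Checks that the payload is integer-valued, that 0 is the background, and
#' that every nonzero label belongs to the declared scheme.
#'
#' @param vol An `mq_volume` (or arguments accepted by [mq_volume()]).
#' @param scheme Named integer vector mapping category names to codes;
#'   defaults to [liver_label_scheme].
#' @return An object of class `c("mq_label_map", "mq_volume")`.
#' @export
as_label_map <- function(vol, scheme = liver_label_scheme) {
  stopifnot(inherits(vol, "mq_volume"))
  vals <- vol$data
  if (any(vals != round(vals), na.rm = TRUE))
    stop("label map payload is not integer-valued", call. = FALSE)
  present <- sort(unique(as.integer(vals)))
  if (length(present) > length(scheme))
    stop("label map contains more distinct labels than the declared scheme", call. = FALSE)
  unknown <- setdiff(present, unname(scheme))
  if (length(unknown))
    stop("labels outside the declared scheme: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vol$data <- array(as.integer(vals), dim = dim(vals))
  vol$scheme <- scheme
  class(vol) <- c("mq_label_map", "mq_volume")
  vol
}

#' Map voxel indices to world coordinates
#'
#' Applies the volume's affine to 0-based voxel indices. Indices may be a
#' length-3 vector or an n x 3 matrix; fractional indices are allowed (used
#' internally for resampling).
#'
#' @param vol An `mq_volume`.
#' @param index Voxel index triple(s), 0-based.
#' @param check Reject out-of-bounds indices (default `TRUE`).
#' @return World point(s) in mm, same shape as the input.
#' @export
voxel_to_world <- function(vol, index, check = TRUE) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1L)
  stopifnot(ncol(idx) == 3L)
  if (check) {
    d <- dim(vol$data)
    if (any(idx < 0) || any(idx[, 1] > d[1] - 1L) ||
        any(idx[, 2] > d[2] - 1L) || any(idx[, 3] > d[3] - 1L))
      stop("voxel index out of bounds", call. = FALSE)
  }
  w <- vol$affine %*% rbind(t(idx), 1)
  out <- t(w[1:3, , drop = FALSE])
  if (is.matrix(index)) out else drop(out)
}

#' Map world coordinates to (continuous) voxel indices
#'
#' Exact inverse of [voxel_to_world()]; returns continuous 0-based indices
#' (not rounded, not clamped).
#'
#' @param vol An `mq_volume`.
#' @param point World point(s) in mm, length-3 vector or n x 3 matrix.
#' @return Continuous voxel index triple(s), 0-based.
#' @export
world_to_voxel <- function(vol, point) {
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1L)
  stopifnot(ncol(pts) == 3L)
  v <- solve(vol$affine) %*% rbind(t(pts), 1)
  out <- t(v[1:3, , drop = FALSE])
  if (is.matrix(point)) out else drop(out)
}

#' World-space slice center points
#'
#' The center of slice k is defined as the world image of the in-plane central
#' voxel index ((nx-1)/2, (ny-1)/2, k). Using the full affine (rather than the
#' z coordinate alone) keeps the definition meaningful for oblique stacks.
#'
#' @param vol An `mq_volume`.
#' @return nz x 3 matrix of world points (mm), one row per slice.
#' @export
slice_centers <- function(vol) {
  d <- dim(vol$data)
  k <- seq_len(d[3]) - 1L
  idx <- cbind((d[1] - 1) / 2, (d[2] - 1) / 2, k)
  voxel_to_world(vol, idx, check = FALSE)
}

#' Euclidean nearest-neighbor slice correspondence
#'
#' For every slice of a parametric map, finds the source (anatomical) slice
#' whose world-space center point is at minimal Euclidean distance from the
#' map slice's center point. Map slices whose centers lie beyond the source
#' stack extent are clamped to the terminal source slice, with the (positive)
#' distance recorded. Distance ties break toward the lower source index.
#'
#' @param map_vol Parametric map `mq_volume`.
#' @param source_vol Source anatomical `mq_volume`.
#' @return A data frame of class `mq_slice_correspondence` with 0-based
#'   columns `map_slice`, `source_slice` and `world_distance_mm`.
#' @export
match_slices <- function(map_vol, source_vol) {
  stopifnot(inherits(map_vol, "mq_volume"), inherits(source_vol, "mq_volume"))
  if (dim(source_vol$data)[3] < 1L)
    stop("empty source volume", call. = FALSE)
  mc <- slice_centers(map_vol)
  sc <- slice_centers(source_vol)
  n_map <- nrow(mc)
  src <- integer(n_map)
  dist <- numeric(n_map)
  for (k in seq_len(n_map)) {
    d2 <- (sc[, 1] - mc[k, 1])^2 + (sc[, 2] - mc[k, 2])^2 + (sc[, 3] - mc[k, 3])^2
    s <- which.min(d2)            # first minimum = lower source index on ties
    src[k] <- s - 1L
    dist[k] <- sqrt(d2[s])
  }
  structure(data.frame(map_slice = seq_len(n_map) - 1L,
                       source_slice = src,
                       world_distance_mm = dist),
            class = c("mq_slice_correspondence", "data.frame"))
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file with the affine taken verbatim from the
#' file's sform (falling back to the qform per NIfTI semantics, as exposed by
#' RNifti) and intensities under standard scl slope/intercept semantics.
#'
#' @param path Path to the NIfTI file.
#' @param sequence_id Sequence tag to attach.
#' @param intensity_range Optional `(lo, hi)` sequence intensity range.
#' @return An `mq_volume`.
#' @export
read_volume <- function(path, sequence_id = "unknown", intensity_range = NULL) {
  if (!file.exists(path))
    stop("missing file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  dims <- dim(dat)
  attributes(dat) <- list(dim = dims)    # strip NIfTI bookkeeping attributes
  if (length(dims) != 3L)
    stop("non-3D payload in ", path, " (dim = ",
         paste(dims, collapse = "x"), ")", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  .check_affine(aff)
  hdr <- RNifti::niftiHeader(img)
  thick <- as.numeric(hdr$pixdim[4])
  mq_volume(dat, aff, sequence_id = sequence_id,
            slice_thickness = thick, intensity_range = intensity_range)
}

#' Read a NIfTI label map with its sidecar scheme
#'
#' @param path Path to the NIfTI label file.
#' @param scheme_path Optional path to a sidecar JSON object mapping label
#'   integers to category names; defaults to [liver_label_scheme] when absent.
#' @return An `mq_label_map`.
#' @export
read_label_map <- function(path, scheme_path = NULL) {
  vol <- read_volume(path, sequence_id = "labels")
  scheme <- liver_label_scheme
  if (!is.null(scheme_path)) {
    raw <- jsonlite::read_json(scheme_path, simplifyVector = TRUE)
    scheme <- stats::setNames(as.integer(names(raw)), unlist(raw))
  }
  as_label_map(vol, scheme = scheme)
}

#' Write a volume to NIfTI-1
#'
#' The affine is written as the sform (code 2); data are written without
#' rescaling. Label maps round-trip bit-identically as integers.
#'
#' @param vol An `mq_volume` or `mq_label_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param scheme_path Optional path for the label-scheme sidecar JSON (label
#'   maps only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, scheme_path = NULL) {
  stopifnot(inherits(vol, "mq_volume"))
  dat <- vol$data
  datatype <- if (inherits(vol, "mq_label_map")) "int16" else "double"
  img <- RNifti::asNifti(dat, datatype = datatype)
  aff <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  if (inherits(vol, "mq_label_map") && !is.null(scheme_path)) {
    scheme <- vol$scheme
    jsonlite::write_json(as.list(stats::setNames(names(scheme), scheme)),
                         scheme_path, auto_unbox = TRUE)
  }
  invisible(path)
}
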