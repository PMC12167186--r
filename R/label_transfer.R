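# Label transfer: resample the source label map onto a parametric map's voxel
# grid through the shared scanner coordinate frame. Labels are categorical, so
# interpolation is nearest-neighbor by construction. The default mode honors
# the slice-matched design: each map slice looks up labels only on its matched
# source slice (in-plane 2D nearest voxel under the full 3D world transform);
# a free 3D nearest-voxel mode is available behind `mode = "volume"`.

# Nearest integer with deterministic half-up tie break.
.round_half_up <- function(x) floor(x + 0.5)

# Label lookup for one map slice k against source slice s (0-based).
# grid: n x 2 matrix of 0-based in-plane map indices. Returns an integer
# vector with NA for map voxels falling outside the source in-plane extent
# ("no ROI").
.lookup_slice <- function(labels, vox_map, grid, k, s, mode = "slice") {
  d <- dim(labels$data)
  P <- vox_map %*% rbind(t(grid), k, 1)   # 3 x n continuous source voxel coords
  ix <- .round_half_up(P[1, ])
  iy <- .round_half_up(P[2, ])
  iz <- if (mode == "slice") rep(s, ncol(P)) else .round_half_up(P[3, ])
  ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
  out <- rep(NA_integer_, ncol(P))
  if (any(ok))
    out[ok] <- labels$data[cbind(ix[ok] + 1L, iy[ok] + 1L, iz[ok] + 1L)]
  out
}

#' Transfer segmental labels onto a parametric map grid
#'
#' Assigns to each map voxel the label of the nearest source voxel in world
#' coordinates, slice-by-slice against the matched source slice (see
#' [match_slices()]). Vessel labels are excluded from every segmental ROI;
#' map voxels whose world position falls outside the source in-plane extent
#' carry no ROI.
#'
#' @param labels An `mq_label_map` on the source grid.
#' @param map_vol Parametric map `mq_volume`.
#' @param correspondence Optional precomputed [match_slices()] result;
#'   computed when `NULL`.
#' @param mode `"slice"` (default; 2D nearest voxel within the matched source
#'   slice) or `"volume"` (free 3D nearest voxel).
#' @return An object of class `mq_roi_set`: a list with the per-segment
#'   masks (`masks`, named list of `mq_roi_mask`), the transferred integer
#'   label array (`transferred`, NA = no ROI), the correspondence used, and
#'   the map sequence tag.
#' @export
transfer_labels <- function(labels, map_vol, correspondence = NULL,
                            mode = c("slice", "volume")) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "mq_label_map"), inherits(map_vol, "mq_volume"))
  if (is.null(correspondence))
    correspondence <- match_slices(map_vol, labels)
  dm <- dim(map_vol$data)
  vox_map <- (solve(labels$affine) %*% map_vol$affine)[1:3, , drop = FALSE]
  grid <- cbind(rep(seq_len(dm[1]) - 1L, dm[2]),
                rep(seq_len(dm[2]) - 1L, each = dm[1]))
  transferred <- array(NA_integer_, dm)
  source_slice_used <- integer(dm[3])
  for (r in seq_len(nrow(correspondence))) {
    k <- correspondence$map_slice[r]
    s <- correspondence$source_slice[r]
    transferred[, , k + 1L] <- .lookup_slice(labels, vox_map, grid, k, s, mode)
    source_slice_used[k + 1L] <- s
  }
  if (all(is.na(transferred)))
    warning("no world-space overlap between label map and parametric map; all ROIs empty",
            call. = FALSE)
  .roi_set_from_transferred(transferred, labels$scheme, map_vol$sequence_id,
                            source_slice_used, correspondence)
}

.roi_set_from_transferred <- function(transferred, scheme, sequence_id,
                                      source_slice_used, correspondence) {
  seg_codes <- scheme[liver_segments()[liver_segments() %in% names(scheme)]]
  masks <- list()
  for (seg in names(seg_codes)) {
    m <- !is.na(transferred) & transferred == seg_codes[[seg]]
    if (any(m)) {
      masks[[seg]] <- structure(list(
        segment = seg,
        map_sequence_id = sequence_id,
        mask = m,
        source_slice_used = source_slice_used
      ), class = "mq_roi_mask")
    }
  }
  structure(list(masks = masks,
                 transferred = transferred,
                 scheme = scheme,
                 correspondence = correspondence,
                 map_sequence_id = sequence_id),
            class = "mq_roi_set")
}

#' @export
print.mq_roi_set <- function(x, ...) {
  cat(sprintf("<mq_roi_set on '%s'> %d segment ROI(s): %s\n",
              x$map_sequence_id, length(x$masks),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Export a transferred label map as a NIfTI debug volume
#'
#' Writes the transferred integer labels (background 0 where no ROI) on the
#' parametric map grid, for visual inspection of the co-registration.
#'
#' @param roi_set An `mq_roi_set` from [transfer_labels()].
#' @param map_vol The parametric map the set was transferred onto.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_transferred_labels <- function(roi_set, map_vol, path) {
  arr <- roi_set$transferred
  arr[is.na(arr)] <- 0L
  lm <- as_label_map(mq_volume(array(as.numeric(arr), dim = dim(arr)),
                               map_vol$affine,
                               sequence_id = paste0(roi_set$map_sequence_id, "_labels")),
                     scheme = roi_set$scheme)
  write_volume(lm, path)
}
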