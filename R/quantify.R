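# Per-exam pipeline: slice matching -> label transfer -> QC -> volumetric ROI
# quantification. Extraction (transfer + erosion + slice subselection) is
# separated from gating (outlier removal + entropy + minimum size) so the
# hyperparameter grid search can reuse extracted voxel values across the
# cheap gate settings.

# Stage A: transfer labels onto each map and collect per-segment voxel values
# after erosion and (optionally) NCC source-slice subselection.
.extract_exam_rois <- function(source, labels, maps, erosion = "none",
                               subselection = FALSE, neighborhood = 2L) {
  out <- list()
  for (map_vol in maps) {
    corr <- match_slices(map_vol, source)
    rois <- suppressWarnings(transfer_labels(labels, map_vol, corr))
    nz <- dim(map_vol$data)[3]
    segs <- list()
    for (seg in liver_segments()) {
      rm0 <- rois$masks[[seg]]
      if (is.null(rm0)) {
        segs[[seg]] <- list(values = numeric(0), per_slice = integer(nz),
                            n_transferred = 0L,
                            source_slices = rep(NA_integer_, nz))
        next
      }
      n_transferred <- sum(rm0$mask)
      mask <- erode_roi(rm0$mask, erosion)
      source_slices <- rm0$source_slice_used
      if (subselection) {
        code <- rois$scheme[[seg]]
        vox_map <- (solve(labels$affine) %*% map_vol$affine)[1:3, , drop = FALSE]
        dm <- dim(map_vol$data)
        grid <- cbind(rep(seq_len(dm[1]) - 1L, dm[2]),
                      rep(seq_len(dm[2]) - 1L, each = dm[1]))
        for (k in seq_len(nz) - 1L) {
          if (!any(mask[, , k + 1L])) next
          matched <- corr$source_slice[corr$map_slice == k]
          sel <- subselect_source_slice(map_vol, source, mask[, , k + 1L],
                                        k, matched, neighborhood)
          if (sel != matched) {
            lab_k <- .lookup_slice(labels, vox_map, grid, k, sel)
            m_k <- matrix(!is.na(lab_k) & lab_k == code, dm[1], dm[2])
            mask[, , k + 1L] <- erode_roi(m_k, erosion)
            source_slices[k + 1L] <- sel
          }
        }
      }
      segs[[seg]] <- list(
        values = map_vol$data[mask],
        per_slice = apply(mask, 3, sum),
        n_transferred = n_transferred,
        source_slices = source_slices
      )
    }
    out[[map_vol$sequence_id]] <- list(
      segments = segs,
      intensity_range = if (is.null(map_vol$intensity_range))
        range(map_vol$data) else map_vol$intensity_range,
      correspondence = corr
    )
  }
  out
}

# Stage B: apply outlier removal, entropy and minimum-size gates to the
# extracted values of one map and quantify.
.gate_sequence <- function(extracted_seq, config, exam_id, sequence_id) {
  segs <- extracted_seq$segments
  pooled <- unlist(lapply(segs, `[[`, "values"), use.names = FALSE)
  ls <- if (length(pooled)) liver_stats(pooled) else list(median = NA_real_, mad = NA_real_)
  rows <- list()
  total_vals <- numeric(0)
  total_n <- 0L
  for (seg in names(segs)) {
    s <- segs[[seg]]
    vals <- s$values
    reason <- "ok"
    retained <- vals
    if (s$n_transferred == 0L) {
      reason <- "no_segment_in_source"
    } else if (!length(vals)) {
      reason <- "below_min_size"            # emptied by erosion
    } else {
      if (config$outlier == "mad3") {
        retained <- remove_outliers(vals, ls$median, ls$mad, config$outlier_k)
        if (!length(retained)) reason <- "emptied_by_outlier_removal"
      }
      if (reason == "ok") {
        eg <- entropy_gate(retained, config, extracted_seq$intensity_range)
        if (!eg$passed) reason <- "high_entropy"
      }
      if (reason == "ok" && length(retained) < config$min_roi_size)
        reason <- "below_min_size"
    }
    passed <- reason == "ok"
    if (passed) { total_vals <- c(total_vals, retained); total_n <- total_n + length(retained) }
    rows[[seg]] <- data.frame(
      exam_id = exam_id, sequence_id = sequence_id, segment = seg,
      mean_ms = if (passed) mean(retained) else NA_real_,
      median_ms = if (passed) stats::median(retained) else NA_real_,
      voxels = length(retained),
      voxels_transferred = s$n_transferred,
      passed = passed, reason = reason,
      stringsAsFactors = FALSE
    )
  }
  list(
    measurements = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    total = data.frame(
      exam_id = exam_id, sequence_id = sequence_id,
      mean_ms = if (total_n) mean(total_vals) else NA_real_,
      median_ms = if (total_n) stats::median(total_vals) else NA_real_,
      voxels = total_n, stringsAsFactors = FALSE
    )
  )
}

#' Quantify a post-QC segmental ROI
#'
#' Volumetric ROI mean: the mean voxel value pooled over all axial slices
#' containing the ROI. This equals the per-slice means weighted by per-slice
#' voxel counts, so the slice-weighted manual protocol is recovered
#' automatically.
#'
#' @param map_vol Parametric map `mq_volume`.
#' @param mask An `mq_roi_mask` or logical array congruent with the map.
#' @param outcome Optional `mq_qc_outcome`; a failed outcome is an error
#'   (omitted segments have no measurement).
#' @return List with `mean_ms`, `median_ms`, `voxel_count` and
#'   `per_slice_counts`.
#' @export
quantify_segment <- function(map_vol, mask, outcome = NULL) {
  if (!is.null(outcome) && !outcome$passed)
    stop("cannot quantify a segment that failed quality control (",
         outcome$reason, ")", call. = FALSE)
  m <- if (inherits(mask, "mq_roi_mask")) mask$mask else mask
  if (!any(m))
    stop("cannot quantify an empty ROI", call. = FALSE)
  vals <- map_vol$data[m]
  list(mean_ms = mean(vals),
       median_ms = stats::median(vals),
       voxel_count = length(vals),
       per_slice_counts = apply(m, 3, sum))
}

#' Run the full quantification pipeline on one exam
#'
#' For each parametric map: matches slices to the source acquisition,
#' transfers the segmental labels through the shared world frame, applies the
#' configured quality-control chain (erosion, source-slice subselection,
#' total-liver median/MAD outlier removal, entropy gate, minimum-size gate —
#' in that order), and computes volumetric segmental and total-liver ROI
#' statistics. Deterministic given inputs and configuration. Every segment of
#' the scheme yields either a measurement or a reasoned omission.
#'
#' @param source Source anatomical `mq_volume` (e.g. T1 VIBE Dixon in-phase).
#' @param labels `mq_label_map` co-registered with `source`.
#' @param maps List of parametric map `mq_volume`s.
#' @param config An `mq_qc_config`.
#' @param exam_id Identifier copied into the output tables.
#' @return An `mq_exam_result`: list with `measurements` (one row per
#'   segment x sequence), `total` (per-sequence total liver) and the QC
#'   `config` used.
#' @export
run_exam <- function(source, labels, maps, config = qc_config_optimized(),
                     exam_id = "exam") {
  stopifnot(inherits(config, "mq_qc_config"))
  if (inherits(maps, "mq_volume")) maps <- list(maps)
  extracted <- .extract_exam_rois(source, labels, maps,
                                  erosion = config$erosion,
                                  subselection = config$subselection,
                                  neighborhood = config$neighborhood)
  meas <- list(); tot <- list()
  for (sid in names(extracted)) {
    g <- .gate_sequence(extracted[[sid]], config, exam_id, sid)
    meas[[sid]] <- g$measurements
    tot[[sid]] <- g$total
  }
  structure(list(
    measurements = do.call(rbind, c(meas, list(make.row.names = FALSE))),
    total = do.call(rbind, c(tot, list(make.row.names = FALSE))),
    config = config,
    exam_id = exam_id
  ), class = "mq_exam_result")
}

#' @export
print.mq_exam_result <- function(x, ...) {
  n_pass <- sum(x$measurements$passed)
  cat(sprintf("<mq_exam_result '%s'> %d/%d segment measurements passed QC over %d sequence(s)\n",
              x$exam_id, n_pass, nrow(x$measurements),
              length(unique(x$measurements$sequence_id))))
  if (n_pass < nrow(x$measurements)) {
    om <- x$measurements[!x$measurements$passed, ]
    cat("omissions:\n")
    for (i in seq_len(nrow(om)))
      cat(sprintf("  %s / %s: %s\n", om$sequence_id[i], om$segment[i], om$reason[i]))
  }
  invisible(x)
}

#' Write exam measurements to CSV
#'
#' Columns: exam_id, sequence_id, segment, mean_ms, median_ms, voxels,
#' voxels_transferred, passed, reason; total-liver rows carry segment
#' `"total_liver"`.
#'
#' @param result An `mq_exam_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(result, path) {
  tot <- result$total
  tot$segment <- "total_liver"
  tot$voxels_transferred <- NA_integer_
  tot$passed <- tot$voxels > 0
  tot$reason <- ifelse(tot$passed, "ok", "no_segment_in_source")
  df <- rbind(result$measurements,
              tot[, names(result$measurements)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
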