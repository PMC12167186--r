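# Grid search over the QC hyperparameters on an optimization dataset,
# scored by an objective balancing mean ICC (up), ICC variability (down) and
# measurement coverage relative to the manual reader (up). The extraction
# stage (transfer + erosion + slice subselection) is cached per exam, since
# the remaining gates act only on the extracted voxel values.

#' Multi-criteria objective for QC configuration scoring
#'
#' `f = mean_icc - alpha * icc_sd + beta * coverage`: strictly increasing in
#' the mean ICC and in coverage, strictly decreasing in the ICC standard
#' deviation. The linear form and unit default weights are this package's
#' declared convention; both weights are exposed so alternative weightings
#' can be restored.
#'
#' @param mean_icc Mean ICC over segment x sequence cells.
#' @param icc_sd Standard deviation of those ICCs.
#' @param coverage Measurements performed / measurements available to the
#'   manual reader, in `[0, 1]`.
#' @param alpha,beta Positive weights (default 1 each).
#' @return The scalar score.
#' @export
objective_f <- function(mean_icc, icc_sd, coverage, alpha = 1, beta = 1) {
  stopifnot(all(coverage >= 0 & coverage <= 1))
  mean_icc - alpha * icc_sd + beta * coverage
}

#' The full QC hyperparameter grid
#'
#' Every combination of erosion (none/small/large), minimum ROI size
#' (50/75/100), outlier removal (off / median +/- 3 MAD), entropy detection
#' (off or one of the four variants), and source-slice subselection (off or
#' neighborhood 2 or 3): 270 configurations.
#'
#' @return Data frame with one row per configuration.
#' @export
default_qc_grid <- function() {
  g <- expand.grid(
    erosion = c("none", "small", "large"),
    min_roi_size = c(50L, 75L, 100L),
    outlier = c("off", "mad3"),
    entropy = c("off", "strict64", "lenient64", "strict32", "lenient32"),
    subselection = c("off", "nbhd2", "nbhd3"),
    stringsAsFactors = FALSE
  )
  g
}

.grid_row_to_config <- function(row) {
  qc_config(erosion = row$erosion,
            min_roi_size = row$min_roi_size,
            outlier = row$outlier,
            entropy = if (row$entropy == "off") "off" else row$entropy,
            subselection = row$subselection != "off",
            neighborhood = if (row$subselection == "nbhd3") 3L else 2L)
}

.config_label <- function(row) {
  paste(row$erosion, row$min_roi_size, row$outlier, row$entropy,
        row$subselection, sep = "_")
}

#' Grid search for the best QC configuration
#'
#' Evaluates every configuration of `grid` on a dataset of exams with
#' reference (manual) measurements. For each configuration, the pipeline is
#' run on every exam; ICC(1,1) is computed per (sequence, segment) cell
#' across exams (cells with fewer than `min_pairs` complete pairs are
#' excluded); the configuration score is [objective_f()] of the mean and SD
#' of those ICCs and of the measurement coverage. Configurations with no
#' valid cell are skipped with a warning. The ranking is deterministic:
#' descending score, ties broken by higher coverage, then configuration
#' label.
#'
#' @param exams List of exams; each a list with elements `source`
#'   (`mq_volume`), `labels` (`mq_label_map`), `maps` (list of `mq_volume`)
#'   and `exam_id`.
#' @param manual Data frame with columns exam_id, sequence_id, segment,
#'   value_ms.
#' @param grid Data frame as produced by [default_qc_grid()] (any subset of
#'   its rows/levels).
#' @param alpha,beta Objective weights.
#' @param min_pairs Minimum complete pairs per ICC cell (default 3).
#' @return Data frame of class `mq_grid_result`, ranked best-first, with the
#'   configuration columns plus `mean_icc`, `icc_sd`, `n_measurements`,
#'   `n_manual`, `coverage`, `f_score`.
#' @export
grid_search <- function(exams, manual, grid = default_qc_grid(),
                        alpha = 1, beta = 1, min_pairs = 3L) {
  stopifnot(nrow(grid) >= 1)
  # cache stage-A extraction per exam per (erosion, subselection) setting
  extraction_key <- function(row) paste(row$erosion, row$subselection, sep = "|")
  cache <- new.env(parent = emptyenv())
  get_extraction <- function(exam, row) {
    key <- paste(exam$exam_id, extraction_key(row), sep = "@")
    if (!is.null(cache[[key]])) return(cache[[key]])
    ex <- .extract_exam_rois(exam$source, exam$labels, exam$maps,
                             erosion = row$erosion,
                             subselection = row$subselection != "off",
                             neighborhood = if (row$subselection == "nbhd3") 3L else 2L)
    cache[[key]] <- ex
    ex
  }
  n_manual <- sum(is.finite(manual$value_ms))
  out <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    row <- grid[gi, , drop = FALSE]
    config <- .grid_row_to_config(row)
    auto <- do.call(rbind, lapply(exams, function(exam) {
      extracted <- get_extraction(exam, row)
      do.call(rbind, lapply(names(extracted), function(sid) {
        .gate_sequence(extracted[[sid]], config, exam$exam_id, sid)$measurements
      }))
    }))
    tab <- agreement_table(auto, manual)
    n_meas <- sum(is.finite(tab$auto_value) & is.finite(tab$manual_value))
    cells <- split(tab, list(tab$sequence_id, tab$segment), drop = TRUE)
    iccs <- vapply(cells, function(cell) {
      ok <- is.finite(cell$manual_value) & is.finite(cell$auto_value)
      if (sum(ok) < min_pairs) return(NA_real_)
      icc_1_1(cell$manual_value[ok], cell$auto_value[ok])$icc
    }, numeric(1))
    iccs <- iccs[is.finite(iccs)]
    if (!length(iccs)) {
      warning("configuration ", .config_label(row),
              " skipped: no cell with >= ", min_pairs, " measurable pairs",
              call. = FALSE)
      next
    }
    mean_icc <- mean(iccs)
    icc_sd <- if (length(iccs) > 1) stats::sd(iccs) else 0
    coverage <- if (n_manual > 0) n_meas / n_manual else 0
    out[[gi]] <- cbind(row, data.frame(
      config = .config_label(row),
      mean_icc = mean_icc, icc_sd = icc_sd,
      n_measurements = n_meas, n_manual = n_manual,
      coverage = coverage,
      f_score = objective_f(mean_icc, icc_sd, coverage, alpha, beta),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(res) || nrow(res) == 0)
    stop("no configuration could be scored on this dataset", call. = FALSE)
  res <- res[order(-res$f_score, -res$coverage, res$config), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mq_grid_result", "data.frame")
  res
}
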