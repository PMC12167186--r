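# Synthetic mpMRI phantom: a thin-slice anatomical source volume with a
# twelve-category Couinaud label map, plus co-acquired parametric maps (4
# axial slices) rendered from per-segment ground-truth relaxation times.
# The geometry is a schematic wedged ellipsoid — nothing downstream depends
# on anatomical realism, only on labels, affines and values. A smooth
# multiplicative "texture" field (shared between the anatomical volume and
# the maps, as real parenchymal structure is) gives the NCC slice
# subselection something to lock onto; it is mean-zero-ish over any ROI and
# is switched off together with the noise for exactness tests.

# Hierarchical ground-truth model: the population spread of liver relaxation
# times (total sd anchored at 50 / 30 / 4 ms around 835 / 518 / 37 ms) is
# carried almost entirely by an exam-level baseline, with small per-segment
# offsets on top — diffuse liver parenchyma is close to homogeneous across
# Couinaud segments within one patient. Marginally, per-segment values are
# N(mean, total_sd^2). exam_sd = sqrt(total_sd^2 - segment_sd^2).
.default_truth_params <- list(
  t1_pre  = c(mean = 835, total_sd = 50, segment_sd = 8),
  t1_post = c(mean = 518, total_sd = 30, segment_sd = 5),
  t2      = c(mean = 37,  total_sd = 4,  segment_sd = 0.3)
)

.default_intensity_ranges <- list(
  t1_pre = c(0, 4095), t1_post = c(0, 4095), t2 = c(0, 409.5),
  dixon_ip = c(0, 2028)
)

.vessel_values <- list(                      # blood-pool values per sequence
  t1_pre = 1600, t1_post = 300, t2 = 60
)

#' Phantom specification
#'
#' Describes a synthetic liver mpMRI exam: a thin-slice (3 mm) anatomical
#' source stack with its label map and three parametric maps (4 slices, 8 mm
#' thickness, 20-32 mm spacing). Geometry and value ranges mirror a typical
#' clinical liver protocol: source pixel spacing around 1.19-1.56 mm, map
#' pixel spacing around 1.41-2.19 mm, noncontrast T1 around 835 ms,
#' post-contrast T1 around 518 ms, T2 around 37 ms.
#'
#' @param seed RNG seed; a fixed seed yields bit-identical phantoms.
#' @param source_dim,source_pixel,source_slice Source grid (nx, ny, nz),
#'   in-plane spacing (mm) and slice spacing = thickness (mm).
#' @param map_dim,map_pixel,map_spacing,map_thickness Map grid, in-plane
#'   spacing (mm), center-to-center slice spacing (mm) and thickness (mm).
#' @param map_z0 World z of the first map slice center (mm).
#' @param sequences Parametric sequences to render (subset of
#'   `"t1_pre"`, `"t1_post"`, `"t2"`).
#' @param noise_sigma Gaussian voxel noise, as a fraction of the local
#'   ground-truth value.
#' @param texture_amplitude Amplitude of the shared smooth intensity
#'   modulation (fraction of the local value); 0 disables it.
#' @param liver_semiaxes Ellipsoid semi-axes (mm) of the schematic liver.
#' @param vessel_radius Radius (mm) of the two vessel tubes.
#' @param reader_sigma Per-sequence synthetic "manual reader" noise (ms).
#' @param speckle_fraction Fraction of parenchymal map voxels replaced by
#'   the top of the intensity range (outlier artifact).
#' @param noisy_segments Segments whose map voxels are replaced by
#'   full-range uniform noise (high-entropy artifact).
#' @return List of class `mq_phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         source_dim = c(160L, 160L, 80L),
                         source_pixel = 1.19,
                         source_slice = 3,
                         map_dim = c(112L, 112L, 4L),
                         map_pixel = 1.88,
                         map_spacing = 32,
                         map_thickness = 8,
                         map_z0 = 70,
                         sequences = c("t1_pre", "t1_post", "t2"),
                         noise_sigma = 0.02,
                         texture_amplitude = 0.05,
                         liver_semiaxes = c(70, 55, 90),
                         vessel_radius = 5,
                         reader_sigma = c(t1_pre = 5, t1_post = 5, t2 = 1),
                         speckle_fraction = 0,
                         noisy_segments = character(0)) {
  stopifnot(source_pixel > 0, source_slice > 0, map_pixel > 0,
            map_spacing > 0, all(liver_semiaxes > 0),
            noise_sigma >= 0, texture_amplitude >= 0,
            speckle_fraction >= 0, speckle_fraction < 1,
            all(noisy_segments %in% liver_segments()),
            all(sequences %in% names(.default_truth_params)))
  structure(as.list(environment()), class = "mq_phantom_spec")
}

# Smooth shared modulation field; roughly mean-zero over extended ROIs. The
# z phase rates make the in-plane pattern decorrelate over a few mm of z
# (like real parenchymal texture), so neighboring 3-mm slices are
# distinguishable by cross-correlation.
.texture_field <- function(x, y, z) {
  sin(2 * pi * x / 20 + z / 4) * cos(2 * pi * y / 20 - z / 6)
}

# Analytic anatomy: label code at world points (n x 3 matrix). The liver is
# an ellipsoid split into 8 angular wedges (segment IV further split
# axially into IVa/IVb) with two vessel tubes running cranio-caudally.
.label_at_world <- function(pts, center, semi, vessel_radius) {
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]; dz <- pts[, 3] - center[3]
  inside <- (dx / semi[1])^2 + (dy / semi[2])^2 + (dz / semi[3])^2 <= 1
  lab <- integer(nrow(pts))
  if (!any(inside)) return(lab)
  th <- atan2(dy[inside], dx[inside])          # (-pi, pi]
  sector <- pmin(floor((th + pi) / (2 * pi / 8)), 7)
  seg_code <- integer(length(sector))
  # sectors 0..7 -> I II III IV V VI VII VIII; IV split axially
  base_codes <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)   # IV handled below
  seg_code <- base_codes[sector + 1L]
  is_iv <- sector == 3L
  seg_code[is_iv] <- ifelse(dz[inside][is_iv] >= 0, 4L, 5L)   # IVa above, IVb below
  lab[inside] <- seg_code
  # vessel tubes override parenchyma within the central axial span
  vz <- abs(dz) <= 0.7 * semi[3]
  portal  <- vz & ((dx - 20)^2 + dy^2 <= vessel_radius^2) & inside
  hepatic <- vz & ((dx + 20)^2 + dy^2 <= vessel_radius^2) & inside
  lab[portal] <- 10L
  lab[hepatic] <- 11L
  lab
}

.world_grid <- function(dim3, affine) {
  idx <- cbind(rep(seq_len(dim3[1]) - 1L, times = dim3[2] * dim3[3]),
               rep(rep(seq_len(dim3[2]) - 1L, each = dim3[1]), times = dim3[3]),
               rep(seq_len(dim3[3]) - 1L, each = dim3[1] * dim3[2]))
  w <- affine %*% rbind(t(idx), 1)
  t(w[1:3, , drop = FALSE])
}

# Fast renderer for the phantom's axis-aligned grids: the in-plane geometry
# (angular sectors, vessel tube cross-sections) does not depend on z, so it
# is computed once per volume; per-slice work reduces to outer products.
# Returns list(labels = integer array, texture = numeric array).
.render_grid <- function(dim3, affine, center, semi, vessel_radius,
                         texture_amplitude) {
  stopifnot(all(abs(affine[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))]) < 1e-12))
  xs <- affine[1, 1] * (seq_len(dim3[1]) - 1L) + affine[1, 4]
  ys <- affine[2, 2] * (seq_len(dim3[2]) - 1L) + affine[2, 4]
  zs <- affine[3, 3] * (seq_len(dim3[3]) - 1L) + affine[3, 4]
  dx <- xs - center[1]; dy <- ys - center[2]; dz <- zs - center[3]
  r2_xy <- outer((dx / semi[1])^2, (dy / semi[2])^2, "+")
  th <- atan2(matrix(dy, dim3[1], dim3[2], byrow = TRUE),
              matrix(dx, dim3[1], dim3[2]))
  sector <- pmin(floor((th + pi) / (2 * pi / 8)), 7)
  base_codes <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)
  lab_xy <- matrix(base_codes[sector + 1L], dim3[1], dim3[2])
  is_iv <- sector == 3L
  portal_xy  <- outer((dx - 20)^2, dy^2, "+") <= vessel_radius^2
  hepatic_xy <- outer((dx + 20)^2, dy^2, "+") <= vessel_radius^2
  labels <- array(0L, dim3)
  texture <- array(1, dim3)
  for (k in seq_len(dim3[3])) {
    inside <- r2_xy <= 1 - (dz[k] / semi[3])^2
    lab_k <- matrix(0L, dim3[1], dim3[2])
    lab_k[inside] <- lab_xy[inside]
    lab_k[inside & is_iv] <- if (dz[k] >= 0) 4L else 5L
    if (abs(dz[k]) <= 0.7 * semi[3]) {
      lab_k[inside & portal_xy] <- 10L
      lab_k[inside & hepatic_xy] <- 11L
    }
    labels[, , k] <- lab_k
    if (texture_amplitude > 0) {
      sx <- sin(2 * pi * xs / 20 + zs[k] / 4)
      cy <- cos(2 * pi * ys / 20 - zs[k] / 6)
      texture[, , k] <- 1 + texture_amplitude * outer(sx, cy)
    }
  }
  list(labels = labels, texture = texture)
}

#' Generate a synthetic mpMRI exam
#'
#' Renders the anatomical source volume, its twelve-category label map, and
#' the parametric maps from per-segment ground-truth values drawn around the
#' physiological anchors (noncontrast T1 ~ N(835, 50^2) ms, post-contrast
#' T1 ~ N(518, 30^2) ms, T2 ~ N(37, 4^2) ms; redrawn in the rare event the
#' per-segment ordering T2 < post-contrast T1 < noncontrast T1 is violated).
#' Deterministic under the spec's seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec An [phantom_spec()].
#' @return List of class `mq_phantom_exam`: `source` (`mq_volume`), `labels`
#'   (`mq_label_map`), `maps` (named list of `mq_volume`),
#'   `map_truth_labels` (integer ground-truth labels at map resolution),
#'   `manifest` (data frame segment x sequence ground truth), `manual`
#'   (synthetic reader table: truth + reader noise), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "mq_phantom_spec"))
  with_local_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  sd3 <- spec$source_dim
  src_aff <- diag(c(spec$source_pixel, spec$source_pixel, spec$source_slice, 1))
  center <- c((sd3[1] - 1) / 2 * spec$source_pixel,
              (sd3[2] - 1) / 2 * spec$source_pixel,
              (sd3[3] - 1) / 2 * spec$source_slice)
  md3 <- spec$map_dim
  map_aff <- diag(c(spec$map_pixel, spec$map_pixel, spec$map_spacing, 1))
  map_aff[1, 4] <- center[1] - (md3[1] - 1) / 2 * spec$map_pixel
  map_aff[2, 4] <- center[2] - (md3[2] - 1) / 2 * spec$map_pixel
  map_aff[3, 4] <- spec$map_z0

  segs <- liver_segments()
  # exam-level baselines (redrawn in the rare event the physiological
  # ordering T2 < post-contrast T1 < noncontrast T1 is violated) plus small
  # per-segment offsets
  repeat {
    baseline <- vapply(spec$sequences, function(sq) {
      p <- .default_truth_params[[sq]]
      stats::rnorm(1, p[["mean"]], sqrt(p[["total_sd"]]^2 - p[["segment_sd"]]^2))
    }, numeric(1))
    full <- c(t2 = 37, t1_post = 518, t1_pre = 835)
    full[names(baseline)] <- baseline
    if (full[["t2"]] < full[["t1_post"]] && full[["t1_post"]] < full[["t1_pre"]] &&
        all(baseline > 0)) break
  }
  truth <- list()
  for (seg in segs) {
    truth[[seg]] <- baseline + vapply(spec$sequences, function(sq) {
      stats::rnorm(1, 0, .default_truth_params[[sq]][["segment_sd"]])
    }, numeric(1))
  }

  # ---- source volume + label map -------------------------------------------
  rsrc <- .render_grid(sd3, src_aff, center, spec$liver_semiaxes,
                       spec$vessel_radius, spec$texture_amplitude)
  lab <- rsrc$labels
  src_base <- c(20, 600 + 15 * (1:9), 900, 900)[lab + 1L]   # bg, segments, vessels
  src_vals <- src_base * rsrc$texture
  if (spec$noise_sigma > 0)
    src_vals <- src_vals + stats::rnorm(length(src_vals), 0, spec$noise_sigma * pmax(src_base, 50))
  source_vol <- mq_volume(array(src_vals, dim = sd3), src_aff,
                          sequence_id = "dixon_ip",
                          slice_thickness = spec$source_slice,
                          intensity_range = .default_intensity_ranges$dixon_ip)
  labels <- as_label_map(mq_volume(array(as.numeric(lab), dim = sd3), src_aff,
                                   sequence_id = "labels",
                                   slice_thickness = spec$source_slice))

  # ---- parametric maps ------------------------------------------------------
  rmap <- .render_grid(md3, map_aff, center, spec$liver_semiaxes,
                       spec$vessel_radius, spec$texture_amplitude)
  mlab <- rmap$labels
  mtex <- rmap$texture
  maps <- list()
  for (sq in spec$sequences) {
    base <- numeric(length(mlab))                    # background 0
    for (i in seq_along(segs))
      base[mlab == i] <- truth[[segs[i]]][[sq]]
    base[mlab == 10L | mlab == 11L] <- .vessel_values[[sq]]
    vals <- base * mtex
    if (spec$noise_sigma > 0)
      vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sigma * pmax(base, 1))
    rng <- .default_intensity_ranges[[sq]]
    if (length(spec$noisy_segments)) {
      bad <- mlab %in% liver_label_scheme[spec$noisy_segments]
      vals[bad] <- stats::runif(sum(bad), rng[1], rng[2])
    }
    if (spec$speckle_fraction > 0) {
      parench <- which(mlab >= 1L & mlab <= 9L)
      n_spk <- round(spec$speckle_fraction * length(parench))
      if (n_spk > 0)
        vals[sample(parench, n_spk)] <- rng[2]
    }
    maps[[sq]] <- mq_volume(array(vals, dim = md3), map_aff, sequence_id = sq,
                            slice_thickness = spec$map_thickness,
                            intensity_range = rng)
  }

  # segments absent from every map slice are worth a warning (omission tests)
  present <- unique(mlab[mlab >= 1L & mlab <= 9L])
  absent <- segs[!(liver_label_scheme[segs] %in% present)]
  if (length(absent))
    warning("segments with zero voxels on all map slices: ",
            paste(absent, collapse = ", "), call. = FALSE)

  manifest <- do.call(rbind, lapply(segs, function(seg) {
    data.frame(segment = seg, sequence_id = spec$sequences,
               true_value_ms = unname(truth[[seg]][spec$sequences]),
               stringsAsFactors = FALSE)
  }))
  manual <- manifest
  names(manual)[names(manual) == "true_value_ms"] <- "value_ms"
  manual$value_ms <- manual$value_ms +
    stats::rnorm(nrow(manual), 0, spec$reader_sigma[manual$sequence_id])
  manual <- cbind(exam_id = paste0("phantom_", spec$seed), manual,
                  stringsAsFactors = FALSE)

  structure(list(source = source_vol, labels = labels, maps = maps,
                 map_truth_labels = array(as.integer(mlab), dim = md3),
                 manifest = manifest, manual = manual,
                 exam_id = paste0("phantom_", spec$seed),
                 breathing_shift_mm = 0, spec = spec),
            class = "mq_phantom_exam")
}

#' @export
print.mq_phantom_exam <- function(x, ...) {
  cat(sprintf("<mq_phantom_exam '%s'> source %s, %d map(s): %s\n",
              x$exam_id, paste(dim(x$source$data), collapse = "x"),
              length(x$maps), paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Simulate breathing displacement between acquisitions
#'
#' Translates the source volume's affine (and the label map's, which shares
#' its grid) along world z by `shift_mm`, leaving the parametric maps
#' untouched. The source data stay where they were generated, so the stated
#' world frame no longer agrees with the maps' anatomy — exactly the
#' misalignment that NCC source-slice subselection is designed to recover.
#'
#' @param exam An `mq_phantom_exam`.
#' @param shift_mm Signed world-z translation (mm); must be smaller than the
#'   source stack extent.
#' @return The modified exam, with `breathing_shift_mm` recorded.
#' @export
inject_breathing_shift <- function(exam, shift_mm) {
  stopifnot(inherits(exam, "mq_phantom_exam"))
  extent <- dim(exam$source$data)[3] * exam$source$slice_spacing
  stopifnot(abs(shift_mm) < extent)
  exam$source$affine[3, 4] <- exam$source$affine[3, 4] + shift_mm
  exam$labels$affine[3, 4] <- exam$labels$affine[3, 4] + shift_mm
  exam$breathing_shift_mm <- exam$breathing_shift_mm + shift_mm
  exam
}

#' Write a phantom exam to disk
#'
#' Writes the source volume, label map (with sidecar scheme JSON), the
#' parametric maps as NIfTI, and the ground-truth manifest and synthetic
#' manual table as CSV.
#'
#' @param exam An `mq_phantom_exam`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(exam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(exam$source, file.path(dir, "dixon_ip.nii.gz"))
  write_volume(exam$labels, file.path(dir, "labels.nii.gz"),
               scheme_path = file.path(dir, "labels.json"))
  for (sq in names(exam$maps))
    write_volume(exam$maps[[sq]], file.path(dir, paste0(sq, ".nii.gz")))
  utils::write.csv(exam$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(exam$manual, file.path(dir, "manual.csv"), row.names = FALSE)
  invisible(dir)
}
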