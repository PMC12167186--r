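test_that("erosion matches brute-force morphology and never grows the mask", {
  # 5x5 solid square erodes to its 3x3 interior
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  ref <- matrix(FALSE, 9, 9); ref[4:6, 4:6] <- TRUE
  expect_identical(erode_roi(array(sq, c(9, 9, 1)), "small")[, , 1], ref)

  # 1-voxel-wide line is annihilated
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_false(any(erode_roi(array(line, c(9, 9, 1)), "small")))

  # none leaves the mask untouched; random masks match the 4-neighbor oracle
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(15 * 13) > 0.4, 15, 13)
    expect_identical(erode_roi(array(m, c(15, 13, 1)), "none")[, , 1], m)
    oracle <- matrix(FALSE, 15, 13)
    for (i in 1:15) for (j in 1:13) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < 15) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < 13) m[i, j + 1] else FALSE)
      oracle[i, j] <- all(nb)
    }
    got <- erode_roi(array(m, c(15, 13, 1)), "small")[, , 1]
    expect_identical(got, oracle)
    expect_true(all(got <= m))
    # large = small applied twice
    expect_identical(erode_roi(array(m, c(15, 13, 1)), "large"),
                     erode_roi(erode_roi(array(m, c(15, 13, 1)), "small"), "small"))
  }
})

test_that("minimum-size gate passes exactly at the threshold", {
  expect_false(min_size_gate(49L, 50)$passed)
  out <- min_size_gate(50L, 50)
  expect_true(out$passed)
  expect_identical(out$reason, "ok")
  expect_true(min_size_gate(array(TRUE, c(1, 1, 1)), 1)$passed)
  empty <- min_size_gate(array(FALSE, c(3, 3, 1)), 1)
  expect_false(empty$passed)
  expect_identical(empty$reason, "below_min_size")
})

test_that("MAD outlier removal keeps the band and guards a zero MAD", {
  # constant ROI: MAD 0, everything retained
  expect_identical(remove_outliers(rep(800, 99), 800, 0), rep(800, 99))
  # hand-computed case: values 790..810 plus a 2000 ms spike
  v <- c(790:810, 2000)
  st <- liver_stats(v)
  expect_equal(st$median, 800.5)
  expect_equal(st$mad, 5.5)                       # median |v - 800.5|
  kept <- remove_outliers(v, st$median, st$mad, k = 3)
  expect_identical(kept, 790:810 + 0)             # band 800.5 +/- 16.5
  # removal is invariant under reflection about the median
  refl <- 2 * st$median - v
  kept_refl <- remove_outliers(refl, st$median, st$mad, k = 3)
  expect_setequal(2 * st$median - kept_refl, kept)
})

test_that("spatial entropy matches the direct histogram computation", {
  expect_equal(spatial_entropy(rep(500, 40), 64, c(0, 4095)), 0)
  # values filling all 64 bins equally -> log2(64) = 6 bits
  centers <- (seq_len(64) - 0.5) / 64 * 4095
  expect_equal(spatial_entropy(rep(centers, 5), 64, c(0, 4095)), 6)
  set.seed(21)
  for (bins in c(32, 64)) {
    v <- runif(400, 0, 409.5)
    expect_equal(spatial_entropy(v, bins, c(0, 409.5)),
                 oracle_entropy(v, bins, 0, 409.5), tolerance = 1e-12)
  }
  expect_error(spatial_entropy(numeric(0), 64, c(0, 1)), "empty ROI")
})

test_that("entropy gate fails only noisy ROIs and can be disabled", {
  cfg <- qc_config(entropy = "strict64")
  expect_true(entropy_gate(rep(812, 100), cfg, c(0, 4095))$passed)
  set.seed(3)
  noisy <- runif(500, 0, 4095)
  out <- entropy_gate(noisy, cfg, c(0, 4095))
  expect_false(out$passed)
  expect_identical(out$reason, "high_entropy")
  # an infinite threshold disables the gate
  inf_cfg <- qc_config(entropy = "strict64", entropy_threshold = Inf)
  expect_true(entropy_gate(noisy, inf_cfg, c(0, 4095))$passed)
  off <- qc_config(entropy = "off")
  expect_true(entropy_gate(noisy, off, c(0, 4095))$passed)
})

test_that("the four entropy variants pair 32/64 bins with strict/lenient thresholds", {
  for (v in c("strict64", "lenient64", "strict32", "lenient32")) {
    cfg <- qc_config(entropy = v)
    expect_identical(cfg$entropy_bins,
                     if (grepl("64", v)) 64L else 32L)
  }
  expect_lt(qc_config(entropy = "strict64")$entropy_threshold,
            qc_config(entropy = "lenient64")$entropy_threshold)
  expect_lt(qc_config(entropy = "strict32")$entropy_threshold,
            qc_config(entropy = "lenient32")$entropy_threshold)
})

test_that("NCC subselection stays put without motion and honors the guards", {
  ex <- generate_phantom(phantom_spec(seed = 9))
  map <- ex$maps$t1_pre
  corr <- match_slices(map, ex$source)
  rois <- transfer_labels(ex$labels, map, corr)
  mask <- erode_roi(rois$masks$VIII$mask, "small")
  k <- 1L
  matched <- corr$source_slice[corr$map_slice == k]
  expect_identical(subselect_source_slice(map, ex$source, mask[, , k + 1],
                                          k, matched, 2L), matched)
  # neighborhood 0 always returns the matched slice
  expect_identical(subselect_source_slice(map, ex$source, mask[, , k + 1],
                                          k, matched, 0L), matched)
  # zero-variance ROI on the map slice: NCC undefined, matched returned
  flat <- map
  flat$data[, , k + 1] <- 1
  expect_identical(subselect_source_slice(flat, ex$source, mask[, , k + 1],
                                          k, matched, 2L), matched)
})

test_that("NCC subselection recovers a one-slice breathing shift and matches
           the exhaustive oracle", {
  ex <- inject_breathing_shift(generate_phantom(phantom_spec(seed = 13)), 3)
  map <- ex$maps$t1_pre
  corr <- match_slices(map, ex$source)
  rois <- transfer_labels(ex$labels, map, corr)
  um <- erode_roi(Reduce(`|`, lapply(rois$masks, function(m) m$mask)), "small")
  for (k in 0:3) {
    matched <- corr$source_slice[corr$map_slice == k]
    sel <- subselect_source_slice(map, ex$source, um[, , k + 1], k, matched, 2L)
    expect_identical(sel, matched + 1L)
    # exhaustive NCC oracle over the window agrees
    ij <- which(um[, , k + 1], arr.ind = TRUE) - 1L
    mv <- map$data[, , k + 1][um[, , k + 1]]
    w <- map$affine %*% rbind(t(ij), k, 1)
    sv <- solve(ex$source$affine) %*% w
    cand <- max(0, matched - 2):min(79, matched + 2)
    nccs <- vapply(cand, function(s)
      oracle_ncc(mv, oracle_bilinear(ex$source$data[, , s + 1], sv[1, ], sv[2, ])),
      numeric(1))
    expect_identical(sel, cand[which.max(nccs)])
  }
})

test_that("NCC selection is invariant to affine intensity rescaling", {
  ex <- inject_breathing_shift(generate_phantom(phantom_spec(seed = 17)), 3)
  map <- ex$maps$t1_pre
  corr <- match_slices(map, ex$source)
  rois <- transfer_labels(ex$labels, map, corr)
  um <- erode_roi(Reduce(`|`, lapply(rois$masks, function(m) m$mask)), "small")
  scaled_src <- ex$source; scaled_src$data <- ex$source$data * 10 + 100
  scaled_map <- map; scaled_map$data <- map$data * 3 + 40
  for (k in c(0L, 2L)) {
    matched <- corr$source_slice[corr$map_slice == k]
    base <- subselect_source_slice(map, ex$source, um[, , k + 1], k, matched, 2L)
    expect_identical(subselect_source_slice(map, scaled_src, um[, , k + 1],
                                            k, matched, 2L), base)
    expect_identical(subselect_source_slice(scaled_map, ex$source, um[, , k + 1],
                                            k, matched, 2L), base)
  }
})

test_that("QC configuration round-trips through YAML and validates inputs", {
  cfg <- qc_config(erosion = "small", min_roi_size = 75, outlier = "off",
                   entropy = "lenient32", subselection = TRUE, neighborhood = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(erosion = "small", min_roi_size = 75, outlier = "off",
                        entropy = "lenient32", subselection = TRUE,
                        neighborhood = 3), path)
  cfg2 <- read_qc_config(path)
  expect_equal(cfg[order(names(cfg))], cfg2[order(names(cfg2))],
               ignore_attr = TRUE)
  expect_error(qc_config(min_roi_size = 0))
  expect_error(qc_config(erosion = "huge"))
})
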