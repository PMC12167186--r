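test_that("ICC(1,1) matches a from-scratch one-way ANOVA oracle", {
  set.seed(31)
  truth <- rnorm(30, 800, 60)
  x <- truth + rnorm(30, 0, 15)
  y <- truth + rnorm(30, 0, 15)
  r <- icc_1_1(x, y)
  expect_equal(r$icc, oracle_icc_aov(x, y), tolerance = 1e-10)
  expect_true(r$ci95[1] <= r$icc && r$icc <= r$ci95[2])
  expect_identical(r$n_pairs, 30L)
})

test_that("ICC is 1 for identical columns and ~0 for independent noise", {
  v <- c(700, 820, 910, 760, 840)
  perfect <- icc_1_1(v, v)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$p_value, 0)

  set.seed(77)
  big <- icc_1_1(rnorm(10000), rnorm(10000))
  expect_lt(abs(big$icc), 0.03)

  expect_error(icc_1_1(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(zero <- icc_1_1(rep(5, 6), rep(5, 6)), "zero variance")
  expect_equal(zero$icc, 0)
})

test_that("ICC is invariant under a common change of units", {
  set.seed(41)
  t <- rnorm(40, 500, 40)
  x <- t + rnorm(40, 0, 10); y <- t + rnorm(40, 0, 10)
  expect_equal(icc_1_1(x, y)$icc, icc_1_1(x / 1000, y / 1000)$icc,
               tolerance = 1e-12)
})

test_that("Deming regression is exact on y = x and symmetric under swap", {
  x <- c(400, 500, 650, 700, 820, 900)
  f <- deming_fit(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  set.seed(51)
  y <- 0.9 * x + 30 + rnorm(6, 0, 5)
  a <- deming_fit(x, y); b <- deming_fit(y, x)
  expect_equal(a$slope * b$slope, 1, tolerance = 1e-12)

  # unit change: slope unchanged, intercept scales
  g <- deming_fit(x / 1000, y / 1000)
  expect_equal(g$slope, a$slope, tolerance = 1e-12)
  expect_equal(g$intercept, a$intercept / 1000, tolerance = 1e-12)

  expect_error(deming_fit(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("Deming recovers a unit slope from doubly noisy data", {
  slopes <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    t <- rnorm(500, 800, 80)
    deming_fit(t + rnorm(500, 0, 10), t + rnorm(500, 0, 10))$slope
  }, numeric(1))
  expect_true(all(slopes > 0.97 & slopes < 1.03))
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  set.seed(61)
  x <- rnorm(50); y <- x^3 + rnorm(50, 0, 0.2)
  r <- spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r$rho, oracle, tolerance = 1e-12)
  # monotone transforms: rho exactly +/- 1
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  expect_warning(flat <- spearman_rho(rep(1, 10), rnorm(10)), "constant column")
  expect_true(is.na(flat$rho))
})

test_that("median comparison detects a constant shift and degenerate equality", {
  set.seed(71)
  manual <- rnorm(50, 830, 40)
  shifted <- compare_medians(manual, manual + 5, B = 500, seed = 3)
  expect_equal(shifted$median_of_differences, 5)
  expect_lt(shifted$wilcoxon_p, 0.001)

  same <- compare_medians(manual, manual, B = 200, seed = 3)
  expect_equal(same$median_of_differences, 0)
  expect_equal(same$wilcoxon_p, 1)
  expect_true(same$degenerate)
})

test_that("bootstrap CIs reproduce a same-seed independently coded oracle", {
  set.seed(81)
  manual <- rnorm(40, 500, 30)
  auto <- manual + rnorm(40, 2, 6)
  B <- 1000L; seed <- 9L
  got <- compare_medians(manual, auto, B = B, seed = seed)
  # oracle: same resampling algorithm (pairs for arms, differences for the
  # difference), same seed, coded independently
  d <- auto - manual; n <- 40L
  set.seed(seed)
  bm <- ba <- bd <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    bm[b] <- median(manual[i]); ba[b] <- median(auto[i])
    j <- sample.int(n, n, replace = TRUE)
    bd[b] <- median(d[j])
  }
  # agreement to within one ulp of the quantile interpolation
  expect_equal(got$ci_manual, unname(quantile(bm, c(0.025, 0.975))),
               tolerance = 1e-12)
  expect_equal(got$ci_auto, unname(quantile(ba, c(0.025, 0.975))),
               tolerance = 1e-12)
  expect_equal(got$ci_difference, unname(quantile(bd, c(0.025, 0.975))),
               tolerance = 1e-12)
})

test_that("agreement categorization counts the four categories and reasons", {
  tab <- data.frame(
    manual_value = c(rep(800, 7), NA, 820, 810),
    auto_value = c(rep(805, 7), NA, NA, NA),
    auto_omission_reason = c(rep(NA, 8), "below_min_size", "high_entropy")
  )
  got <- categorize_agreement(tab)
  expect_identical(got$positive_agreement, 7L)
  expect_identical(got$negative_agreement, 1L)
  expect_identical(got$human_only, 2L)
  expect_identical(got$algorithm_only, 0L)
  expect_identical(unname(got$human_only_reasons[["below_min_size"]]), 1L)
  expect_identical(unname(got$human_only_reasons[["high_entropy"]]), 1L)

  empty <- categorize_agreement(tab[0, ])
  expect_identical(empty$n, 0L)
  expect_identical(empty$positive_agreement + empty$negative_agreement +
                     empty$human_only + empty$algorithm_only, 0L)
})

test_that("agreement categories partition every random table", {
  set.seed(91)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    tab <- data.frame(
      manual_value = ifelse(runif(n) < 0.8, rnorm(n, 800, 50), NA),
      auto_value = ifelse(runif(n) < 0.8, rnorm(n, 800, 50), NA),
      auto_omission_reason = sample(c("below_min_size", "high_entropy", NA),
                                    n, replace = TRUE)
    )
    got <- categorize_agreement(tab)
    expect_identical(got$positive_agreement + got$negative_agreement +
                       got$human_only + got$algorithm_only, n)
    expect_identical(sum(got$human_only_reasons), got$human_only)
  }
})

test_that("agreement tables join automated results with manual references", {
  auto <- data.frame(exam_id = "e1", sequence_id = "t2",
                     segment = c("I", "II", "III"),
                     mean_ms = c(37.5, NA, 36.1),
                     reason = c("ok", "high_entropy", "ok"))
  manual <- data.frame(exam_id = "e1", sequence_id = "t2",
                       segment = c("I", "II", "IVa"),
                       value_ms = c(37, 38, 36))
  tab <- agreement_table(auto, manual)
  expect_identical(nrow(tab), 4L)
  ii <- tab[tab$segment == "II", ]
  expect_true(is.na(ii$auto_value))
  expect_identical(ii$auto_omission_reason, "high_entropy")
  iva <- tab[tab$segment == "IVa", ]
  expect_true(is.na(iva$auto_value) && !is.na(iva$manual_value))
})
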