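test_that("normality gate: calibration, power, and degenerate input", {
  # null calibration on normal draws
  set.seed(5)
  pass <- vapply(seq_len(200), function(i)
    test_normality(rnorm(100))$is_normal, TRUE)
  expect_gte(mean(pass), 0.9)
  # power on a strongly bimodal sample
  bim <- c(rnorm(25, -5, 0.1), rnorm(25, 5, 0.1))
  expect_false(test_normality(bim)$is_normal)
  # contract violations
  expect_error(test_normality(c(1, 2)), "at least 3")
  expect_warning(res <- test_normality(rep(3, 10)), "Constant")
  expect_equal(res$p_value, 0)
  expect_false(res$is_normal)
})

test_that("compare_groups picks the right test and detects forced separation", {
  set.seed(6)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 5, 1)
  res <- compare_groups(a, b)
  expect_equal(res$test, "student_t")
  expect_true(res$significant)
  # identical samples: never significant
  expect_false(compare_groups(a, a)$significant)
  # heavily skewed data routes to Mann-Whitney
  sk <- rexp(40)^3
  res2 <- compare_groups(sk, sk * 1.0)
  expect_equal(res2$test, "mann_whitney_u")
  expect_error(compare_groups(1:2, 1:10), "at least 3")
})

test_that("type-I error is calibrated and the gate switches under a skewed null", {
  set.seed(7)
  n_rep <- 600
  rej_norm <- 0L
  for (i in seq_len(n_rep))
    rej_norm <- rej_norm + compare_groups(rnorm(30), rnorm(30))$significant
  expect_lt(abs(rej_norm / n_rep - 0.05), 0.02)

  rej_skew <- 0L; mw <- 0L
  for (i in seq_len(n_rep)) {
    r <- compare_groups(rexp(30)^2, rexp(30)^2)
    rej_skew <- rej_skew + r$significant
    mw <- mw + (r$test == "mann_whitney_u")
  }
  expect_lt(abs(rej_skew / n_rep - 0.05), 0.02)
  expect_gt(mw / n_rep, 0.8)
})

test_that("noiseless quadratic data give exact modal coefficients and zero RSS", {
  d <- tidyr::expand_grid(timepoint_h = c(0, 1, 2, 3), rep = 1:6) |>
    dplyr::mutate(R13 = timepoint_h^2)
  f <- bootstrap_polyfit(d, n_reps = 200, seed = 2)
  expect_equal(unname(f$coefficients), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(f$rss, 1e-18)
  # constant data: (0, 0, 7)
  d2 <- dplyr::mutate(d, R13 = 7)
  f2 <- bootstrap_polyfit(d2, n_reps = 50, seed = 3)
  expect_equal(unname(f2$coefficients), c(0, 0, 7), tolerance = 1e-9)
  expect_lt(f2$rss, 1e-18)
})

test_that("fraction 1 with one rep reduces to a single least-squares fit of medians", {
  set.seed(11)
  d <- tidyr::expand_grid(timepoint_h = c(0, 2, 5, 9), rep = 1:7) |>
    dplyr::mutate(R13 = 0.3 * timepoint_h^2 - 1.1 * timepoint_h + rnorm(28))
  f <- bootstrap_polyfit(d, subsample_fraction = 1, n_reps = 1, seed = 4)
  med <- tapply(d$R13, d$timepoint_h, median)
  t <- as.numeric(names(med))
  ls <- stats::lm(med ~ I(t^2) + t)
  expect_equal(unname(f$coefficients),
               unname(stats::coef(ls)[c(2, 3, 1)]), tolerance = 1e-9)
})

test_that("bootstrap results are seed-deterministic and histograms sum to n_reps", {
  set.seed(12)
  d <- tidyr::expand_grid(timepoint_h = sip_timepoints(), rep = 1:12) |>
    dplyr::mutate(R13 = 0.01 + 0.001 * timepoint_h + rnorm(dplyr::n(), 0, 0.002))
  f1 <- bootstrap_polyfit(d, n_reps = 400, seed = 99)
  f2 <- bootstrap_polyfit(d, n_reps = 400, seed = 99)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$histograms, f2$histograms)
  for (h in f1$histograms) expect_equal(sum(h$count), 400)
  expect_gte(f1$rss, 0)
})

test_that("the modal c2 recovers a known quadratic median trajectory", {
  co <- c(5e-4, 2e-3, 0.0112)
  hits <- 0L
  modal_err <- numeric(8)
  for (s in 1:8) {
    set.seed(500 + s)
    d <- purrr::map_dfr(sip_timepoints(), function(t) {
      center <- co[1] * t^2 + co[2] * t + co[3]
      tibble::tibble(timepoint_h = t,
                     R13 = rnorm(40, center, 0.1 * center))
    })
    # classical with-replacement reps: histogram width is a valid
    # dispersion estimate, so "modal within the 95% band around truth"
    # is a meaningful coverage check
    f <- bootstrap_polyfit(d, n_reps = 2000, seed = s, keep_reps = TRUE,
                           replace = TRUE)
    qs <- quantile(f$reps["c2", ], c(0.025, 0.975))
    hits <- hits + (abs(f$coefficients["c2"] - co[1]) <= diff(qs) / 2)
    # default subset variant: the modal estimate itself stays close
    fd <- bootstrap_polyfit(d, n_reps = 2000, seed = s)
    modal_err[s] <- abs(fd$coefficients["c2"] - co[1]) / co[1]
  }
  expect_gte(hits, 7)
  expect_lt(mean(modal_err), 0.15)
})

test_that("with-replacement resampling is available and deterministic", {
  set.seed(13)
  d <- tidyr::expand_grid(timepoint_h = c(0, 1, 3, 6), rep = 1:10) |>
    dplyr::mutate(R13 = rnorm(40, 1, 0.1))
  f <- bootstrap_polyfit(d, replace = TRUE, n_reps = 200, seed = 1)
  f2 <- bootstrap_polyfit(d, replace = TRUE, n_reps = 200, seed = 1)
  expect_identical(f$coefficients, f2$coefficients)
})

test_that("too few time points are rejected", {
  d <- tibble::tibble(timepoint_h = rep(c(0, 1), each = 4), R13 = rnorm(8))
  expect_error(bootstrap_polyfit(d), "time points")
})

test_that("heterogeneity profile tracks a linearly growing spread", {
  set.seed(14)
  d <- purrr::map_dfr(sip_timepoints(), function(t)
    tibble::tibble(timepoint_h = t, R13 = rnorm(100, 0.05, 0.001 + 5e-4 * t)))
  prof <- heterogeneity_profile(d)
  expect_equal(nrow(prof), 8)
  tr <- heterogeneity_trend(prof)
  expect_gt(tr$spearman_rho, 0.9)
})

test_that("IQR scales with the group SD (normal theory)", {
  set.seed(15)
  d <- dplyr::bind_rows(
    tibble::tibble(timepoint_h = 0, R13 = rnorm(1e4, 0, 1)),
    tibble::tibble(timepoint_h = 1, R13 = rnorm(1e4, 0, 2)))
  prof <- heterogeneity_profile(d)
  expect_equal(prof$iqr[2] / prof$iqr[1], 2, tolerance = 0.05)
})

test_that("degenerate heterogeneity input reports a flagged zero trend", {
  d <- tidyr::expand_grid(timepoint_h = c(0, 1, 2), rep = 1:5) |>
    dplyr::mutate(R13 = 4)
  prof <- heterogeneity_profile(d)
  expect_true(all(prof$iqr == 0))
  tr <- heterogeneity_trend(prof)
  expect_equal(tr$spearman_rho, 0)
  expect_match(tr$flag, "undefined")
  # undersized groups are flagged, not dropped
  d2 <- dplyr::bind_rows(d, tibble::tibble(timepoint_h = 3, rep = 1, R13 = 9))
  prof2 <- heterogeneity_profile(d2)
  expect_equal(nrow(prof2), 4)
  expect_equal(prof2$flag[prof2$timepoint_h == 3], "undersized")
})

test_that("pairwise time-point comparison covers every pair and supports Holm", {
  set.seed(16)
  d <- tidyr::expand_grid(timepoint_h = c(0, 1, 2.5, 8), rep = 1:10) |>
    dplyr::mutate(R13 = rnorm(40, 0.01 + 0.001 * timepoint_h, 0.002))
  out <- compare_timepoints(d, holm = TRUE)
  expect_equal(nrow(out), choose(4, 2))
  expect_true(all(out$p_holm >= out$p_value - 1e-12))
})
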