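test_that("the smoother reproduces the hand-derived closed form", {
  y_hat <- gaussian_kernel_smooth(1:3, c(0, 1, 0), bandwidth = 1)
  expect_equal(y_hat[2], 1 / (1 + 2 * exp(-0.5)), tolerance = 1e-12)
  expect_equal(y_hat[2], 0.45186, tolerance = 1e-4)
  expect_equal(y_hat, nw_oracle(1:3, c(0, 1, 0), 1), tolerance = 1e-14)
})

test_that("smoothing a constant returns the constant; huge bandwidth returns the mean", {
  expect_equal(gaussian_kernel_smooth(1:9, rep(3.7, 9), 0.8), rep(3.7, 9))
  set.seed(5)
  y <- rnorm(9)
  expect_equal(gaussian_kernel_smooth(1:9, y, 1e6), rep(mean(y), 9),
               tolerance = 1e-6)
})

test_that("production smoother matches the direct double-loop evaluation", {
  set.seed(101)
  for (b in c(0.5, 1, 2)) {
    for (rep in 1:50) {
      y <- rlnorm(9, 0, 0.5)
      expect_equal(gaussian_kernel_smooth(1:9, y, b), nw_oracle(1:9, y, b),
                   tolerance = 1e-12)
    }
  }
  # and on irregular (outlier-excluded) positions
  x <- c(1, 2, 3, 4, 6, 7, 8, 9)
  y <- rlnorm(8)
  expect_equal(gaussian_kernel_smooth(x, y, 1), nw_oracle(x, y, 1),
               tolerance = 1e-12)
})

test_that("smoother is affine-equivariant, shift-invariant in x, and convex", {
  set.seed(7)
  y <- rnorm(9); x <- 1:9
  base <- gaussian_kernel_smooth(x, y, 1)
  expect_equal(gaussian_kernel_smooth(x, 2.5 * y - 3, 1), 2.5 * base - 3)
  expect_equal(gaussian_kernel_smooth(x + 17, y, 1), base)
  expect_true(all(base >= min(y) & base <= max(y)))
  # b -> 0+ limit: fit approaches the data pointwise
  expect_equal(gaussian_kernel_smooth(x, y, 1e-3), y, tolerance = 1e-6)
})

test_that("smoother rejects invalid input", {
  expect_error(gaussian_kernel_smooth(1:9, rnorm(9), 0), "parameter error")
  expect_error(gaussian_kernel_smooth(1:9, c(rnorm(8), NA), 1), "input error")
  expect_error(gaussian_kernel_smooth(c(1, 2, 2), rnorm(3), 1), "input error")
  expect_error(gaussian_kernel_smooth(1:2, rnorm(2), 1), "input error")
})

test_that("average slope is the mean adjacent tangent and telescopes when equispaced", {
  expect_equal(average_slope(c(1, 2, 3), 1:3), 1.0)
  expect_equal(average_slope(c(1.0, 1.2, 1.1), 1:3), 0.05)
  set.seed(13)
  for (i in 1:25) {
    y <- rnorm(9)
    expect_equal(average_slope(y, 1:9), (y[9] - y[1]) / 8, tolerance = 1e-12)
  }
  # unequal spacing: plain mean of pairwise tangents
  x <- c(1, 2, 4)
  y <- c(0, 1, 0)
  expect_equal(average_slope(y, x), mean(c(1, -0.5)))
  expect_error(average_slope(1), "degenerate")
})

test_that("run statistics count longest strict monotone streaks; ties break runs", {
  expect_equal(run_statistics(c(1, 1.2, 1.4, 1.5, 1.45, 1.3, 1.15, 1.05, 1.0)),
               c(max_up_run = 3L, max_down_run = 5L))
  expect_equal(run_statistics(seq(1, 2, length.out = 9)),
               c(max_up_run = 8L, max_down_run = 0L))
  expect_equal(run_statistics(rep(1, 9)), c(max_up_run = 0L, max_down_run = 0L))
  set.seed(23)
  for (i in 1:50) {
    y <- sample(c(rnorm(7), 0, 0))    # may contain tied neighbours
    r <- run_statistics(y)
    o <- runs_oracle(y)
    expect_equal(unname(r), unname(o))
    expect_lte(r[["max_up_run"]] + r[["max_down_run"]], length(y) - 1L)
  }
})

test_that("fit_dose_curve populates all statistics consistently", {
  tr <- dose_trace(rep(500, 9), fixture_design())
  fit <- fit_dose_curve(normalize_first_dose(tr), small_config())
  expect_s3_class(fit, "dose_curve")
  expect_equal(fit$average_slope, 0)
  expect_equal(fit$range_fitted, 0)
  expect_equal(fit$max_up_run, 0L)
  expect_equal(fit$max_down_run, 0L)

  spike <- fit_dose_curve(c(0, 1, 0) + 1, bandwidth = 1)
  oh <- nw_oracle(1:3, c(1, 2, 1), 1)
  expect_equal(fitted(spike), oh, tolerance = 1e-12)
  expect_equal(spike$range_fitted, max(oh) - min(oh))
  expect_equal(spike$end_diff, abs(oh[3] - oh[1]))
  expect_error(fit_dose_curve(dose_trace(1:9, fixture_design())),
               "normalized")
})

test_that("excluded positions propagate into the fit with original labels", {
  cfg <- small_config(excluded_positions = 5L)
  y <- c(100, 110, 130, 160, 999999, 240, 270, 285, 290)
  tr <- normalize_first_dose(dose_trace(y, fixture_design()))
  fit <- fit_dose_curve(tr, cfg)
  expect_equal(fit$x, c(1:4, 6:9))
  keep <- c(1:4, 6:9)
  expect_equal(fitted(fit), nw_oracle(keep, y[keep] / y[1], 1),
               tolerance = 1e-12)
})

test_that("dose_curve methods behave like a standard model object", {
  set.seed(3)
  tr <- normalize_first_dose(dose_trace(rlnorm(9, 6, 0.3), fixture_design()))
  fit <- fit_dose_curve(tr, bandwidth = 1)
  expect_named(coef(fit), "average_slope")
  expect_equal(residuals(fit), fit$y - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, fit$x), fitted(fit), tolerance = 1e-12)
  s <- summary(fit, small_config())
  expect_s3_class(s, "summary.dose_curve")
  expect_true(s$category %in% response_categories())
  expect_output(print(fit), "average slope")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("the vectorized matrix path agrees with per-trace fitting", {
  set.seed(31)
  y <- matrix(rlnorm(20 * 9, 0, 0.4), nrow = 20)
  y <- y / y[, 1]
  x <- 1:9
  fm <- doseimpact:::smooth_matrix(y, x, 1)
  st <- doseimpact:::curve_stats_matrix(fm, x)
  for (i in seq_len(nrow(y))) {
    fit <- fit_dose_curve(y[i, ], bandwidth = 1)
    expect_equal(fm[i, ], fitted(fit), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(st$average_slope[i], fit$average_slope, tolerance = 1e-12)
    expect_equal(st$max_up_run[i], fit$max_up_run)
    expect_equal(st$max_down_run[i], fit$max_down_run)
    expect_equal(st$end_diff[i], fit$end_diff, tolerance = 1e-12)
  }
})
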