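# Wrap a pre-smoothed fitted vector into a dose_curve for classification:
# classification consumes fitted-curve statistics, so tests can feed the
# fitted values directly through a near-zero bandwidth (fit ~ data).
as_curve <- function(y_hat) fit_dose_curve(y_hat, bandwidth = 1e-4)

default_cfg <- run_config()   # T = 0.3, C = 5, B = 3, E = 0.45

test_that("the four worked fixtures classify as NR / hyper / hypo / biphasic", {
  nr <- c(1.0, 1.1, 1.05, 1.15, 1.1, 1.2, 1.15, 1.1, 1.05)
  hyper <- c(1.00, 1.05, 1.12, 1.20, 1.28, 1.33, 1.37, 1.40, 1.42)
  hypo <- rev(hyper)
  biph <- c(1.00, 1.20, 1.40, 1.50, 1.45, 1.30, 1.15, 1.05, 1.00)
  fixtures <- list(nr = nr, hyper = hyper, hypo = hypo, biph = biph)
  expected <- c(nr = "NR", hyper = "hyper", hypo = "hypo", biph = "biphasic")
  for (nm in names(fixtures)) {
    expect_equal(classify_curve(as_curve(fixtures[[nm]]), default_cfg),
                 unname(expected[nm]), label = nm)
    expect_equal(rule_checker(fixtures[[nm]]), unname(expected[nm]),
                 label = paste("oracle", nm))
  }
})

test_that("classification agrees with the independent rule checker on random curves", {
  set.seed(47)
  for (i in 1:300) {
    y_hat <- gaussian_kernel_smooth(1:9, rlnorm(9, 0, 0.35), 1)
    expect_equal(classify_curve(as_curve(y_hat), default_cfg),
                 rule_checker(y_hat))
  }
})

test_that("every curve receives exactly one category (totality)", {
  set.seed(53)
  cats <- vapply(1:500, function(i) {
    classify_curve(as_curve(cumsum(rnorm(9, 0, 0.2)) + 1), default_cfg)
  }, "")
  expect_true(all(cats %in% response_categories()))
  expect_equal(sum(table(cats)), 500L)
})

test_that("negating a curve swaps hyper and hypo when B == C", {
  cfg <- run_config(up_run_B = 4L, down_run_C = 4L)
  swap <- c(hyper = "hypo", hypo = "hyper", biphasic = "biphasic", NR = "NR")
  set.seed(59)
  for (i in 1:200) {
    y_hat <- gaussian_kernel_smooth(1:9, rlnorm(9, 0, 0.35), 1)
    mirrored <- 2 * y_hat[1] - y_hat
    expect_equal(classify_curve(as_curve(mirrored), cfg),
                 unname(swap[classify_curve(as_curve(y_hat), cfg)]))
  }
})

test_that("raising T only ever moves curves into NR (monotone gate)", {
  set.seed(61)
  curves <- replicate(150, gaussian_kernel_smooth(1:9, rlnorm(9, 0, 0.3), 1),
                      simplify = FALSE)
  for (T2 in c(0.4, 0.6)) {
    cfg_lo <- run_config(range_T = 0.3)
    cfg_hi <- run_config(range_T = T2)
    for (y_hat in curves) {
      lo <- classify_curve(as_curve(y_hat), cfg_lo)
      hi <- classify_curve(as_curve(y_hat), cfg_hi)
      if (lo == "NR") expect_equal(hi, "NR")
    }
  }
})

test_that("alternative biphasic and end-difference readings are honoured", {
  # up-run 3, down-run 4: biphasic under B-rule, not under C-rule (C = 5)
  y_hat <- c(1.0, 1.2, 1.4, 1.6, 1.5, 1.35, 1.2, 1.02, 1.02)
  expect_equal(classify_curve(as_curve(y_hat), run_config()), "biphasic")
  expect_equal(classify_curve(as_curve(y_hat),
                              run_config(biphasic_down_run = "C")), "hyper")
  # end_rule "threshold" compares end_diff to E*T = 0.135 instead of E*range
  wide <- c(1.0, 1.3, 1.6, 1.9, 1.8, 1.6, 1.45, 1.35, 1.3)  # end_diff 0.3
  expect_equal(classify_curve(as_curve(wide), run_config()), "biphasic")
  expect_equal(classify_curve(as_curve(wide),
                              run_config(end_rule = "threshold")), "hyper")
})

test_that("replicate reconciliation enforces concordance and averages slopes", {
  call1 <- list(entity_id = "P1_S10", category = "hyper", average_slope = 0.10)
  call2 <- list(entity_id = "P1_S10", category = "hyper", average_slope = 0.20)
  out <- reconcile_replicates(call1, call2)
  expect_equal(out$final_category, "hyper")
  expect_equal(out$mean_average_slope, 0.15)
  call2$category <- "hypo"
  expect_equal(reconcile_replicates(call1, call2)$final_category, "NR")
  call1$category <- "biphasic"; call2$category <- "NR"
  disc <- reconcile_replicates(call1, call2)
  expect_equal(disc$final_category, "NR")
  expect_equal(disc$mean_average_slope, 0.15)  # slope averaged regardless
  call2$entity_id <- "P2_S10"
  expect_error(reconcile_replicates(call1, call2), "pairing error")
})

test_that("the upward-interval metric runs on the mean fitted curve", {
  up <- seq(1, 2, length.out = 9)
  expect_equal(upward_interval_metric(up, up + 0.1), 8L)
  expect_equal(upward_interval_metric(rep(1, 9), rep(2, 9)), 0L)
  # one replicate rises 3 then flattens, the other rises 4: mean rises 4
  f1 <- c(1, 1.1, 1.2, 1.3, 1.3, 1.3, 1.3, 1.3, 1.3)
  f2 <- c(1, 1.1, 1.2, 1.3, 1.4, 1.4, 1.4, 1.4, 1.4)
  expect_equal(upward_interval_metric(f1, f2),
               runs_oracle((f1 + f2) / 2)[["up"]])
  expect_equal(upward_interval_metric(f1, f2), 4L)
  expect_error(upward_interval_metric(f1, f2[-1]), "pairing error")
})
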