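test_that("peak detection follows the minimum-separation rule", {
  expect_length(find_peaks(seq(0, 1, length.out = 50), 5), 0) # monotone ramp
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  two_close <- dnorm(t, 0.50, 0.02) + dnorm(t, 0.60, 0.02) # 100 ms apart
  two_far <- dnorm(t, 0.50, 0.02) + dnorm(t, 1.00, 0.02)   # 500 ms apart
  expect_equal(detect_ppgdr_peaks(two_close, fs, 250), 1)
  expect_equal(detect_ppgdr_peaks(two_far, fs, 250), 2)
  expect_error(detect_ppgdr_peaks(numeric(0), fs), "non-empty")
})

test_that("sliding windows compute range/IQR/variance/peaks per center-second", {
  fs <- 25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  pd <- structure(list(values = sin(2 * pi * 0.25 * t), fs = fs,
                       derived_from = "x"), class = "ppgdr_signal")
  wf <- sliding_features(pd)
  expect_s3_class(wf, "window_features")
  expect_equal(nrow(wf), 60)
  expect_named(wf, c("center_s", "range_5", "range_7", "range_11", "range_21",
                     "iqr_11", "iqr_21", "var_11", "var_21",
                     "npeaks_11", "npeaks_21"))
  mid <- wf[wf$center_s > 15 & wf$center_s < 45, ]
  # one full 0.25 Hz cycle fits in 5 s: range = peak-to-trough = 2
  expect_true(all(abs(mid$range_5 - 2) < 0.04))
  # 11 s x 0.25 Hz = 2.75 cycles: 2 or 3 maxima
  expect_true(all(mid$npeaks_11 %in% c(2, 3)))
  # population variance of a full-cycle sinusoid is 1/2
  expect_true(all(abs(mid$var_21 - 0.5) < 0.02))
  # invariant: range >= iqr >= 0
  expect_true(all(wf$range_11 >= wf$iqr_11 - 1e-12))
  expect_true(all(wf$iqr_11 >= 0))

  flat <- structure(list(values = rep(2, 30 * fs), fs = fs,
                         derived_from = "x"), class = "ppgdr_signal")
  wff <- sliding_features(flat)
  expect_true(all(wff$range_21 == 0))
  expect_true(all(wff$var_11 == 0))
  expect_true(all(wff$npeaks_21 == 0))
})

test_that("event aggregation matches naive recomputation on random series", {
  set.seed(42)
  nm <- setdiff(names(sliding_features(structure(
    list(values = rnorm(30 * 25), fs = 25, derived_from = "x"),
    class = "ppgdr_signal"))), "center_s")
  for (rep_i in 1:5) {
    n <- 40
    series <- as.data.frame(matrix(runif(n * 10), n, 10,
                                   dimnames = list(NULL, nm)))
    series$npeaks_11 <- sample(0:4, n, replace = TRUE)
    series$npeaks_21 <- sample(0:4, n, replace = TRUE)
    series <- cbind(center_s = seq(0.5, by = 1, length.out = n), series)
    start <- runif(1, 0, 10)
    end <- start + runif(1, 8, 25)
    agg <- aggregate_event(start, end, series)
    sel <- series$center_s >= start & series$center_s < end
    sub <- series[sel, ]
    expect_equal(agg[["range_7_min"]], min(sub$range_7))
    expect_equal(agg[["range_7_low3"]], mean(sort(sub$range_7)[1:3]))
    expect_equal(agg[["iqr_21_p10"]],
                 unname(quantile(sub$iqr_21, 0.10)))
    expect_equal(agg[["var_11_p25"]],
                 unname(quantile(sub$var_11, 0.25)))
    expect_equal(agg[["npeaks_11_n2"]], sum(sub$npeaks_11 == 2))
    expect_equal(agg[["npeaks_21_p0"]], mean(sub$npeaks_21 == 0))
    # count/proportion consistency and ordering invariants
    expect_equal(agg[["npeaks_11_p1"]],
                 agg[["npeaks_11_n1"]] / nrow(sub))
    expect_lte(agg[["range_11_min"]], agg[["range_11_low3"]])
    expect_lte(agg[["iqr_11_p10"]], agg[["iqr_11_p25"]])
    # permutation invariance
    perm <- series[sample(n), ]
    expect_equal(aggregate_event(start, end, perm)[feature_names()],
                 agg[feature_names()])
  }
})

test_that("aggregation handles constant series and degenerate events", {
  nm <- c("range_5", "range_7", "range_11", "range_21", "iqr_11", "iqr_21",
          "var_11", "var_21")
  series <- as.data.frame(matrix(5, 20, 8, dimnames = list(NULL, nm)))
  series$npeaks_11 <- c(0, 0, 1, 2, 2, rep(1, 15))
  series$npeaks_21 <- 1
  series <- cbind(center_s = seq(0.5, by = 1, length.out = 20), series)
  agg <- aggregate_event(0, 5, series)
  expect_equal(unname(agg[c("range_7_min", "range_7_low3",
                            "range_7_p10", "range_7_p25")]),
               c(5, 5, 5, 5))
  expect_equal(unname(agg[c("npeaks_11_n0", "npeaks_11_p0",
                            "npeaks_11_n2", "npeaks_11_p2",
                            "npeaks_11_min")]),
               c(2, 0.4, 2, 0.4, 0))
  # fewer than 3 windows -> degenerate
  expect_null(aggregate_event(0, 2, series))
  # full masking -> degenerate
  expect_null(aggregate_event(0, 5, series, mask = rep(TRUE, 20)))
  # partial mask restricts aggregation to unmasked rows
  series$range_7 <- c(rep(9, 10), rep(1, 10))
  m <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(aggregate_event(0, 20, series, mask = m)[["range_7_min"]], 1)
  expect_equal(aggregate_event(0, 20, series, mask = !m)[["range_7_min"]], 9)
})

test_that("feature vector layout is frozen at 46 named entries", {
  nm <- feature_names()
  expect_length(nm, 46)
  expect_equal(nm[1], "range_5_min")
  expect_true(all(c("range_7_min", "npeaks_21_p2") %in% nm))
  expect_identical(feature_version(), feature_version())
})

test_that("min range_7 separates central from obstructive on synthetic data", {
  proc <- small_cohort_processed()
  vals <- list(central = numeric(0), obstructive = numeric(0))
  for (p in proc) {
    ok <- !p$events$rejected & !is.na(p$events$label)
    for (lb in c("central", "obstructive")) {
      vals[[lb]] <- c(vals[[lb]],
                      p$features[ok & p$events$label == lb, "range_7_min"])
    }
  }
  expect_gt(length(vals$central), 5)
  expect_gt(length(vals$obstructive), 5)
  mw <- wilcox.test(vals$central, vals$obstructive, alternative = "less")
  expect_lt(mw$p.value, 0.01)
})
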