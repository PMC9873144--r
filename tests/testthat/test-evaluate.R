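test_that("screening metrics match definitions on a worked table", {
  # TP=9 FN=2 FP=1 TN=88 encoded as cAHI values around cutoff 10
  pred <- c(rep(20, 9), rep(0, 2), rep(20, 1), rep(0, 88))
  true <- c(rep(20, 9), rep(20, 2), rep(0, 1), rep(0, 88))
  m <- screening_metrics(pred, true, cutoff = 10, n_boot = 200, seed = 2)
  expect_equal(m$table, c(tp = 9, fn = 2, fp = 1, tn = 88))
  expect_equal(m$sensitivity, 9 / 11)
  expect_equal(m$specificity, 88 / 89)
  expect_equal(m$lr_plus, (9 / 11) / (1 - 88 / 89))
  o <- oracle_metrics(9, 2, 1, 88)
  expect_equal(m$kappa, o$kappa)
  expect_true(m$kappa_ci[1] <= m$kappa && m$kappa <= m$kappa_ci[2])
  # Wilson CI contains the point estimate
  expect_true(m$sensitivity_ci[1] <= m$sensitivity &&
                m$sensitivity <= m$sensitivity_ci[2])
  # perfect prediction
  mp <- screening_metrics(c(1, 20), c(1, 20), 10, n_boot = 0)
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$npv, mp$kappa),
               rep(1, 5))
  w <- capture_warnings(m0 <- screening_metrics(c(1, 2), c(1, 2), 10,
                                                n_boot = 0))
  expect_true(any(grepl("sensitivity undefined", w)))
  expect_true(is.na(m0$sensitivity))
  expect_equal(m0$specificity, 1)
})

test_that("metrics agree with the brute-force oracle on all small tables", {
  for (tp in 0:5) for (fn in 0:5) for (fp in 0:5) for (tn in 0:5) {
    if (tp + fn + fp + tn == 0) next
    pred <- c(rep(20, tp), rep(0, fn), rep(20, fp), rep(0, tn))
    true <- c(rep(20, tp + fn), rep(0, fp + tn))
    m <- suppressWarnings(
      screening_metrics(pred, true, cutoff = 10, n_boot = 0))
    o <- oracle_metrics(tp, fn, fp, tn)
    for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                 "kappa")) {
      expect_equal(m[[nm]], o[[nm]], info = sprintf(
        "%s at tp=%d fn=%d fp=%d tn=%d", nm, tp, fn, fp, tn))
    }
  }
})

test_that("ROC/PR curves behave at the extremes", {
  mk_patients <- function(n, truth) {
    data.frame(patient_id = sprintf("p%03d", seq_len(n)),
               erp = 0, tst_hours = 1,
               true_cahi = ifelse(truth, 20, 0))
  }
  # perfectly ordered scores: every central-case event scores 0.9
  n <- 40
  truth <- rep(c(TRUE, FALSE), n / 2)
  pats <- mk_patients(n, truth)
  scores <- lapply(seq_len(n), function(i) {
    data.frame(p_central = rep(ifelse(truth[i], 0.9, 0.1), 15))
  })
  names(scores) <- pats$patient_id
  cv <- roc_pr_curves(scores, pats, cutoff = 10)
  expect_equal(cv$roc_auc, 1.0)
  expect_true(all(diff(cv$roc$fpr[order(cv$roc$threshold)]) <= 0))
  # PR endpoint at recall 1 has precision = prevalence
  at_r1 <- cv$pr[!is.na(cv$pr$recall) & cv$pr$recall == 1, ]
  expect_true(any(abs(at_r1$precision - mean(truth)) < 1e-12))

  # random scores on 200 patients: AUC near 1/2
  set.seed(14)
  n <- 200
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  pats <- mk_patients(n, truth)
  scores <- lapply(seq_len(n), function(i)
    data.frame(p_central = runif(30)))
  names(scores) <- pats$patient_id
  cv <- roc_pr_curves(scores, pats, cutoff = 10)
  expect_lt(abs(cv$roc_auc - 0.5), 0.05)
  # monotone score transformation leaves the ROC AUC unchanged
  scores2 <- lapply(scores, function(s)
    data.frame(p_central = s$p_central^3))
  cv2 <- roc_pr_curves(scores2, pats, cutoff = 10)
  expect_equal(cv2$roc_auc, cv$roc_auc)
  # constant scores: degenerate curve
  scores3 <- lapply(scores, function(s)
    data.frame(p_central = rep(0.7, nrow(s))))
  cv3 <- roc_pr_curves(scores3, pats, cutoff = 10)
  expect_true(is.na(cv3$roc_auc))
})

test_that("four-class confusion bins at 5/10/15 and matches kappa oracle", {
  same <- confusion_4class(c(1, 7, 12, 30), c(2, 6, 11, 40))
  expect_equal(same$accuracy, 1)
  expect_equal(same$kappa, 1)
  # shift by +5: accuracy = fraction not crossing a bin edge
  true <- c(1, 2, 6, 7, 11, 12, 20, 30, 40, 3)
  pred <- true + 5
  cf <- confusion_4class(pred, true)
  bin <- function(x) findInterval(x, c(5, 10, 15))
  expect_equal(cf$accuracy, mean(bin(pred) == bin(true)))
  # kappa against direct po/pe computation
  po <- mean(bin(pred) == bin(true))
  tt <- table(factor(bin(true), 0:3), factor(bin(pred), 0:3))
  pe <- sum(rowSums(tt) * colSums(tt)) / sum(tt)^2
  expect_equal(cf$kappa, (po - pe) / (1 - pe))
})

test_that("PPV/NPV sweep finds the operating point and degenerates safely", {
  pred <- c(0, 2, 4, 8, 12, 14, 3, 18, 1, 9)
  m <- ppv_npv_sweep(pred, pred) # perfect predictor
  nd <- !is.na(m$sweep$sum)
  expect_true(all(m$sweep$sum[nd] == 2))
  # piecewise-constant between observed values
  pred2 <- c(1, 6, 11, 16); true2 <- c(2, 7, 12, 17)
  sw <- ppv_npv_sweep(pred2, true2, cutoff_grid = c(3, 4, 4.5))
  expect_true(all(sw$sweep$ppv == sw$sweep$ppv[1]))
  # cutoff above every prediction: PPV undefined (no predicted positives)
  sw2 <- ppv_npv_sweep(c(1, 2), c(1, 30), cutoff_grid = 10)
  expect_true(is.na(sw2$sweep$ppv))
  expect_equal(sw2$sweep$npv, 0.5)
})

test_that("Pearson agreement returns r, the fitted line, and guards", {
  x <- c(1, 4, 7, 9, 12, 15, 2, 8, 11, 5)
  expect_equal(pearson_cahi(x, x)$r, 1)
  expect_equal(pearson_cahi(x, x)$slope, 1)
  expect_equal(pearson_cahi(x, x)$intercept, 0)
  expect_equal(pearson_cahi(2 * x, x)$slope, 2)
  # brute-force covariance formula oracle
  set.seed(3)
  y <- x + rnorm(10)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cahi(y, x)$r, r_oracle)
  expect_warning(out <- pearson_cahi(rep(3, 5), 1:5), "undefined")
  expect_true(is.na(out$r))
})
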