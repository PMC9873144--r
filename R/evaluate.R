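#' Wilson score confidence interval for a proportion
#'
#' @param k Successes; @param n Trials; @param conf Confidence level.
#' @return Numeric c(lower, upper); c(NA, NA) when n = 0.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Cohen's kappa for paired categorical ratings
#'
#' @param a,b Equal-length vectors of categories.
#' @return Unweighted kappa in [-1, 1]; NA when chance agreement is 1.
#' @export
cohen_kappa <- function(a, b) {
  lv <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(a, lv), factor(b, lv))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

boot_ci <- function(stat, n, n_boot, seed, conf = 0.95) {
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) stat(sample.int(n, replace = TRUE)),
                 numeric(1))
  stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  na.rm = TRUE, names = FALSE)
}

#' Screening metrics at one cAHI cutoff
#'
#' Both axes are dichotomized at \code{cahi >= cutoff} (a patient sitting
#' exactly on the cutoff is flagged). Proportion CIs are Wilson score
#' intervals; the kappa CI is a seeded bootstrap.
#'
#' @param pred_cahi,true_cahi Aligned per-patient cAHI vectors.
#' @param cutoff cAHI cutoff in events/hour.
#' @param n_boot Bootstrap replicates for the kappa CI (0 skips the CI).
#' @param seed Bootstrap seed.
#' @return List of metrics; undefined quantities (e.g. sensitivity with zero
#'   true positives + false negatives) are NA with a warning.
#' @export
screening_metrics <- function(pred_cahi, true_cahi, cutoff,
                              n_boot = 2000, seed = 1L) {
  stopifnot(length(pred_cahi) == length(true_cahi))
  pf <- pred_cahi >= cutoff
  tf <- true_cahi >= cutoff
  tp <- sum(pf & tf); fn <- sum(!pf & tf)
  fp <- sum(pf & !tf); tn <- sum(!pf & !tf)
  n <- tp + fn + fp + tn
  rate <- function(k, d, what) {
    if (d == 0) {
      warning(sprintf("%s undefined (empty denominator)", what))
      return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    list(est = k / d, ci = wilson_ci(k, d))
  }
  sens <- rate(tp, tp + fn, "sensitivity")
  spc <- rate(tn, tn + fp, "specificity")
  ppv <- rate(tp, tp + fp, "PPV")
  npv <- rate(tn, tn + fn, "NPV")
  acc <- rate(tp + tn, n, "accuracy")
  lr_plus <- if (!is.na(spc$est) && spc$est < 1 && !is.na(sens$est))
    sens$est / (1 - spc$est) else NA_real_
  lr_minus <- if (!is.na(spc$est) && spc$est > 0 && !is.na(sens$est))
    (1 - sens$est) / spc$est else NA_real_
  kap <- cohen_kappa(pf, tf)
  kci <- if (n_boot > 0)
    boot_ci(function(idx) cohen_kappa(pf[idx], tf[idx]), n, n_boot, seed)
  else c(NA_real_, NA_real_)
  list(cutoff = cutoff,
       table = c(tp = tp, fn = fn, fp = fp, tn = tn),
       sensitivity = sens$est, sensitivity_ci = sens$ci,
       specificity = spc$est, specificity_ci = spc$ci,
       ppv = ppv$est, ppv_ci = ppv$ci,
       npv = npv$est, npv_ci = npv$ci,
       accuracy = acc$est, accuracy_ci = acc$ci,
       lr_plus = lr_plus, lr_minus = lr_minus,
       kappa = kap, kappa_ci = kci)
}

#' Patient-wise ROC and PR curves from event scores
#'
#' For each probability threshold (every distinct event score plus the 0/1
#' endpoints) the per-patient cAHI is recomputed from the events scoring at
#' or above the threshold, patients are flagged at the cAHI cutoff, and one
#' (FPR, TPR) / (recall, precision) point is emitted. AUCs by trapezoid.
#'
#' @param event_scores Named list (per patient) of data.frames with a
#'   \code{p_central} column, as in \code{loocv()$event_scores}.
#' @param patients data.frame with columns \code{patient_id, erp, tst_hours,
#'   true_cahi} covering the same patients.
#' @param cutoff cAHI cutoff defining the patient-level condition.
#' @return List with \code{roc} and \code{pr} data.frames, \code{roc_auc}
#'   and \code{pr_auc} (NA when the curve is degenerate).
#' @export
roc_pr_curves <- function(event_scores, patients, cutoff) {
  ids <- patients$patient_id
  stopifnot(all(ids %in% names(event_scores)))
  truth <- patients$true_cahi >= cutoff
  all_scores <- unlist(lapply(event_scores[ids], `[[`, "p_central"))
  taus <- sort(unique(c(0, all_scores, 1)))
  pts <- lapply(taus, function(tau) {
    flag <- vapply(seq_along(ids), function(i) {
      nc <- sum(event_scores[[ids[i]]]$p_central >= tau)
      cahi <- (nc / patients$tst_hours[i]) / (1 - patients$erp[i])
      cahi >= cutoff
    }, logical(1))
    tp <- sum(flag & truth); fp <- sum(flag & !truth)
    fn <- sum(!flag & truth); tn <- sum(!flag & !truth)
    c(tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      prec = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      rec = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  m <- do.call(rbind, pts)
  roc <- data.frame(threshold = taus, fpr = m[, "fpr"], tpr = m[, "tpr"])
  pr <- data.frame(threshold = taus, recall = m[, "rec"],
                   precision = m[, "prec"])
  trap <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L || diff(range(x)) == 0) return(NA_real_)
    o <- order(x, y)
    sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
  }
  degenerate <- length(unique(all_scores)) < 2L
  list(roc = roc, pr = pr,
       roc_auc = if (degenerate) NA_real_ else trap(roc$fpr, roc$tpr),
       pr_auc = if (degenerate) NA_real_ else trap(pr$recall, pr$precision))
}

CAHI_BINS <- c(0, 5, 10, 15, Inf)
CAHI_BIN_LABELS <- c("<5", "[5,10)", "[10,15)", ">=15")

#' Four-category cAHI confusion matrix
#'
#' Bins both cAHI vectors into \{<5, [5,10), [10,15), >=15\} and reports the
#' 4x4 confusion matrix, multiclass accuracy and unweighted Cohen's kappa.
#'
#' @param pred_cahi,true_cahi Aligned per-patient cAHI vectors.
#' @return List with \code{table} (true in rows), \code{accuracy},
#'   \code{kappa}.
#' @export
confusion_4class <- function(pred_cahi, true_cahi) {
  bin <- function(x) cut(x, CAHI_BINS, labels = CAHI_BIN_LABELS,
                         right = FALSE, include.lowest = TRUE)
  pb <- bin(pred_cahi); tb <- bin(true_cahi)
  tab <- table(true = tb, predicted = pb)
  list(table = tab, accuracy = sum(diag(tab)) / sum(tab),
       kappa = cohen_kappa(tb, pb))
}

#' PPV/NPV sweep over cAHI cutoffs
#'
#' Reports PPV, NPV and their sum at each cutoff of the grid, plus the
#' cutoff maximizing the sum — the screening operating point trading
#' unnecessary referrals (PPV) against missed CSA (NPV).
#'
#' @param pred_cahi,true_cahi Aligned per-patient cAHI vectors.
#' @param cutoff_grid Cutoffs to evaluate (default 0 to 15 by 0.5).
#' @return List with \code{sweep} (data.frame cutoff/ppv/npv/sum) and
#'   \code{best_cutoff} (argmax of ppv + npv; NA-sum cutoffs skipped).
#' @export
ppv_npv_sweep <- function(pred_cahi, true_cahi,
                          cutoff_grid = seq(0, 15, by = 0.5)) {
  rows <- lapply(cutoff_grid, function(ct) {
    pf <- pred_cahi >= ct; tf <- true_cahi >= ct
    tp <- sum(pf & tf); fp <- sum(pf & !tf)
    tn <- sum(!pf & !tf); fn <- sum(!pf & tf)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    data.frame(cutoff = ct, ppv = ppv, npv = npv, sum = ppv + npv)
  })
  sw <- do.call(rbind, rows)
  best <- if (all(is.na(sw$sum))) NA_real_ else
    sw$cutoff[which.max(sw$sum)]
  list(sweep = sw, best_cutoff = best)
}

#' Pearson correlation and least-squares line for cAHI agreement
#'
#' @param pred_cahi,true_cahi Aligned per-patient cAHI vectors (n >= 3,
#'   non-constant).
#' @return List with \code{r}, \code{p_value}, \code{slope},
#'   \code{intercept}; NA with a warning for degenerate input.
#' @export
pearson_cahi <- function(pred_cahi, true_cahi) {
  if (length(pred_cahi) < 3L || stats::sd(pred_cahi) == 0 ||
      stats::sd(true_cahi) == 0) {
    warning("Pearson correlation undefined for constant or tiny input")
    return(list(r = NA_real_, p_value = NA_real_, slope = NA_real_,
                intercept = NA_real_))
  }
  ct <- stats::cor.test(true_cahi, pred_cahi)
  fit <- stats::lm(pred_cahi ~ true_cahi)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Full cohort evaluation of LOOCV predictions
#'
#' @param result A \code{loocv_result} (true cAHI must be present).
#' @param cutoffs cAHI cutoffs for the screening metrics (default 5, 10, 15).
#' @param seed Seed for bootstrap CIs.
#' @return An object of class \code{cohort_evaluation}: per-patient table,
#'   per-cutoff screening metrics and ROC/PR curves, 4-class confusion,
#'   Pearson agreement and the PPV/NPV sweep.
#' @export
evaluate_cohort <- function(result, cutoffs = c(5, 10, 15), seed = 1L) {
  stopifnot(inherits(result, "loocv_result"))
  pred <- result$predictions
  if (any(is.na(pred$true_cahi)))
    stop("true cAHI missing; evaluation needs ground truth")
  metrics <- lapply(cutoffs, function(ct)
    screening_metrics(pred$cahi_extrapolated, pred$true_cahi, ct, seed = seed))
  names(metrics) <- paste0("cutoff_", cutoffs)
  curves <- lapply(cutoffs, function(ct)
    roc_pr_curves(result$event_scores, pred, ct))
  names(curves) <- paste0("cutoff_", cutoffs)
  structure(list(
    patients = pred,
    metrics = metrics,
    curves = curves,
    confusion = confusion_4class(pred$cahi_extrapolated, pred$true_cahi),
    pearson = pearson_cahi(pred$cahi_extrapolated, pred$true_cahi),
    sweep = ppv_npv_sweep(pred$cahi_extrapolated, pred$true_cahi),
    n_rejected_patients = result$n_rejected_patients),
    class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d patients (+%d rejected)\n",
              nrow(x$patients), x$n_rejected_patients))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf(
      "  %s: Se %.2f Sp %.2f PPV %.2f NPV %.2f acc %.3f kappa %.3f\n",
      nm, m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy, m$kappa))
  }
  cat(sprintf("  Pearson r %.3f; 4-class accuracy %.3f, kappa %.3f\n",
              x$pearson$r, x$confusion$accuracy, x$confusion$kappa))
  invisible(x)
}
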