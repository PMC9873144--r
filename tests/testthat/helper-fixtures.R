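# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A 5-event labeling scenario exercising every matching rule: unique overlap,
# preceding-annotation match, unmatchable event, central-dominant double
# overlap, and plain obstructive overlap.
fig5_fixture <- function() {
  pat <- respiratory_events(
    start = c(12, 60, 90, 125, 158),
    end = c(28, 75, 105, 140, 170),
    source = "pat_hsat", type = "unlabeled")
  expert <- respiratory_events(
    start = c(10, 40, 120, 128, 160),
    end = c(25, 52, 135, 142, 172),
    source = "expert",
    type = c("central", "obstructive", "central", "obstructive",
             "obstructive"))
  local <- respiratory_events(
    start = c(11, 41, 121, 127, 159),
    end = c(24, 51, 136, 141, 171),
    source = "local", type = "unlabeled")
  list(pat = pat, expert = expert, local = local)
}

# Small strongly-separated cohort processed once and reused across tests.
small_cohort_processed <- function() {
  memo("small_cohort", {
    cohort <- simulate_cohort(cohort_spec(
      n_patients = 8, csa_prevalence = 0.4, duration_s = 600,
      separation = "strong", rng_seed = 301))
    lapply(cohort, process_patient)
  })
}

# Labeled event features pooled over the small cohort, for classifier tests.
pooled_training <- function() {
  memo("pooled_training", {
    proc <- small_cohort_processed()
    xs <- list(); ys <- character(0)
    for (p in proc) {
      ok <- !p$events$rejected & !p$events$removed & !is.na(p$events$label)
      xs[[length(xs) + 1L]] <- p$features[ok, , drop = FALSE]
      ys <- c(ys, p$events$label[ok])
    }
    list(x = do.call(rbind, xs), y = ys)
  })
}

# Brute-force screening oracle: expands a 2x2 table into paired flag vectors
# and computes every metric from first principles.
oracle_metrics <- function(tp, fn, fp, tn) {
  pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  true <- c(rep(TRUE, tp), rep(TRUE, fn), rep(FALSE, fp), rep(FALSE, tn))
  n <- length(pred)
  po <- mean(pred == true)
  pe <- mean(pred) * mean(true) + mean(!pred) * mean(!true)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = po,
    kappa = if (pe < 1) (po - pe) / (1 - pe) else NA_real_)
}
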