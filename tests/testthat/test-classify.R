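test_that("classifier separates synthetic classes and is seed-deterministic", {
  tr <- pooled_training()
  expect_gt(length(tr$y), 30)
  model <- train_event_classifier(tr$x, tr$y, classifier_spec(rng_seed = 9))
  pred <- predict_events(model, tr$x)
  expect_gt(mean(pred$label == tr$y), 0.95)
  expect_true(all(pred$p_central >= 0 & pred$p_central <= 1))
  model2 <- train_event_classifier(tr$x, tr$y, classifier_spec(rng_seed = 9))
  expect_identical(predict_events(model2, tr$x), pred)
  # single-class training refused
  cidx <- tr$y == "central"
  expect_error(train_event_classifier(tr$x[cidx, ], tr$y[cidx]),
               "both classes")
})

test_that("decision rule is conservative: threshold strict, ties obstructive", {
  tr <- pooled_training()
  model <- train_event_classifier(tr$x, tr$y,
                                  classifier_spec(fp_cost = 1, rng_seed = 3))
  pred <- predict_events(model, tr$x)
  # with fp_cost 1 the threshold is 0.5; a score of exactly 0.5 -> obstructive
  at_half <- pred$p_central == 0.5
  if (any(at_half)) expect_true(all(pred$label[at_half] == "obstructive"))
  expect_true(all((pred$p_central > 0.5) == (pred$label == "central")))
  # all-zero feature vector still yields a valid prediction
  z <- matrix(0, 1, ncol(tr$x), dimnames = list(NULL, colnames(tr$x)))
  pz <- predict_events(model, z)
  expect_true(pz$label %in% c("central", "obstructive"))
  expect_true(pz$p_central >= 0 && pz$p_central <= 1)
  # duplicated rows get identical outputs
  dup <- predict_events(model, tr$x[c(1, 1), , drop = FALSE])
  expect_identical(dup$label[1], dup$label[2])
  expect_identical(dup$p_central[1], dup$p_central[2])
})

test_that("raising the false-positive cost never adds central calls", {
  tr <- pooled_training()
  model <- train_event_classifier(tr$x, tr$y, classifier_spec(rng_seed = 5))
  counts <- vapply(c(1, 2.5, 5, 10), function(cc) {
    sum(predict_events(model, tr$x, fp_cost = cc)$label == "central")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trees respect the split cap and reject stale feature layouts", {
  tr <- pooled_training()
  spec <- classifier_spec(max_splits = 3, rng_seed = 2)
  model <- train_event_classifier(tr$x, tr$y, spec)
  for (fit in model$trees) {
    expect_lte(sum(fit$frame$var != "<leaf>"), 3)
  }
  bad <- tr$x
  colnames(bad) <- rev(colnames(bad))
  expect_error(predict_events(model, bad), "feature columns")
})

test_that("cAHI arithmetic and ERP extrapolation are exact", {
  r <- compute_cahi(12, erp = 0, tst_hours = 6)
  expect_equal(r$cahi_raw, 2)
  expect_equal(r$cahi_extrapolated, 2) # identity at ERP 0
  r <- compute_cahi(12, erp = 0.2, tst_hours = 6)
  expect_equal(r$cahi_extrapolated, 2.5) # 2 / 0.8 exactly
  r <- compute_cahi(0, erp = 0.9, tst_hours = 6)
  expect_equal(r$cahi_extrapolated, 0)
  expect_equal(compute_cahi(c("central", "obstructive", "central"),
                            0, 2)$cahi_raw, 1)
  expect_error(compute_cahi(3, erp = 1, tst_hours = 6), "rejected upstream")
})

test_that("feature importance credits split risk to the right features", {
  set.seed(7)
  n <- 200
  nm <- feature_names()
  x <- matrix(rnorm(n * length(nm), sd = 0.01), n,
              dimnames = list(NULL, nm))
  y <- rep(c("central", "obstructive"), each = n / 2)
  # only range_7_min carries class signal
  x[, "range_7_min"] <- ifelse(y == "central", 0.1, 1) + rnorm(n, sd = 0.05)
  model <- train_event_classifier(x, y, classifier_spec(rng_seed = 4))
  imp <- feature_importance(model)
  expect_equal(imp$feature[1], "range_7_min")
  expect_true(all(imp$importance >= 0))
  unused <- setdiff(nm, unlist(lapply(model$trees, function(tr)
    as.character(tr$frame$var))))
  expect_true(all(imp$importance[imp$feature %in% unused] == 0))
  # importances sum to total risk decrease over branch nodes
  tot_drop <- 0; tot_branch <- 0
  for (tr in model$trees) {
    fr <- tr$frame
    nodes <- as.integer(rownames(fr))
    br <- which(fr$var != "<leaf>")
    tot_branch <- tot_branch + length(br)
    for (i in br) {
      tot_drop <- tot_drop + fr$dev[i] -
        fr$dev[match(nodes[i] * 2L, nodes)] -
        fr$dev[match(nodes[i] * 2L + 1L, nodes)]
    }
  }
  expect_equal(sum(imp$importance), tot_drop / tot_branch)
})

test_that("LOOCV never trains on the held-out patient and recovers cAHI", {
  proc <- small_cohort_processed()
  res <- loocv(proc)
  expect_equal(nrow(res$predictions), length(proc))
  for (pid in names(res$folds)) {
    fold <- res$folds[[pid]]
    expect_length(intersect(fold$held_out_ids, fold$training_ids), 0)
    expect_true(all(grepl(paste0("^", pid, ":"),
                          fold$held_out_ids)))
  }
  # strong separation: predicted cAHI close to truth for most patients
  pr <- res$predictions
  rel_ok <- abs(pr$cahi_extrapolated - pr$true_cahi) <=
    pmax(0.3 * pr$true_cahi, 4.001)
  expect_gte(mean(rel_ok), 0.8)
  expect_error(loocv(proc[1:2]), "at least 3")
})
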