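#' Classifier hyperparameters
#'
#' The event classifier is a bagged ensemble of CART trees: 30 trees, each
#' grown on a bootstrap resample of the training events and pruned to at
#' most 150 internal splits. The false-positive cost (cost of calling an
#' obstructive event central) is applied as a decision-threshold shift: an
#' event is called central only when the central vote fraction exceeds
#' \code{fp_cost / (1 + fp_cost)} (strictly; ties go to obstructive). This
#' keeps the screen conservative against over-calling CSA and makes the
#' predicted-central count exactly non-increasing in \code{fp_cost}.
#'
#' @param n_trees Number of bagged trees (default 30).
#' @param max_splits Maximum internal splits per tree (default 150).
#' @param fp_cost Cost of misclassifying an obstructive event as central
#'   (default 2.5).
#' @param rng_seed Integer seed for the bootstrap resampling.
#' @return An object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(n_trees = 30, max_splits = 150, fp_cost = 2.5,
                            rng_seed = 20230112L) {
  stopifnot(n_trees >= 1, max_splits >= 1, fp_cost > 0)
  structure(list(n_trees = as.integer(n_trees),
                 max_splits = as.integer(max_splits),
                 fp_cost = fp_cost, rng_seed = as.integer(rng_seed)),
            class = "classifier_spec")
}

prune_to_splits <- function(fit, max_splits) {
  cpt <- fit$cptable
  if (max(cpt[, "nsplit"]) <= max_splits) return(fit)
  ok <- cpt[cpt[, "nsplit"] <= max_splits, , drop = FALSE]
  rpart::prune(fit, cp = ok[nrow(ok), "CP"] * 1.000001)
}

#' Train the bagged-trees event classifier
#'
#' @param x Numeric feature matrix, one row per labeled non-rejected event,
#'   columns in \code{\link{feature_names}} order.
#' @param y Labels, values \code{"central"} / \code{"obstructive"}.
#' @param spec A \code{\link{classifier_spec}}.
#' @return An object of class \code{csa_classifier}: bagged rpart trees plus
#'   the spec and the feature-ordering version the model was trained under.
#' @export
train_event_classifier <- function(x, y, spec = classifier_spec()) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("obstructive", "central"))
  if (any(is.na(y))) stop("labels must be central/obstructive, no NA")
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  df <- as.data.frame(x)
  df$.y <- y
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 5, minbucket = 2,
                               maxdepth = 30, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  set.seed(spec$rng_seed)
  trees <- vector("list", spec$n_trees)
  for (b in seq_len(spec$n_trees)) {
    idx <- sample.int(nrow(df), replace = TRUE)
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        method = "class", control = ctrl)
    trees[[b]] <- prune_to_splits(fit, spec$max_splits)
  }
  structure(list(trees = trees, spec = spec,
                 feature_version = feature_version(),
                 feature_names = colnames(x)),
            class = "csa_classifier")
}

#' @export
print.csa_classifier <- function(x, ...) {
  cat(sprintf("<csa_classifier> %d bagged trees, fp_cost %.2f (%s)\n",
              length(x$trees), x$spec$fp_cost, x$feature_version))
  invisible(x)
}

#' Predict event types with a trained classifier
#'
#' The probability score is the fraction of trees voting central; the label
#' is central iff that fraction strictly exceeds the cost-shifted threshold
#' \code{fp_cost/(1+fp_cost)}.
#'
#' @param model A \code{csa_classifier}.
#' @param x Feature matrix in the model's feature ordering.
#' @param fp_cost Optional override of the model's false-positive cost.
#' @return data.frame with columns \code{label} and \code{p_central}.
#' @export
predict_events <- function(model, x, fp_cost = NULL) {
  stopifnot(inherits(model, "csa_classifier"))
  if (model$feature_version != feature_version())
    stop("feature-ordering version mismatch between model and package")
  x <- as.matrix(x)
  if (!identical(colnames(x), model$feature_names))
    stop("feature columns do not match the model's feature ordering")
  if (is.null(fp_cost)) fp_cost <- model$spec$fp_cost
  df <- as.data.frame(x)
  votes <- vapply(model$trees, function(tr) {
    as.character(predict(tr, newdata = df, type = "class")) == "central"
  }, logical(nrow(x)))
  if (nrow(x) == 1L) votes <- matrix(votes, nrow = 1L)
  p <- rowMeans(votes)
  thr <- fp_cost / (1 + fp_cost)
  data.frame(label = ifelse(p > thr, "central", "obstructive"),
             p_central = p, stringsAsFactors = FALSE)
}

#' Central apnea-hypopnea index from event predictions
#'
#' The raw cAHI is the predicted central event count over total sleep time;
#' since predictions are made only on non-rejected events, the raw value is
#' extrapolated by dividing by (1 - ERP) to account for the rejected share.
#'
#' @param n_central Number of events predicted central (or a vector of
#'   predicted labels, in which case centrals are counted).
#' @param erp Event rejection proportion in [0, 1).
#' @param tst_hours Total sleep time in hours (> 0).
#' @return List with \code{cahi_raw} and \code{cahi_extrapolated}.
#' @export
compute_cahi <- function(n_central, erp, tst_hours) {
  if (is.character(n_central)) n_central <- sum(n_central == "central")
  stopifnot(tst_hours > 0, erp >= 0)
  if (erp >= 1)
    stop("ERP of 1 leaves no events; patient must be rejected upstream")
  raw <- n_central / tst_hours
  list(cahi_raw = raw, cahi_extrapolated = raw / (1 - erp))
}

#' Split-risk feature importance of a bagged ensemble
#'
#' For every branch node, the decrease in classification risk achieved by
#' its split is credited to the splitting feature; the per-feature sums are
#' divided by the total number of branch nodes in the ensemble. Features
#' never used in a split have importance 0.
#'
#' @param model A \code{csa_classifier}.
#' @return data.frame with columns \code{feature}, \code{importance}, sorted
#'   decreasing.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "csa_classifier"))
  gains <- stats::setNames(numeric(length(model$feature_names)),
                           model$feature_names)
  n_branch <- 0L
  for (tr in model$trees) {
    fr <- tr$frame
    nodes <- as.integer(rownames(fr))
    branch <- fr$var != "<leaf>"
    n_branch <- n_branch + sum(branch)
    for (i in which(branch)) {
      kid_l <- match(nodes[i] * 2L, nodes)
      kid_r <- match(nodes[i] * 2L + 1L, nodes)
      drop <- fr$dev[i] - (fr$dev[kid_l] + fr$dev[kid_r])
      v <- as.character(fr$var[i])
      gains[v] <- gains[v] + drop
    }
  }
  imp <- gains / max(n_branch, 1L)
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Run the full single-patient processing chain
#'
#' PPGDR extraction, sliding features, vasoconstriction masking, per-event
#' aggregation, beat-interval quality rejection and (when PSG annotations
#' are present) training-label construction.
#'
#' @param record A \code{\link{patient_record}}.
#' @param config A \code{\link{pipeline_config}}.
#' @return List: \code{patient_id}, \code{events} (with labels, rejection
#'   flags), \code{features} (per-event matrix), \code{quality}
#'   (\code{quality_report}), \code{erp}, \code{patient_rejected},
#'   \code{tst_hours}, \code{true_cahi}.
#' @export
process_patient <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "patient_record"))
  ppgdr <- extract_ppgdr(record$recording, config)
  series <- sliding_features(ppgdr, config)
  zones <- detect_vasoconstrictions(record$recording, config)
  mask <- zone_mask(series, zones)
  fm <- event_feature_matrix(record$pat_events, series, mask)
  beats <- detect_beats(record$recording, config)
  irr <- irregular_intervals(beats, config$irr_interval_frac)
  rr <- reject_events(record$pat_events, beats, irr, config$event_irr_frac,
                      extra_rejected = fm$degenerate)
  events <- rr$events
  if (!is.null(record$expert_events) && !is.null(record$local_events)) {
    gt <- consensus_filter(record$expert_events, record$local_events)
    events <- label_pat_events(events, gt, config$match_gap_s)
  } else {
    events$label <- NA_character_
    events$removed <- TRUE
    events$matched_gt <- ""
  }
  quality <- structure(
    list(vaso_zones = zones, beat_times = beats, irregular_mask = irr,
         irr_frac = rr$irr_frac, events = events, erp = rr$erp,
         patient_rejected = reject_patient(rr$erp, config$erp_cutoff)),
    class = "quality_report")
  list(patient_id = record$recording$patient_id, events = events,
       features = fm$features, quality = quality, erp = rr$erp,
       patient_rejected = quality$patient_rejected,
       tst_hours = record$tst_hours, true_cahi = record$true_cahi)
}

#' Leave-one-patient-out cross-validated cAHI prediction
#'
#' For each retained (ERP <= cutoff) patient, a classifier is trained on the
#' labeled, non-rejected events of all other retained patients, and applied
#' to every non-rejected event of the held-out patient regardless of label
#' availability. The per-patient predicted central count is converted to a
#' cAHI and extrapolated by 1/(1 - ERP).
#'
#' @param processed List of \code{\link{process_patient}} results.
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{loocv_result}: \code{predictions}
#'   (data.frame, one row per retained patient), \code{event_scores} (list
#'   of per-event score tables), \code{folds} (training/held-out event-id
#'   bookkeeping per fold, for leakage audits).
#' @export
loocv <- function(processed, config = pipeline_config()) {
  retained <- Filter(function(p) !p$patient_rejected, processed)
  if (length(retained) < 3L) stop("need at least 3 retained patients")
  pull_training <- function(p) {
    ok <- !p$events$rejected & !p$events$removed & !is.na(p$events$label)
    list(x = p$features[ok, , drop = FALSE], y = p$events$label[ok],
         ids = paste(p$patient_id, p$events$event_id[ok], sep = ":"))
  }
  rows <- list()
  scores <- list()
  folds <- list()
  for (k in seq_along(retained)) {
    held <- retained[[k]]
    tr <- lapply(retained[-k], pull_training)
    x_tr <- do.call(rbind, lapply(tr, `[[`, "x"))
    y_tr <- unlist(lapply(tr, `[[`, "y"))
    ids_tr <- unlist(lapply(tr, `[[`, "ids"))
    if (length(unique(y_tr)) < 2L)
      stop(sprintf("degenerate fold for patient %s: training data has a ",
                   held$patient_id), "single class")
    spec <- classifier_spec(n_trees = config$n_trees,
                            max_splits = config$max_splits,
                            fp_cost = config$fp_cost,
                            rng_seed = (config$rng_seed + k) %% .Machine$integer.max)
    model <- train_event_classifier(x_tr, y_tr, spec)
    ok <- !held$events$rejected
    pr <- predict_events(model, held$features[ok, , drop = FALSE])
    cahi <- compute_cahi(pr$label, held$erp, held$tst_hours)
    rows[[k]] <- data.frame(
      patient_id = held$patient_id,
      n_events_total = nrow(held$events),
      n_events_rejected = sum(held$events$rejected),
      erp = held$erp,
      n_predicted_central = sum(pr$label == "central"),
      tst_hours = held$tst_hours,
      cahi_raw = cahi$cahi_raw,
      cahi_extrapolated = cahi$cahi_extrapolated,
      true_cahi = held$true_cahi,
      stringsAsFactors = FALSE)
    sc <- data.frame(event_id = held$events$event_id[ok],
                     p_central = pr$p_central, label = pr$label,
                     stringsAsFactors = FALSE)
    scores[[held$patient_id]] <- sc
    folds[[held$patient_id]] <- list(
      held_out_ids = paste(held$patient_id, held$events$event_id, sep = ":"),
      training_ids = ids_tr)
  }
  structure(list(predictions = do.call(rbind, rows), event_scores = scores,
                 folds = folds,
                 n_rejected_patients = length(processed) - length(retained)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d patients (%d rejected upstream)\n",
              nrow(x$predictions), x$n_rejected_patients))
  invisible(x)
}
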