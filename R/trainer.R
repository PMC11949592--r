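# Stratified k-fold training and evaluation with the reference optimisation
# protocol: Adam, L2 weight decay, mini-batches of 16, weighted cross entropy.
# Defaults are the clinical-scale settings (lr 1e-5, 200 epochs, 5 folds);
# desk-scale experiments override epochs/folds/lr explicitly.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 regularisation coefficient (added to gradients).
#' @param batch_size subjects per mini-batch.
#' @param epochs training epochs.
#' @param n_folds folds for cross-validation.
#' @param class_weights optional named weights for (NEG, POS); computed from
#'   the training labels via [class_weights()] when NULL.
#' @param seed integer seed controlling init and epoch shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, weight_decay = 1e-4,
                         batch_size = 16, epochs = 200, n_folds = 5,
                         class_weights = NULL, seed = 1L) {
  if (learning_rate <= 0 || weight_decay < 0 || batch_size < 1 || epochs < 0)
    stopf("learning_rate > 0, weight_decay >= 0, batch_size >= 1, epochs >= 0 required")
  if (n_folds < 2) stopf("n_folds must be >= 2")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 n_folds = as.integer(n_folds), class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Inverse-frequency class weights for weighted cross entropy
#'
#' `w_c = N / (2 * N_c)`: balanced labels give (1, 1); the minority class is
#' up-weighted in proportion to the imbalance.
#' @param labels character vector of `"NEG"`/`"POS"` labels.
#' @return named numeric vector in class order (NEG, POS).
#' @export
class_weights <- function(labels) {
  counts <- table(factor(labels, AMY_CLASSES))
  if (any(counts == 0)) stopf("both classes must be present to compute class weights")
  w <- length(labels) / (2 * as.numeric(counts))
  stats::setNames(w, AMY_CLASSES)
}

#' Stratified k-fold split on the amyloid label
#'
#' Deterministic for a fixed seed; evaluation folds are pairwise disjoint,
#' cover the cohort, and preserve label proportions within one subject.
#' @param labels character label vector, optionally named by subject id.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `fold_split` objects: `fold_id`, `train_ids`, `eval_ids`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  ids <- names(labels) %||% as.character(seq_along(labels))
  counts <- table(labels)
  if (any(counts < k))
    stopf("every class needs >= k members (k = %d, smallest class = %d)", k, min(counts))
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      sel <- which(labels == cl)
      sel <- sel[sample.int(length(sel))]
      assignment[sel] <- rep_len(seq_len(k), length(sel))
    }
  })
  lapply(seq_len(k), function(f) {
    structure(list(fold_id = f,
                   train_ids = ids[assignment != f],
                   eval_ids = ids[assignment == f]),
              class = "fold_split")
  })
}

#' Load a cohort's tensors into memory
#'
#' Reads every subject's volume and matrices, validates them against the model
#' config, and precomputes the graph operators that stay fixed during
#' training.
#' @param manifest a `cohort_manifest`.
#' @param config an [model_config()].
#' @return object of class `cohort_data`: named list of subjects, each with
#'   `id`, `label`, `input` (see [prepare_subject_input()]), and the raw
#'   `fnc`/`sc` connectivity matrices, plus a `labels` attribute.
#' @export
load_cohort_data <- function(manifest, config) {
  stopifnot(inherits(manifest, "cohort_manifest"), inherits(config, "amynet_config"))
  rec <- manifest$records
  br <- active_branches(config)
  subjects <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    vol <- if ("smri" %in% br)
      read_volume(rec$volume_path[i], expected_dim = config$grid_extents) else NULL
    fnc <- if ("fmri" %in% br || TRUE) read_matrix(rec$fnc_path[i], "FNC") else NULL
    sc <- if ("dmri" %in% br || TRUE) read_matrix(rec$sc_path[i], "SC") else NULL
    subjects[[i]] <- list(
      id = rec$subject_id[i],
      label = rec$label[i],
      input = prepare_subject_input(vol = vol, fnc = fnc, sc = sc, config = config),
      fnc = fnc, sc = sc,
      vol = if (!is.null(vol)) vol$data else NULL)
  }
  names(subjects) <- rec$subject_id
  structure(subjects, labels = stats::setNames(rec$label, rec$subject_id),
            config = config, class = "cohort_data")
}

cohort_labels <- function(cohort_data) attr(cohort_data, "labels")

# ---------------------------------------------------------------------------
# Adam optimiser state

adam_init <- function(par) {
  list(m = lapply(par, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(par, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(par, grads, opt, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(par)) {
    g <- grads[[nm]] + wd * par[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(par = par, opt = opt)
}

# accumulate gradient lists (same names/shapes)
grads_add <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

# ---------------------------------------------------------------------------

#' Classification metrics with POS as the positive class
#'
#' Precision is defined as 0 (with a warning) when there are no predicted
#' positives; recall likewise when there are no true positives.
#' @param true,predicted character vectors of `"NEG"`/`"POS"`.
#' @return list with accuracy, precision, recall, f1 and confusion counts.
#' @export
compute_metrics <- function(true, predicted) {
  stopifnot(length(true) == length(predicted), length(true) > 0)
  tp <- sum(true == "POS" & predicted == "POS")
  fp <- sum(true == "NEG" & predicted == "POS")
  fn <- sum(true == "POS" & predicted == "NEG")
  tn <- sum(true == "NEG" & predicted == "NEG")
  if (tp + fp == 0) {
    warnf("no predicted positives; precision defined as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  if (tp + fn == 0) {
    warnf("no true positives; recall defined as 0")
    recall <- 0
  } else recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(true), precision = precision,
       recall = recall, f1 = f1,
       confusion = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Evaluate a model on a set of subjects
#'
#' @param state an `amynet_model`.
#' @param cohort_data a [load_cohort_data()] result.
#' @param ids subject ids to evaluate (default: all).
#' @return list with `metrics` (see [compute_metrics()]) and `predictions`
#'   (data.frame subject_id, true, predicted, p_POS).
#' @export
evaluate <- function(state, cohort_data, ids = NULL) {
  ids <- ids %||% names(cohort_data)
  if (length(ids) == 0) stopf("empty evaluation id list")
  rows <- lapply(ids, function(id) {
    s <- cohort_data[[id]]
    if (is.null(s)) stopf("unknown subject id: %s", id)
    probs <- full_forward(state, s$input)$probs
    data.frame(subject_id = id, true = s$label,
               predicted = AMY_CLASSES[which.max(probs)],
               p_POS = probs[2], stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, rows)
  list(metrics = compute_metrics(predictions$true, predictions$predicted),
       predictions = predictions)
}

#' Train a model on one fold
#'
#' Runs Adam over mini-batches for the configured number of epochs, logging
#' the mean training loss per epoch, then evaluates on the fold's held-out
#' subjects. Zero epochs returns the untrained model's evaluation.
#'
#' @param state an initialised `amynet_model`.
#' @param fold a `fold_split`.
#' @param cohort_data a [load_cohort_data()] result.
#' @param tc a [train_config()].
#' @param verbose log per-epoch losses.
#' @return list with `state` (trained), `epoch_losses`, `metrics`,
#'   `predictions`, `fold_id`.
#' @export
train_fold <- function(state, fold, cohort_data, tc, verbose = FALSE) {
  stopifnot(inherits(state, "amynet_model"), inherits(tc, "train_config"))
  train_ids <- fold$train_ids
  labels <- cohort_labels(cohort_data)[train_ids]
  w <- tc$class_weights %||% class_weights(labels)
  par <- state$par
  opt <- adam_init(par)
  epoch_losses <- numeric(tc$epochs)
  if (tc$epochs > 0) with_seed(tc$seed + 7919L * fold$fold_id, {
    for (ep in seq_len(tc$epochs)) {
      order_ids <- train_ids[sample.int(length(train_ids))]
      batches <- split(order_ids, ceiling(seq_along(order_ids) / tc$batch_size))
      losses <- numeric(0)
      for (batch in batches) {
        acc <- NULL
        bl <- 0
        for (id in batch) {
          s <- cohort_data[[id]]
          y <- match(s$label, AMY_CLASSES)
          fwd <- full_forward(state, s$input)
          lo <- weighted_ce(fwd$logits, y, w)
          bl <- bl + lo$loss
          bw <- full_backward(state, fwd, lo$dlogits, guided = FALSE)
          acc <- grads_add(acc, bw$grads)
        }
        nb <- length(batch)
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
        bl <- bl / nb
        if (!is.finite(bl))
          stopf("non-finite training loss at epoch %d (fold %d); check inputs/learning rate",
                ep, fold$fold_id)
        upd <- adam_step(state$par, acc, opt, tc$learning_rate, tc$weight_decay)
        state$par <- upd$par
        opt <- upd$opt
        losses <- c(losses, bl)
      }
      epoch_losses[ep] <- mean(losses)
      if (verbose) log_line("train", "fold %d epoch %d loss %.5f",
                            fold$fold_id, ep, epoch_losses[ep])
    }
  })
  ev <- evaluate(state, cohort_data, fold$eval_ids)
  list(state = state, epoch_losses = epoch_losses,
       metrics = ev$metrics, predictions = ev$predictions, fold_id = fold$fold_id)
}

#' Stratified cross-validation of the full model
#'
#' Each fold gets a fresh seeded initialisation, is trained on the fold's
#' training subjects only, and is evaluated on its held-out subjects. The best
#' fold is the one with the highest evaluation accuracy (ties broken by the
#' lowest fold id); its evaluation-set predictions feed the post hoc
#' explainability analysis.
#'
#' @param cohort_data a [load_cohort_data()] result.
#' @param mcfg an [model_config()].
#' @param tc a [train_config()].
#' @param verbose log progress.
#' @return object of class `cv_report`: `per_fold` metrics data.frame,
#'   `mean`/`sd` of the four metrics, `best_fold_id`, per-fold `predictions`,
#'   `models` and `folds`.
#' @export
cross_validate <- function(cohort_data, mcfg, tc, verbose = FALSE) {
  labels <- cohort_labels(cohort_data)
  folds <- stratified_kfold(labels, tc$n_folds, seed = tc$seed)
  results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    if (verbose) log_line("cv", "fold %d/%d: training on %d subjects",
                          f, length(folds), length(folds[[f]]$train_ids))
    state <- init_model(mcfg, seed = tc$seed + f)
    results[[f]] <- train_fold(state, folds[[f]], cohort_data, tc, verbose = verbose)
  }
  metric_names <- c("accuracy", "precision", "recall", "f1")
  per_fold <- do.call(rbind, lapply(results, function(r) {
    data.frame(fold_id = r$fold_id,
               accuracy = r$metrics$accuracy, precision = r$metrics$precision,
               recall = r$metrics$recall, f1 = r$metrics$f1)
  }))
  means <- vapply(metric_names, function(m) mean(per_fold[[m]]), numeric(1))
  sds <- vapply(metric_names, function(m) stats::sd(per_fold[[m]]), numeric(1))
  best <- which.max(per_fold$accuracy)  # ties: lowest fold id
  structure(list(per_fold = per_fold, mean = means, sd = sds,
                 best_fold_id = per_fold$fold_id[best],
                 predictions = lapply(results, `[[`, "predictions"),
                 epoch_losses = lapply(results, `[[`, "epoch_losses"),
                 models = lapply(results, `[[`, "state"),
                 folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds (best fold: %d)\n",
              nrow(x$per_fold), x$best_fold_id))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}
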