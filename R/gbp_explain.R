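# Guided-backpropagation attribution, region aggregation, percentage
# contributions and top-k selection. Attribution targets the pre-softmax score
# of the requested class (pre-softmax gradients avoid saturation flattening);
# every rectified-linear backward is replaced by the guided rule.

#' Guided-backpropagation attribution maps for one subject
#'
#' Computes the gradient of the target class's pre-softmax score with respect
#' to each input, with every ReLU backward replaced by
#' [guided_relu_backward()]. The sMRI map has the shape of the input volume;
#' the graph maps hold one attribution per node (the gradient with respect to
#' that node's unit feature).
#'
#' @param state an `amynet_model`.
#' @param input a [prepare_subject_input()] result.
#' @param target_class `"POS"` (default) or `"NEG"`.
#' @return named list of attribution maps for the active branches
#'   (`smri`: 3D array; `fmri`, `dmri`: numeric vectors).
#' @export
attribute_subject <- function(state, input, target_class = "POS") {
  stopifnot(inherits(state, "amynet_model"))
  if (!target_class %in% AMY_CLASSES)
    stopf("unknown target class: %s", target_class)
  fwd <- full_forward(state, input)
  dlogits <- numeric(state$config$n_classes)
  dlogits[match(target_class, AMY_CLASSES)] <- 1
  bw <- full_backward(state, fwd, dlogits, guided = TRUE)
  bw$dinputs
}

#' Average attribution map over correctly classified amyloid-positive subjects
#'
#' The cohort-level map is the voxelwise/nodewise arithmetic mean over the
#' subjects of the analysis set whose true and predicted labels are both POS
#' (conventionally the best fold's evaluation set).
#'
#' @param predictions data.frame with columns subject_id, true, predicted.
#' @param maps named list (by subject id) of [attribute_subject()] outputs.
#' @return named list of mean maps, one entry per modality.
#' @export
mean_positive_map <- function(predictions, maps) {
  ok <- predictions$true == "POS" & predictions$predicted == "POS"
  ids <- predictions$subject_id[ok]
  ids <- ids[ids %in% names(maps)]
  if (length(ids) == 0)
    stopf("no correctly classified POS subjects; cannot form the mean attribution map")
  modalities <- names(maps[[ids[1]]])
  out <- lapply(modalities, function(md) {
    acc <- maps[[ids[1]]][[md]]
    if (length(ids) > 1) for (id in ids[-1]) acc <- acc + maps[[id]][[md]]
    acc / length(ids)
  })
  stats::setNames(out, modalities)
}

#' Aggregate a voxel attribution map by atlas region
#'
#' Region score = (sum of attribution magnitudes inside the region) / (region
#' voxel count), i.e. the attribution sum weighted to account for region
#' volume so that scores are comparable across regions of different size. By
#' default magnitudes are summed: attribution maps carry mixed voxel signs
#' within a region (first-layer filter weights are signed), and a signed sum
#' cancels them and leaves "contribution of the region" ill-defined — the
#' same rationale [percentage_contributions()] applies across regions. The
#' signed sum is available via `absolute = FALSE`.
#'
#' @param map 3D attribution array aligned to the atlas grid.
#' @param atlas an [atlas_partition()].
#' @param absolute sum `|attribution|` (default) instead of the signed values.
#' @return named numeric vector of per-region raw scores.
#' @export
aggregate_smri_by_roi <- function(map, atlas, absolute = TRUE) {
  stopifnot(inherits(atlas, "atlas_partition"))
  if (!all(dim(map) == dim(atlas$label_grid)))
    stopf("attribution grid %s is not aligned to atlas grid %s",
          paste(dim(map), collapse = "x"),
          paste(dim(atlas$label_grid), collapse = "x"))
  labs <- as.vector(atlas$label_grid)
  keep <- labs > 0L
  vals <- as.vector(map)[keep]
  if (absolute) vals <- abs(vals)
  sums <- rowsum(vals, labs[keep])
  scores <- as.vector(sums) / as.numeric(atlas$region_volumes[as.integer(rownames(sums))])
  stats::setNames(scores, atlas$region_names[as.integer(rownames(sums))])
}

#' Percentage contributions of regions within and across modalities
#'
#' Percentages are computed on absolute raw scores (signed sums can cancel and
#' leave "percent of total" ill-defined): `pct_within` is the share of the
#' modality's total absolute score, `pct_across` the share of the grand total
#' over all modalities.
#'
#' @param scores named list (by modality) of named numeric region scores.
#' @return data.frame with columns modality, region, raw, pct_within,
#'   pct_across; within each modality pct_within sums to 100, and pct_across
#'   sums to 100 over all rows.
#' @export
percentage_contributions <- function(scores) {
  stopifnot(is.list(scores), length(scores) > 0)
  for (md in names(scores)) {
    if (length(scores[[md]]) < 1) stopf("modality %s has no regions", md)
    if (all(scores[[md]] == 0))
      stopf("all-zero attribution scores in modality %s: percentages undefined", md)
  }
  grand <- sum(vapply(scores, function(s) sum(abs(s)), numeric(1)))
  out <- lapply(names(scores), function(md) {
    s <- scores[[md]]
    data.frame(modality = md,
               region = names(s) %||% as.character(seq_along(s)),
               raw = as.numeric(s),
               pct_within = 100 * abs(s) / sum(abs(s)),
               pct_across = 100 * abs(s) / grand,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Select the top-k regions by percentage contribution
#'
#' Descending by percentage; ties are broken by region name (lexicographic)
#' for determinism. If fewer than `k` regions exist, all are returned with a
#' warning.
#'
#' @param contributions a [percentage_contributions()] data.frame.
#' @param k number of regions to keep (default 10).
#' @param scope rank by `"within"`-modality or `"across"`-modality percentage.
#' @param modality restrict to one modality (required for scope "within" when
#'   several are present).
#' @return the selected rows, ranked, with a `rank` column.
#' @export
top_k <- function(contributions, k = 10, scope = c("within", "across"),
                  modality = NULL) {
  scope <- match.arg(scope)
  if (k <= 0) stopf("k must be positive")
  df <- contributions
  if (!is.null(modality)) df <- df[df$modality == modality, , drop = FALSE]
  if (scope == "within" && length(unique(df$modality)) > 1)
    stopf("scope 'within' needs a single modality; pass modality=")
  pct <- if (scope == "within") df$pct_within else df$pct_across
  ord <- order(-pct, df$region)
  if (k >= nrow(df)) {
    if (k > nrow(df)) warnf("k = %d >= available regions (%d); returning all", k, nrow(df))
    k <- nrow(df)
  }
  sel <- df[ord[seq_len(k)], , drop = FALSE]
  sel$rank <- seq_len(k)
  rownames(sel) <- NULL
  sel
}

#' Mask an attribution map at a display percentile
#'
#' Display-only helper mirroring the usual rendering of attribution overlays:
#' voxels below the given percentile (default 96th) are zeroed.
#' @param map 3D attribution array.
#' @param percentile percentile threshold in (0, 100).
#' @export
mask_percentile <- function(map, percentile = 96) {
  thr <- stats::quantile(map, percentile / 100)
  map[map < thr] <- 0
  map
}

#' Run the full guided-backpropagation analysis on the best fold
#'
#' Attribution maps are extracted for the best fold's evaluation subjects, the
#' mean map over correctly classified POS subjects is formed per modality,
#' sMRI maps are aggregated by atlas region, node attributions are taken
#' directly from the two graph branches, and percentage contributions plus
#' top-k rankings are derived.
#'
#' @param cv a [cross_validate()] report.
#' @param cohort_data the [load_cohort_data()] used for training.
#' @param atlas an [atlas_partition()] aligned to the volumes.
#' @param k top-k size (default 10).
#' @param target_class attribution target (default `"POS"`).
#' @return list with `mean_maps`, `scores`, `contributions`, `top` (named list
#'   per modality), `predictions` (best-fold evaluation predictions),
#'   `best_fold_id`.
#' @export
explain_best_fold <- function(cv, cohort_data, atlas, k = 10,
                              target_class = "POS") {
  stopifnot(inherits(cv, "cv_report"))
  best <- which(cv$per_fold$fold_id == cv$best_fold_id)
  state <- cv$models[[best]]
  predictions <- cv$predictions[[best]]
  maps <- lapply(predictions$subject_id, function(id)
    attribute_subject(state, cohort_data[[id]]$input, target_class))
  names(maps) <- predictions$subject_id
  mean_maps <- mean_positive_map(predictions, maps)

  scores <- list()
  if (!is.null(mean_maps$smri))
    scores$smri <- aggregate_smri_by_roi(mean_maps$smri, atlas)
  if (!is.null(mean_maps$fmri)) {
    s <- cohort_data[[predictions$subject_id[1]]]
    scores$fmri <- stats::setNames(mean_maps$fmri, s$fnc$node_names)
  }
  if (!is.null(mean_maps$dmri)) {
    s <- cohort_data[[predictions$subject_id[1]]]
    scores$dmri <- stats::setNames(mean_maps$dmri, s$sc$node_names)
  }
  contributions <- percentage_contributions(scores)
  top <- lapply(names(scores), function(md)
    top_k(contributions, k = k, scope = "within", modality = md))
  names(top) <- names(scores)
  list(mean_maps = mean_maps, scores = scores, contributions = contributions,
       top = top, predictions = predictions, best_fold_id = cv$best_fold_id)
}
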