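# Graph summary metrics on the input connectivity matrices and the two-group
# statistical comparison of the top-ranked regions' input features.

#' Node strength of a weighted graph
#'
#' Strength of node i is the signed sum of the weights of its incident edges
#' (negative correlations subtract). An absolute-value variant is available
#' for sensitivity analyses.
#'
#' @param m a [connectivity_matrix()] (typically FNC) or a square symmetric
#'   matrix.
#' @param absolute sum `|w|` instead of `w`.
#' @return named numeric vector of per-node strengths.
#' @export
node_strength <- function(m, absolute = FALSE) {
  vals <- if (inherits(m, "connectivity_matrix")) m$values else m
  check_square_symmetric(vals, what = "strength input")
  A <- vals
  diag(A) <- 0
  if (absolute) A <- abs(A)
  rowSums(A)
}

#' Betweenness centrality of a weighted connectome
#'
#' Fraction of all shortest paths between other node pairs that pass through
#' each node, with edge length the reciprocal of the streamline count (larger
#' counts mean stronger, hence "shorter", connections); zero-count pairs carry
#' no traversable edge. Normalised by (n-1)(n-2) over ordered source-target
#' pairs. Computed with igraph.
#'
#' @param m a [connectivity_matrix()] of kind SC or a nonnegative symmetric
#'   matrix with zero diagonal.
#' @return named numeric vector of normalised betweenness values in \[0, 1\].
#' @export
betweenness_centrality <- function(m) {
  vals <- if (inherits(m, "connectivity_matrix")) m$values else m
  check_square_symmetric(vals, what = "betweenness input")
  if (min(vals) < 0) stopf("betweenness input must be nonnegative")
  A <- vals
  diag(A) <- 0
  n <- nrow(A)
  if (all(A == 0)) stopf("all-zero matrix: betweenness undefined (no paths)")
  if (n < 3) return(stats::setNames(numeric(n), rownames(vals)))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight  # length = 1 / count
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  # igraph counts unordered pairs; ordered-pair normalisation doubles it
  stats::setNames(2 * b / ((n - 1) * (n - 2)), rownames(vals) %||% names(b))
}

#' Extract per-subject input features for the top regions of one modality
#'
#' sMRI: mean gray-matter intensity within each atlas ROI of the subject's
#' input volume; fMRI: node strength of each node from the full FNC matrix;
#' dMRI: betweenness centrality of each node from the full SC matrix.
#' Computed for the requested subjects (conventionally all correctly
#' classified subjects of both classes).
#'
#' @param cohort_data a [load_cohort_data()] result.
#' @param regions region/node names to extract (must belong to the modality's
#'   region set).
#' @param modality `"smri"`, `"fmri"` or `"dmri"`.
#' @param atlas an [atlas_partition()] (sMRI only).
#' @param ids subjects to use (default: all).
#' @return long data.frame: subject_id, group, modality, region, value.
#' @export
extract_features <- function(cohort_data, regions, modality = c("smri", "fmri", "dmri"),
                             atlas = NULL, ids = NULL) {
  modality <- match.arg(modality)
  ids <- ids %||% names(cohort_data)
  rows <- lapply(ids, function(id) {
    s <- cohort_data[[id]]
    if (is.null(s)) stopf("unknown subject id: %s", id)
    vals <- switch(modality,
      smri = {
        if (is.null(atlas)) stopf("atlas required for sMRI features")
        if (is.null(s$vol)) stopf("no volume loaded for subject %s", id)
        labs <- as.vector(atlas$label_grid)
        keep <- labs > 0
        means <- rowsum(as.vector(s$vol)[keep], labs[keep]) /
          as.numeric(atlas$region_volumes)
        stats::setNames(as.vector(means), atlas$region_names)
      },
      fmri = node_strength(s$fnc),
      dmri = betweenness_centrality(s$sc))
    unknown <- setdiff(regions, names(vals))
    if (length(unknown)) stopf("unknown region(s) for %s: %s", modality,
                               paste(unknown, collapse = ", "))
    data.frame(subject_id = id, group = s$label, modality = modality,
               region = regions, value = as.numeric(vals[regions]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Two-sided Mann-Whitney test
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param x,y numeric samples for the two groups (both nonempty).
#' @return list with `U` (the Mann-Whitney U statistic of `x`) and `p`
#'   (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stopf("both groups must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in rank.
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Compare feature distributions between amyloid groups
#'
#' For each (modality, region), a two-sided Mann-Whitney test compares NEG and
#' POS values; Benjamini-Hochberg FDR is applied within each modality's family
#' of tests. Direction is derived from the group medians when the adjusted p
#' falls below `alpha`, otherwise the row is labelled n.s.; a separate trend
#' flag marks raw p < `trend_p`.
#'
#' @param features long data.frame from [extract_features()] (possibly several
#'   modalities row-bound together).
#' @param alpha significance level on adjusted p-values.
#' @param trend_p threshold for the uncorrected trend flag.
#' @param contributions optional [percentage_contributions()] data.frame whose
#'   pct_within values are merged into the output table.
#' @return data.frame (modality, region, pct_within, p_raw, p_fdr, direction,
#'   trend_flag) ordered as the input regions.
#' @export
compare_groups <- function(features, alpha = 0.05, trend_p = 0.1,
                           contributions = NULL) {
  stopifnot(all(c("modality", "region", "group", "value") %in% names(features)))
  out <- list()
  for (md in unique(features$modality)) {
    fm <- features[features$modality == md, , drop = FALSE]
    regions <- unique(fm$region)
    res <- lapply(regions, function(r) {
      fr <- fm[fm$region == r, , drop = FALSE]
      x <- fr$value[fr$group == "NEG"]
      y <- fr$value[fr$group == "POS"]
      if (length(x) == 0 || length(y) == 0)
        stopf("region %s (%s) lacks one of the groups", r, md)
      mw <- mann_whitney(x, y)
      data.frame(modality = md, region = r, p_raw = mw$p,
                 median_neg = stats::median(x), median_pos = stats::median(y),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_fdr <- fdr_bh(res$p_raw)  # family = this modality's tests
    res$direction <- ifelse(res$p_fdr < alpha,
                            ifelse(res$median_neg > res$median_pos, "NEG > POS", "NEG < POS"),
                            "n.s.")
    res$trend_flag <- res$p_raw < trend_p
    out[[md]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(contributions)) {
    out <- merge(out, contributions[, c("modality", "region", "pct_within")],
                 by = c("modality", "region"), sort = FALSE)
  } else out$pct_within <- NA_real_
  out[, c("modality", "region", "pct_within", "p_raw", "p_fdr",
          "direction", "trend_flag")]
}

#' Write a group-comparison table as TSV
#' @param stats_table a [compare_groups()] result.
#' @param path output path.
#' @export
write_stats_table <- function(stats_table, path) {
  utils::write.table(stats_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
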