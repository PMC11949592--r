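# Synthetic cohorts with the statistical structure the analysis assumes:
# atlas-structured gray-matter volumes with group-dependent regional atrophy,
# correlation-valued FNC matrices with group-dependent node-strength shifts,
# and overdispersed streamline-count SC matrices with group-dependent edge
# effects. CSF Abeta42 values are sampled on the correct side of the 980 pg/ml
# cutoff so derived labels always agree with the generating group.

#' Specification for a synthetic cohort
#'
#' Defaults mirror the clinical cohort the pipeline targets: subgroup counts
#' (CN/SMC/EMCI amyloid-negative: 69/75/41; EMCI/LMCI/AD amyloid-positive:
#' 53/53/27), 53 FNC nodes, 84 SC nodes, a 56-region atlas, and 6-mm FWHM
#' Gaussian smoothing of the volumes. The default grid is 32^3 voxels at 3 mm
#' so a full cohort fits on one CPU; the full 121x145x121 grid is available by
#' overriding `grid_extents`.
#'
#' @param n_per_subgroup integer vector of six counts in the order
#'   CN-NEG, SMC-NEG, EMCI-NEG, EMCI-POS, LMCI-POS, AD-POS.
#' @param grid_extents 3D grid extents of the volumes.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_regions atlas region count.
#' @param n_fnc_nodes,n_sc_nodes graph sizes for the two connectivity views.
#' @param atrophy_regions atlas labels carrying gray-matter loss in POS.
#' @param atrophy_effect fractional GM reduction in POS within those regions.
#' @param fnc_effect_nodes FNC nodes whose incident edges shift in POS.
#' @param fnc_effect_delta additive correlation shift on those edges
#'   (re-clamped to \[-1, 1\]).
#' @param sc_effect_edges two-column matrix of SC node pairs whose expected
#'   streamline count is multiplied in POS.
#' @param sc_effect_factor multiplicative streamline-count factor.
#' @param noise_sd_gm per-voxel Gaussian noise sd added to volumes (pre-smooth).
#' @param subject_var_gm sd of the per-subject regional intensity factors
#'   `1 + N(0, subject_var_gm)` emulating anatomical between-subject
#'   variability of regional gray matter.
#' @param fnc_noise sd of per-subject perturbation of the FNC factor loadings.
#' @param sc_dispersion negative-binomial size parameter for SC counts
#'   (smaller = more overdispersed; variance = mu + mu^2/size > mu).
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM in mm (0 disables).
#' @param seed integer seed determining the whole cohort.
#' @return object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_per_subgroup = c(69, 75, 41, 53, 53, 27),
                                  grid_extents = c(32, 32, 32),
                                  voxel_size_mm = 3,
                                  n_regions = 56,
                                  n_fnc_nodes = 53,
                                  n_sc_nodes = 84,
                                  atrophy_regions = 1:5,
                                  atrophy_effect = 0.3,
                                  fnc_effect_nodes = 1:3,
                                  fnc_effect_delta = 0.3,
                                  sc_effect_edges = cbind(1:5, 6:10),
                                  sc_effect_factor = 2,
                                  noise_sd_gm = 0.05,
                                  subject_var_gm = 0.1,
                                  fnc_noise = 0.1,
                                  sc_dispersion = 8,
                                  smoothing_fwhm_mm = 6,
                                  seed = 1L) {
  if (length(n_per_subgroup) != 6 || any(n_per_subgroup < 0))
    stopf("n_per_subgroup must be six nonnegative counts")
  if (length(grid_extents) != 3 || any(grid_extents < 4))
    stopf("grid_extents must be three integers >= 4")
  if (atrophy_effect < 0 || atrophy_effect >= 1)
    stopf("atrophy_effect must lie in [0, 1)")
  if (length(atrophy_regions) && (min(atrophy_regions) < 1 || max(atrophy_regions) > n_regions))
    stopf("atrophy_regions outside 1..n_regions")
  if (length(fnc_effect_nodes) && (min(fnc_effect_nodes) < 1 || max(fnc_effect_nodes) > n_fnc_nodes))
    stopf("fnc_effect_nodes outside 1..n_fnc_nodes")
  sc_effect_edges <- as.matrix(sc_effect_edges)
  if (nrow(sc_effect_edges) && (ncol(sc_effect_edges) != 2 ||
      min(sc_effect_edges) < 1 || max(sc_effect_edges) > n_sc_nodes ||
      any(sc_effect_edges[, 1] == sc_effect_edges[, 2])))
    stopf("sc_effect_edges must be node pairs (i != j) within 1..n_sc_nodes")
  if (sc_effect_factor < 0) stopf("sc_effect_factor must be nonnegative")
  structure(list(
    n_per_subgroup = as.integer(n_per_subgroup),
    grid_extents = as.integer(grid_extents), voxel_size_mm = voxel_size_mm,
    n_regions = as.integer(n_regions), n_fnc_nodes = as.integer(n_fnc_nodes),
    n_sc_nodes = as.integer(n_sc_nodes),
    atrophy_regions = as.integer(atrophy_regions), atrophy_effect = atrophy_effect,
    fnc_effect_nodes = as.integer(fnc_effect_nodes), fnc_effect_delta = fnc_effect_delta,
    sc_effect_edges = sc_effect_edges, sc_effect_factor = sc_effect_factor,
    noise_sd_gm = noise_sd_gm, subject_var_gm = subject_var_gm,
    fnc_noise = fnc_noise, sc_dispersion = sc_dispersion,
    smoothing_fwhm_mm = smoothing_fwhm_mm, seed = as.integer(seed)),
    class = "synthetic_cohort_spec")
}

# subgroup table in generation order
subgroup_table <- function(spec) {
  data.frame(stage = c("CN", "SMC", "EMCI", "EMCI", "LMCI", "AD"),
             label = rep(c("NEG", "POS"), each = 3),
             n = spec$n_per_subgroup, stringsAsFactors = FALSE)
}

#' Build a toy atlas partition on a voxel grid
#'
#' Stands in for the anatomical atlases used on real data. Region seed voxels
#' are sampled inside an ellipsoidal brain mask and every mask voxel is
#' assigned to its nearest seed, which yields nonempty, spatially contiguous
#' regions (Voronoi cells intersected with a convex mask). Deterministic for a
#' fixed seed.
#'
#' @param grid_extents length-3 integer grid size.
#' @param n_regions number of regions (>= 2).
#' @param seed integer seed.
#' @return an [atlas_partition()].
#' @export
make_toy_atlas <- function(grid_extents, n_regions, seed = 1L) {
  if (n_regions < 2) stopf("n_regions must be >= 2")
  d <- as.integer(grid_extents)
  if (prod(d) < n_regions) stopf("grid too small for %d regions", n_regions)
  ctr <- (d + 1) / 2
  rad <- 0.46 * d
  ix <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
  inside <- ((ix[, 1] - ctr[1]) / rad[1])^2 + ((ix[, 2] - ctr[2]) / rad[2])^2 +
    ((ix[, 3] - ctr[3]) / rad[3])^2 <= 1
  if (sum(inside) < n_regions) stopf("brain mask too small for %d regions", n_regions)
  mask_vox <- ix[inside, , drop = FALSE]
  seeds <- with_seed(seed, mask_vox[sample.int(nrow(mask_vox), n_regions), , drop = FALSE])
  # squared Euclidean distance of every mask voxel to every seed
  d2 <- outer(rowSums(mask_vox^2), rep(1, n_regions)) -
    2 * mask_vox %*% t(seeds) + outer(rep(1, nrow(mask_vox)), rowSums(seeds^2))
  lab <- max.col(-d2, ties.method = "first")
  grid <- array(0L, dim = d)
  grid[inside] <- lab
  atlas_partition(grid, sprintf("R%02d", seq_len(n_regions)))
}

# ---------------------------------------------------------------------------
# Gaussian smoothing (separable, truncated at 3 sigma, kernel rows normalised
# so a constant field is preserved; sigma = FWHM / 2.355 in voxel units)

gauss_band_matrix <- function(d, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  K <- outer(seq_len(d), seq_len(d), function(i, j) {
    w <- exp(-((i - j)^2) / (2 * sigma^2))
    w * (abs(i - j) <= r)
  })
  K / rowSums(K)
}

smooth_gaussian_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / 2.355 / voxel_size_mm
  d <- dim(arr)
  K1 <- gauss_band_matrix(d[1], sigma)
  K2 <- gauss_band_matrix(d[2], sigma)
  K3 <- gauss_band_matrix(d[3], sigma)
  out <- array(K1 %*% matrix(arr, d[1], d[2] * d[3]), d)
  out <- aperm(array(K2 %*% matrix(aperm(out, c(2, 1, 3)), d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(K3 %*% matrix(aperm(out, c(3, 1, 2)), d[3], d[1] * d[2]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

# ---------------------------------------------------------------------------
# Modality samplers (draw from the current RNG stream)

# FNC: correlation matrix from a low-rank factor model. Loadings B = B0 + noise
# give covariance BB' + I, converted to correlations (PSD by construction).
# POS effect: additive shift on edges incident to the effect nodes, clamped.
sample_fnc <- function(base_loadings, fnc_noise, effect_nodes = integer(0), delta = 0) {
  n <- nrow(base_loadings)
  B <- base_loadings + matrix(stats::rnorm(length(base_loadings), sd = fnc_noise),
                              n, ncol(base_loadings))
  S <- tcrossprod(B) + diag(n)
  R <- stats::cov2cor(S)
  if (length(effect_nodes) && delta != 0) {
    in_set <- seq_len(n) %in% effect_nodes
    msk <- outer(in_set, in_set, "|")
    diag(msk) <- FALSE
    R[msk] <- R[msk] + delta
    R <- pmin(pmax(R, -1), 1)
    diag(R) <- 1
  }
  (R + t(R)) / 2
}

# SC: symmetric overdispersed counts around a distance-decayed template.
sample_sc <- function(mu, dispersion, effect_edges = NULL, factor = 1) {
  n <- nrow(mu)
  if (!is.null(effect_edges) && nrow(effect_edges) && factor != 1) {
    for (e in seq_len(nrow(effect_edges))) {
      i <- effect_edges[e, 1]; j <- effect_edges[e, 2]
      mu[i, j] <- mu[i, j] * factor
      mu[j, i] <- mu[i, j]
    }
  }
  up <- upper.tri(mu)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rnbinom(sum(up), size = dispersion, mu = mu[up])
  counts + t(counts)
}

# truncated normal via inverse-CDF so each draw uses exactly one uniform
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# CSF Abeta42 group parameters (pg/ml): POS 607.5 +/- 189.3, NEG 1684.3 +/- 601.2
CSF_PARAMS <- list(POS = c(mean = 607.5, sd = 189.3),
                   NEG = c(mean = 1684.3, sd = 601.2))

sample_csf <- function(label, cutoff = 980) {
  p <- CSF_PARAMS[[label]]
  if (label == "POS") rtruncnorm1(1, p["mean"], p["sd"], lower = 0, upper = cutoff - 1e-6)
  else rtruncnorm1(1, p["mean"], p["sd"], lower = cutoff)
}

# ---------------------------------------------------------------------------

#' Generate a synthetic cohort on disk
#'
#' Produces, under `out_dir`: per-subject gray-matter volumes (NIfTI), FNC and
#' SC matrices (TSV), the toy atlas (NIfTI + TSV), a cohort manifest (CSV) and
#' a YAML snapshot of the generating spec. Gray-matter volumes are a
#' region-mean template scaled by per-subject regional anatomical factors,
#' plus voxel noise, with the atrophy regions of amyloid-positive subjects
#' scaled by (1 - atrophy_effect) before Gaussian smoothing. Fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (a `cohort_manifest`), `atlas`, and `dir`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("vols", "fnc", "sc"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)

  atlas <- make_toy_atlas(spec$grid_extents, spec$n_regions, seed = spec$seed)
  write_atlas(atlas, file.path(out_dir, "atlas.nii.gz"),
              voxel_size = spec$voxel_size_mm)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # cohort-level templates
  region_means <- stats::runif(spec$n_regions, 0.4, 0.8)
  q <- 4L
  fnc_loadings <- matrix(stats::rnorm(spec$n_fnc_nodes * q, sd = 0.5),
                         spec$n_fnc_nodes, q)
  centroids <- matrix(stats::runif(spec$n_sc_nodes * 3), spec$n_sc_nodes, 3)
  dist_sc <- as.matrix(stats::dist(centroids))
  sc_mu <- 400 * exp(-dist_sc / 0.25)
  diag(sc_mu) <- 0

  template <- array(c(0, region_means)[atlas$label_grid + 1L],
                    dim = spec$grid_extents)
  mask <- atlas$label_grid > 0L
  atrophy_mask <- array(atlas$label_grid %in% spec$atrophy_regions,
                        dim = spec$grid_extents)
  fnc_names <- sprintf("IC%02d", seq_len(spec$n_fnc_nodes))
  sc_names <- sprintf("ROI%02d", seq_len(spec$n_sc_nodes))

  groups <- subgroup_table(spec)
  records <- list()
  sid <- 0L
  for (g in seq_len(nrow(groups))) {
    for (i in seq_len(groups$n[g])) {
      sid <- sid + 1L
      id <- sprintf("S%04d", sid)
      label <- groups$label[g]

      rfac <- pmax(1 + stats::rnorm(spec$n_regions, sd = spec$subject_var_gm), 0.1)
      vol <- template * array(c(1, rfac)[atlas$label_grid + 1L],
                              dim = spec$grid_extents)
      if (label == "POS" && spec$atrophy_effect > 0)
        vol[atrophy_mask] <- vol[atrophy_mask] * (1 - spec$atrophy_effect)
      vol[mask] <- vol[mask] + stats::rnorm(sum(mask), sd = spec$noise_sd_gm)
      vol <- smooth_gaussian_3d(vol, spec$smoothing_fwhm_mm, spec$voxel_size_mm)

      fnc <- sample_fnc(fnc_loadings, spec$fnc_noise,
                        effect_nodes = if (label == "POS") spec$fnc_effect_nodes else integer(0),
                        delta = spec$fnc_effect_delta)
      sc <- sample_sc(sc_mu, spec$sc_dispersion,
                      effect_edges = if (label == "POS") spec$sc_effect_edges else NULL,
                      factor = spec$sc_effect_factor)
      csf <- sample_csf(label)

      vpath <- file.path(out_dir, "vols", paste0(id, ".nii.gz"))
      fpath <- file.path(out_dir, "fnc", paste0(id, ".tsv"))
      spath <- file.path(out_dir, "sc", paste0(id, ".tsv"))
      write_volume(gm_volume(vol, voxel_size = spec$voxel_size_mm), vpath)
      write_matrix(connectivity_matrix(fnc, "FNC", fnc_names), fpath)
      write_matrix(connectivity_matrix(sc, "SC", sc_names), spath)

      records[[sid]] <- data.frame(
        subject_id = id, stage = groups$stage[g], csf_abeta42 = csf,
        label = label, volume_path = vpath, fnc_path = fpath, sc_path = spath,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  derived <- label_amyloid_status(records$csf_abeta42)
  if (!all(derived == records$label))
    stopf("internal generation error: derived labels disagree with generating groups")

  manifest <- assemble_cohort(records, provenance = "synthetic cohort",
                              seed = spec$seed)
  if (nrow(manifest$excluded) > 0)
    stopf("internal generation error: %d subjects failed assembly", nrow(manifest$excluded))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  yaml::write_yaml(lapply(unclass(spec), function(x) if (is.matrix(x)) as.data.frame(x) else x),
                   file.path(out_dir, "cohort_spec.yaml"))
  list(manifest = manifest, atlas = atlas, dir = out_dir)
}

#' Generate node time courses with a target correlation structure
#'
#' Draws Gaussian series whose population correlation equals `target_fnc`;
#' the empirical Pearson correlation converges to the target as the number of
#' timepoints grows. Used to exercise the FNC computation the way IC time
#' courses are used on real data.
#'
#' @param n_nodes number of series.
#' @param n_timepoints series length.
#' @param target_fnc target correlation matrix (positive semidefinite within
#'   1e-8).
#' @param seed integer seed.
#' @return `n_timepoints x n_nodes` matrix.
#' @export
generate_timecourses <- function(n_nodes, n_timepoints, target_fnc = diag(n_nodes),
                                 seed = 1L) {
  check_square_symmetric(target_fnc, what = "target_fnc")
  if (nrow(target_fnc) != n_nodes) stopf("target_fnc size != n_nodes")
  eig <- eigen(target_fnc, symmetric = TRUE)
  if (min(eig$values) < -1e-8)
    stopf("target_fnc is not positive semidefinite (min eigenvalue %.3g); consider a nearest-correlation repair before use",
          min(eig$values))
  if (n_timepoints < n_nodes + 1)
    warnf("n_timepoints (%d) <= n_nodes (%d): empirical correlation will be rank-deficient",
          n_timepoints, n_nodes)
  lam <- pmax(eig$values, 0)
  half <- eig$vectors %*% (sqrt(lam) * t(eig$vectors))
  Z <- with_seed(seed, matrix(stats::rnorm(n_timepoints * n_nodes), n_timepoints, n_nodes))
  Z %*% half
}
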