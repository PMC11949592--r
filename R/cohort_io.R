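# Data model, amyloid labeling, cohort assembly and on-disk formats.
#
# Volumes travel as NIfTI-1 (.nii/.nii.gz), connectivity matrices as TSV with a
# header row of node names, cohort manifests as CSV. All readers validate type
# invariants and refuse to coerce silently.

#' Clinical stages recognised by the cohort model
#' @export
AMY_STAGES <- c("CN", "SMC", "EMCI", "LMCI", "AD")

#' Amyloid classes in fixed order (used for model outputs and metrics)
#' @export
AMY_CLASSES <- c("NEG", "POS")

# stages eligible for each amyloid class when assembling the analysis cohort
NEG_STAGES <- c("CN", "SMC", "EMCI")
POS_STAGES <- c("EMCI", "LMCI", "AD")

#' Label amyloid status from a CSF Abeta42 concentration
#'
#' A subject is amyloid-positive when the CSF Abeta42 level lies strictly below
#' the cutoff (default 980 pg/ml); a value exactly at the cutoff is negative.
#'
#' @param csf_abeta42 numeric vector of CSF Abeta42 concentrations in pg/ml;
#'   must be finite and nonnegative.
#' @param cutoff positivity cutoff in pg/ml.
#' @return character vector of `"POS"`/`"NEG"`.
#' @examples
#' label_amyloid_status(c(607.5, 1684.3, 980))
#' @export
label_amyloid_status <- function(csf_abeta42, cutoff = 980) {
  if (!is.numeric(csf_abeta42) || length(csf_abeta42) == 0)
    stopf("csf_abeta42 must be a nonempty numeric vector")
  if (any(!is.finite(csf_abeta42)))
    stopf("csf_abeta42 contains non-finite values")
  if (any(csf_abeta42 < 0))
    stopf("csf_abeta42 contains negative values")
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stopf("cutoff must be a positive scalar")
  ifelse(csf_abeta42 < cutoff, "POS", "NEG")
}

#' Assemble the analysis cohort from subject records
#'
#' Applies the stage-by-status eligibility rules: amyloid-negative subjects are
#' retained only at the CN, SMC or EMCI stages; amyloid-positive subjects only
#' at EMCI, LMCI or AD. Late-stage amyloid-negative subjects are excluded
#' because their decline may reflect non-amyloid pathology. Records missing any
#' modality file reference are excluded as incomplete.
#'
#' @param records data.frame with columns `subject_id`, `stage`, and either
#'   `label` or `csf_abeta42` (label is derived via [label_amyloid_status()]
#'   when absent); optional columns `volume_path`, `fnc_path`, `sc_path`.
#' @param cutoff CSF cutoff in pg/ml used when deriving labels.
#' @param provenance free-text provenance note.
#' @param seed generating seed when the cohort is synthetic, else `NA`.
#' @param require_modalities if TRUE (default), records whose modality paths
#'   are missing or unresolvable are excluded.
#' @return an object of class `cohort_manifest`: list with `records` (retained
#'   subjects), `excluded` (dropped subjects with a `reason` column),
#'   `provenance`, `seed`.
#' @export
assemble_cohort <- function(records, cutoff = 980, provenance = "",
                            seed = NA_integer_, require_modalities = TRUE) {
  if (!is.data.frame(records))
    stopf("records must be a data.frame")
  if (nrow(records) == 0) {
    empty <- records
    return(structure(list(records = empty, excluded = cbind(empty, reason = character(0)),
                          provenance = provenance, seed = seed),
                     class = "cohort_manifest"))
  }
  need <- c("subject_id", "stage")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("records is missing required columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records$subject_id))
    stopf("subject_id values are not unique")
  bad_stage <- !records$stage %in% AMY_STAGES
  if (any(is.na(records$stage)) || any(bad_stage))
    stopf("record(s) with missing/unknown stage: %s",
          paste(records$subject_id[is.na(records$stage) | bad_stage], collapse = ", "))

  if (!"label" %in% names(records)) {
    if (!"csf_abeta42" %in% names(records))
      stopf("records need either a label or a csf_abeta42 column")
    records$label <- label_amyloid_status(records$csf_abeta42, cutoff)
  } else {
    if (any(is.na(records$label)) || !all(records$label %in% AMY_CLASSES))
      stopf("record(s) with missing/unknown label: %s",
            paste(records$subject_id[is.na(records$label) |
                                       !records$label %in% AMY_CLASSES], collapse = ", "))
    if ("csf_abeta42" %in% names(records) && any(ok <- is.finite(records$csf_abeta42))) {
      derived <- label_amyloid_status(records$csf_abeta42[ok], cutoff)
      if (any(derived != records$label[ok]))
        stopf("label inconsistent with csf_abeta42 for subject(s): %s",
              paste(records$subject_id[ok][derived != records$label[ok]], collapse = ", "))
    }
  }

  reason <- rep(NA_character_, nrow(records))
  ineligible <- (records$label == "NEG" & !records$stage %in% NEG_STAGES) |
    (records$label == "POS" & !records$stage %in% POS_STAGES)
  reason[ineligible] <- sprintf("stage %s ineligible for %s class",
                                records$stage[ineligible], records$label[ineligible])

  if (require_modalities) {
    path_cols <- c("volume_path", "fnc_path", "sc_path")
    have_cols <- intersect(path_cols, names(records))
    if (length(have_cols) < 3L) {
      incomplete <- is.na(reason)
      reason[incomplete] <- "missing modality reference"
    } else {
      for (pc in path_cols) {
        bad <- is.na(records[[pc]]) | !nzchar(records[[pc]]) | !file.exists(records[[pc]])
        sel <- bad & is.na(reason)
        reason[sel] <- sprintf("missing modality: %s", pc)
      }
    }
  }

  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  for (id in excluded$subject_id)
    log_line("cohort", "excluded %s (%s)", id, excluded$reason[excluded$subject_id == id])
  structure(list(records = records[keep, , drop = FALSE],
                 excluded = excluded, provenance = provenance, seed = seed),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  tab <- table(factor(x$records$label, AMY_CLASSES),
               factor(x$records$stage, AMY_STAGES))
  cat(sprintf("cohort_manifest: %d subjects retained (%d NEG, %d POS), %d excluded\n",
              nrow(x$records), sum(x$records$label == "NEG"),
              sum(x$records$label == "POS"), nrow(x$excluded)))
  print(tab)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gray-matter volumes

#' Construct a gray-matter volume object
#'
#' @param data 3D numeric array of gray-matter probabilities/intensities.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param affine optional 4x4 voxel-to-world mapping; defaults to a scaled
#'   identity from `voxel_size`.
#' @return object of class `gm_volume` with fields `data`, `affine`,
#'   `voxel_size`.
#' @export
gm_volume <- function(data, voxel_size = 3, affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a 3D array")
  if (any(!is.finite(data))) stopf("volume contains non-finite values")
  if (!is_scalar_number(voxel_size) || voxel_size <= 0)
    stopf("voxel_size must be a positive scalar (mm)")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stopf("affine must be a 4x4 matrix")
  if (all(data == 0)) warnf("volume is identically zero")
  structure(list(data = data, affine = affine, voxel_size = voxel_size),
            class = "gm_volume")
}

#' Write a gray-matter volume as NIfTI-1
#'
#' Values are stored as float64 so a write/read round trip is bit-exact.
#' @param vol a [gm_volume()] object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  data <- vol$data
  attr(data, "pixdim") <- rep(vol$voxel_size, 3)
  img <- RNifti::asNifti(data, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a gray-matter volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param expected_dim optional length-3 integer vector; a mismatch with the
#'   on-disk grid is an error (the network input grid is fixed by config).
#' @return a [gm_volume()] object.
#' @export
read_volume <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("malformed NIfTI file %s: %s", path, conditionMessage(e)))
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L) stopf("%s is not a 3D volume", path)
  if (!is.null(expected_dim) && !all(dim(data) == expected_dim))
    stopf("volume grid %s does not match configured grid %s",
          paste(dim(data), collapse = "x"), paste(expected_dim, collapse = "x"))
  vs <- RNifti::pixdim(img)[1]
  gm_volume(data, voxel_size = vs, affine = RNifti::xform(img))
}

# ---------------------------------------------------------------------------
# Connectivity matrices

#' Construct a validated connectivity matrix
#'
#' FNC matrices hold Pearson correlations between independent-component time
#' courses (entries in \[-1, 1\], unit diagonal); SC matrices hold streamline
#' counts between anatomical ROIs (nonnegative, zero diagonal). Both must be
#' symmetric within 1e-8.
#'
#' @param values square numeric matrix.
#' @param kind `"FNC"` or `"SC"`.
#' @param node_names optional character vector of node labels (defaults to
#'   existing dimnames or `n1..nN`).
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("FNC", "SC"), node_names = NULL) {
  kind <- match.arg(kind)
  check_square_symmetric(values, tol = 1e-8, what = sprintf("%s matrix", kind))
  n <- nrow(values)
  if (is.null(node_names)) node_names <- rownames(values) %||% sprintf("n%02d", seq_len(n))
  if (length(node_names) != n) stopf("node_names length %d != matrix size %d", length(node_names), n)
  if (kind == "FNC") {
    if (max(abs(values)) > 1 + 1e-8)
      stopf("FNC entries must lie in [-1, 1]; max |value| = %.4f", max(abs(values)))
    values <- pmin(pmax(values, -1), 1)
  } else {
    if (min(values) < 0) stopf("SC entries must be nonnegative; min = %.4f", min(values))
    if (any(diag(values) != 0)) stopf("SC diagonal must be zero (self-connections ignored)")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(node_names, node_names)
  structure(list(kind = kind, values = values, node_names = node_names),
            class = "connectivity_matrix")
}

#' Write a connectivity matrix as TSV with a node-name header
#' @param m a [connectivity_matrix()].
#' @param path output TSV path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  utils::write.table(m$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a connectivity matrix from TSV
#'
#' The header row carries node names; symmetry and value-range invariants are
#' enforced on read. When `expected_names` is given, a node-order mismatch is
#' an error (matrices are never silently reordered).
#' @param path TSV file path.
#' @param kind `"FNC"` or `"SC"`.
#' @param expected_names optional character vector the header must equal.
#' @export
read_matrix <- function(path, kind = c("FNC", "SC"), expected_names = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(df)
  rownames(values) <- colnames(values)
  if (!is.null(expected_names) && !identical(colnames(values), expected_names))
    stopf("node names in %s do not match the configured node list", path)
  connectivity_matrix(values, kind = kind, node_names = colnames(values))
}

# ---------------------------------------------------------------------------
# Atlas partitions

#' Construct an atlas partition
#'
#' @param label_grid 3D integer array; 0 is background, labels `1..R` index
#'   `region_names`.
#' @param region_names character vector naming every nonzero label.
#' @return object of class `atlas_partition` with `label_grid`, `region_names`,
#'   `region_volumes` (voxel counts in label order).
#' @export
atlas_partition <- function(label_grid, region_names) {
  if (!is.array(label_grid) || length(dim(label_grid)) != 3L)
    stopf("label_grid must be a 3D array")
  labs <- sort(unique(as.integer(label_grid)))
  labs <- labs[labs != 0L]
  if (length(labs) == 0) stopf("atlas has no nonzero labels")
  if (!all(labs == seq_along(region_names)))
    stopf("labels present (%s) must be exactly 1..%d matching region_names",
          paste(range(labs), collapse = "-"), length(region_names))
  counts <- tabulate(as.integer(label_grid), nbins = length(region_names))
  if (any(counts == 0)) stopf("region(s) with zero voxels: %s",
                              paste(region_names[counts == 0], collapse = ", "))
  structure(list(label_grid = label_grid, region_names = region_names,
                 region_volumes = stats::setNames(counts, region_names)),
            class = "atlas_partition")
}

#' Write an atlas partition (NIfTI label grid + TSV region table)
#' @param atlas an [atlas_partition()].
#' @param path_nii label-grid NIfTI path; region table goes to the same path
#'   with extension `.tsv` unless `path_tsv` is given.
#' @param path_tsv optional region-table path.
#' @param voxel_size voxel size in mm recorded in the NIfTI header.
#' @export
write_atlas <- function(atlas, path_nii, path_tsv = NULL, voxel_size = 3) {
  stopifnot(inherits(atlas, "atlas_partition"))
  if (is.null(path_tsv)) path_tsv <- sub("\\.nii(\\.gz)?$", ".tsv", path_nii)
  grid <- atlas$label_grid
  attr(grid, "pixdim") <- rep(voxel_size, 3)
  img <- RNifti::asNifti(grid, datatype = "int32")
  RNifti::writeNifti(img, path_nii, datatype = "int32")
  utils::write.table(
    data.frame(label = seq_along(atlas$region_names),
               region = atlas$region_names,
               n_voxels = as.integer(atlas$region_volumes)),
    path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_nii)
}

#' Read an atlas partition written by [write_atlas()]
#' @param path_nii label-grid NIfTI path.
#' @param path_tsv region-table path (default: sibling `.tsv`).
#' @export
read_atlas <- function(path_nii, path_tsv = NULL) {
  if (is.null(path_tsv)) path_tsv <- sub("\\.nii(\\.gz)?$", ".tsv", path_nii)
  img <- RNifti::readNifti(path_nii)
  grid <- array(as.integer(img), dim = dim(img))
  tab <- utils::read.delim(path_tsv)
  atlas_partition(grid, as.character(tab$region))
}

# ---------------------------------------------------------------------------
# Manifests on disk

#' Write a cohort manifest as CSV
#' @param manifest a `cohort_manifest`.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  utils::write.csv(manifest$records, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest CSV and re-run assembly validation
#' @param path CSV path with columns subject_id, stage, csf_abeta42, label and
#'   the three modality paths.
#' @param ... passed to [assemble_cohort()].
#' @export
read_manifest <- function(path, ...) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assemble_cohort(df, ...)
}
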