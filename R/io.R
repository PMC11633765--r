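#' Read a 4D NIfTI volume series
#'
#' Loads a 4D functional image, optionally restricts it to a gray-matter
#' mask, and returns the frames x voxels carrier used by every pipeline
#' stage. TR is taken from the header's fourth pixdim unless overridden.
#'
#' @param path 4D NIfTI file.
#' @param gm_mask_path optional 3D NIfTI mask; voxels with value > 0.5 are
#'   kept. Default: all voxels.
#' @param tr repetition time in seconds; default: from the header.
#' @return A [volume_series()].
#' @export
read_volume <- function(path, gm_mask_path = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("'", path, "' is not a 4D image (dim ",
                            paste(d, collapse = "x"), ")")
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop("'", path, "' has no usable TR in its header; pass 'tr'")
  }
  grid <- d[1:3]
  if (!is.null(gm_mask_path)) {
    mask <- RNifti::readNifti(gm_mask_path)
    if (!identical(as.integer(dim(mask)), as.integer(grid)))
      stop("mask '", gm_mask_path, "' grid ",
           paste(dim(mask), collapse = "x"), " does not match volume grid ",
           paste(grid, collapse = "x"))
    keep <- which(as.array(mask) > 0.5)
  } else {
    keep <- seq_len(prod(grid))
  }
  vi <- arrayInd(keep, .dim = grid)
  mat <- matrix(aperm(as.array(img), c(4, 1, 2, 3)), d[4], prod(grid))
  volume_series(mat[, keep, drop = FALSE], tr = tr, voxel_index = vi,
                grid = grid)
}

#' Write a volume series as 4D NIfTI
#'
#' Inverse of [read_volume()]: voxels outside the mask are written as 0.
#'
#' @param series a [volume_series()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  d <- c(series$grid, n_frames(series))
  a <- array(0, dim = d)
  flat <- series$voxel_index[, 1] +
    series$grid[1] * (series$voxel_index[, 2] - 1L) +
    series$grid[1] * series$grid[2] * (series$voxel_index[, 3] - 1L)
  npv <- prod(series$grid)
  for (t in seq_len(d[4])) a[flat + (t - 1L) * npv] <- series$data[t, ]
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1, 1, 1, series$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a seed or atlas mask aligned to a series
#'
#' @param path 3D NIfTI image of weights (probabilistic) or 0/1 (binary).
#' @param series the [volume_series()] the mask must align to.
#' @return A [seed_mask()] over the series' voxel columns.
#' @export
read_mask <- function(path, series) {
  img <- RNifti::readNifti(path)
  if (!identical(as.integer(dim(img)), as.integer(series$grid)))
    stop("mask '", path, "' grid ", paste(dim(img), collapse = "x"),
         " does not match series grid ", paste(series$grid, collapse = "x"))
  seed_mask(as.array(img)[series$voxel_index])
}

#' Read a motion-parameter or covariates TSV
#'
#' @param path tab-separated file with a header row.
#' @param type `"motion"` (requires trans_x..rot_z), `"nuisance"` (wm, csf),
#'   or `"covariates"` (subject_id, group, age, sex, medication, bdi,
#'   stai_s).
#' @return data.frame (motion additionally as a plain matrix attribute-free).
#' @export
read_table <- function(path, type = c("motion", "nuisance", "covariates")) {
  type <- match.arg(type)
  d <- utils::read.delim(path, check.names = FALSE)
  need <- switch(type,
    motion = c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"),
    nuisance = c("wm", "csf"),
    covariates = c("subject_id", "group", "age", "sex", "medication",
                   "bdi", "stai_s"))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("'", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (type == "motion") {
    m <- as.matrix(d[need])
    if (any(!is.finite(m))) stop("'", path, "' contains non-finite values")
    return(m)
  }
  d
}

#' Write a synthetic cohort to disk
#'
#' Per subject: a 4D NIfTI series, a motion TSV and a nuisance TSV; plus one
#' cohort covariates TSV and a JSON ground-truth sidecar (latent state
#' labels, spike frames, configuration).
#'
#' @param cohort a `cap_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_volume(s$series, file.path(dir, paste0(s$id, "_bold.nii.gz")))
    utils::write.table(as.data.frame(s$motion),
                       file.path(dir, paste0(s$id, "_motion.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(s$nuisance,
                       file.path(dir, paste0(s$id, "_nuisance.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- list(
    config = cohort$config[c("n_per_group", "n_frames", "tr", "grid",
                             "k_true", "seed_voxels", "pattern_amplitude",
                             "noise_sd", "motion_spike_prob", "rng_seed")],
    state_labels = lapply(cohort$subjects, function(s) s$truth$state_labels),
    spike_frames = lapply(cohort$subjects, function(s) s$truth$spike_frames)
  )
  names(truth$state_labels) <- names(truth$spike_frames) <-
    vapply(cohort$subjects, `[[`, "", "id")
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write pipeline results with a run manifest
#'
#' Emits the per-subject metric table and flattened transition matrices as
#' TSV, the group-comparison table as TSV, each CAP map as 3D NIfTI, and a
#' JSON manifest recording the settings, their hash, seeds, package version
#' and per-stage frame counts — enough to confirm that a rerun reproduced
#' the same analysis.
#'
#' @param result a [run_cap_pipeline()] result.
#' @param dir output directory.
#' @param voxel_index,grid voxel geometry for writing the CAP maps; defaults
#'   to the full grid implied by the map length being a full grid (otherwise
#'   required).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, voxel_index = NULL, grid = NULL) {
  stopifnot(inherits(result, "cap_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mt <- cbind(subject_id = result$covariates$subject_id,
              group = result$covariates$group, result$metric_table)
  utils::write.table(mt, file.path(dir, "temporal_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$group_result))
    utils::write.table(as.data.frame(result$group_result),
                       file.path(dir, "group_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(voxel_index) && !is.null(grid)) {
    for (j in seq_len(result$caps$k)) {
      a <- frame_to_array(result$caps$maps[, j], voxel_index, grid)
      RNifti::writeNifti(RNifti::asNifti(a),
                         file.path(dir, sprintf("cap%02d_map.nii.gz", j)))
    }
  }
  settings_json <- jsonlite::toJSON(result$settings, auto_unbox = TRUE,
                                    digits = NA)
  tf <- tempfile(); writeLines(settings_json, tf)
  manifest <- list(
    package = "capdyn",
    version = as.character(utils::packageVersion("capdyn")),
    settings = result$settings,
    config_hash = unname(tools::md5sum(tf)),
    n_subjects = length(result$sequences),
    n_selected = result$covariates$n_selected,
    n_excluded = result$covariates$n_excluded,
    k = result$caps$k,
    cap_sizes = result$caps$sizes,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
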