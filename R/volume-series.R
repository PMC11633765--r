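#' Masked volume time-series container
#'
#' The central data carrier of the pipeline: a frames-by-voxels matrix of
#' gray-matter-masked BOLD values together with the repetition time, the
#' mapping from voxel columns back to 3D grid coordinates, and a per-frame
#' validity flag used for motion censoring. Frames are never deleted by any
#' stage; censored frames are flagged so the original temporal adjacency is
#' preserved for the dynamics computations.
#'
#' @param data numeric matrix, frames x voxels.
#' @param tr repetition time in seconds.
#' @param voxel_index integer matrix, voxels x 3, giving the (x, y, z) grid
#'   coordinate of each voxel column.
#' @param grid integer vector of length 3, the full grid dimensions.
#' @param frame_valid logical vector of per-frame validity flags; defaults to
#'   all `TRUE`.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr, voxel_index, grid, frame_valid = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  voxel_index <- as.matrix(voxel_index)
  if (ncol(voxel_index) != 3L)
    stop("'voxel_index' must have 3 columns (x, y, z)")
  if (nrow(voxel_index) != ncol(data))
    stop("voxel_index rows (", nrow(voxel_index),
         ") do not match data columns (", ncol(data), ")")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 1L))
    stop("'grid' must be 3 positive integers")
  if (any(voxel_index < 1L) || any(voxel_index > rep(grid, each = nrow(voxel_index))))
    stop("voxel coordinates fall outside the grid")
  if (is.null(frame_valid)) frame_valid <- rep(TRUE, nrow(data))
  frame_valid <- as.logical(frame_valid)
  if (length(frame_valid) != nrow(data))
    stop("'frame_valid' length (", length(frame_valid),
         ") does not match frame count (", nrow(data), ")")
  structure(
    list(data = data, tr = tr, voxel_index = voxel_index, grid = grid,
         frame_valid = frame_valid, n_excluded = 0L,
         zero_variance_voxels = integer(0), log = character(0)),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  cat("<volume_series> ", nrow(x$data), " frames x ", ncol(x$data),
      " voxels, TR = ", x$tr, " s\n", sep = "")
  cat("  grid ", paste(x$grid, collapse = " x "),
      "; valid frames: ", sum(x$frame_valid), "/", length(x$frame_valid),
      "\n", sep = "")
  if (length(x$log)) cat("  steps: ", paste(x$log, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

# number of frames / voxels, internal shorthand
n_frames <- function(series) nrow(series$data)
n_voxels <- function(series) ncol(series$data)

#' Full-grid voxel index for a rectangular grid
#'
#' @param grid integer vector of length 3.
#' @return integer matrix, prod(grid) x 3, x coordinate varying fastest
#'   (column-major array order).
#' @export
grid_voxel_index <- function(grid) {
  grid <- as.integer(grid)
  arrayInd(seq_len(prod(grid)), .dim = grid)
}

# scatter one frame (voxel vector) into a dense 3D array; unmasked voxels 0
frame_to_array <- function(values, voxel_index, grid) {
  a <- array(0, dim = grid)
  a[voxel_index] <- values
  a
}
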