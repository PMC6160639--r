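#' Acquisition specification
#'
#' Describes one functional run: repetition time, number of volumes
#' (including initial dummy volumes), the spatial grid and the affine that
#' maps 0-based voxel indices to mm coordinates. Defaults mirror a 3 T EPI
#' protocol at TR 2.5 s with 4 dummy volumes on a desk-scale 3 mm grid
#' placed symmetrically around the midline.
#'
#' @param tr_seconds repetition time in seconds
#' @param n_volumes number of volumes acquired (dummies included)
#' @param n_dummy initial dummy volumes discarded before analysis
#' @param grid_shape integer vector of 3 voxel counts
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths in mm
#' @param affine 4x4 voxel-to-mm matrix; default centres the grid on the
#'   origin with axes aligned to the voxel lattice
#' @return an object of class `acq_spec`
#' @export
acq_spec <- function(tr_seconds = 2.5, n_volumes = 222L, n_dummy = 4L,
                     grid_shape = c(24L, 28L, 24L),
                     voxel_size_mm = c(3, 3, 3), affine = NULL) {
  stopifnot(tr_seconds > 0, length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  n_volumes <- as.integer(n_volumes); n_dummy <- as.integer(n_dummy)
  if (n_dummy < 0 || n_dummy >= n_volumes)
    stopf("n_dummy (%d) must be in [0, n_volumes)", n_dummy)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size_mm
    affine[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stopf("affine must be an invertible 4x4 matrix")
  structure(list(tr_seconds = tr_seconds, n_volumes = n_volumes,
                 n_dummy = n_dummy, grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, affine = affine),
            class = "acq_spec")
}

#' @rdname acq_spec
#' @details `attention_acq()` is the three-run multimodal sentence task
#'   protocol (222 volumes); `nback_acq()` the two-run n-back protocol
#'   (155 volumes).
#' @param ... passed on to [acq_spec()]
#' @export
attention_acq <- function(...) acq_spec(n_volumes = 222L, ...)

#' @rdname acq_spec
#' @export
nback_acq <- function(...) acq_spec(n_volumes = 155L, ...)

# usable run length in seconds, after dummy removal
run_duration <- function(acq) (acq$n_volumes - acq$n_dummy) * acq$tr_seconds

#' Gridded BOLD time series
#'
#' Container for a 4D volume: `data` is an X-Y-Z-T array, `affine` maps
#' 0-based voxel indices to mm, `mask` marks analyzed voxels.
#'
#' @param data 4D numeric array (X, Y, Z, T)
#' @param affine 4x4 voxel-to-mm matrix
#' @param tr_seconds repetition time in seconds
#' @param mask 3D logical array; default all `TRUE`
#' @return an object of class `volume4d`
#' @export
volume4d <- function(data, affine, tr_seconds, mask = NULL) {
  stopifnot(length(dim(data)) == 4)
  sp <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!all(dim(mask) == sp)) stopf("mask shape must match spatial shape")
  structure(list(data = data, affine = as.matrix(affine),
                 tr_seconds = tr_seconds, mask = mask),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d voxels, %d frames, TR %.3g s, %d masked\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

n_frames <- function(vol) dim(vol$data)[4]

# T x V matrix view of a volume (V = all voxels, column-major spatial order)
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, prod(d[1:3]), d[4]))
}

matrix_to_vol <- function(m, template) {
  d <- dim(template$data); d[4] <- nrow(m)
  volume4d(array(t(m), d), template$affine, template$tr_seconds, template$mask)
}

#' mm coordinates of every voxel centre on a grid
#'
#' @param x an `acq_spec` or `volume4d`
#' @return a (n voxels) x 3 matrix, rows in column-major voxel order
#' @export
voxel_coords_mm <- function(x) {
  if (inherits(x, "volume4d")) {
    shape <- dim(x$data)[1:3]; aff <- x$affine
  } else {
    shape <- x$grid_shape; aff <- x$affine
  }
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1,
                               j = seq_len(shape[2]) - 1,
                               k = seq_len(shape[3]) - 1))
  t(aff[1:3, 1:3] %*% t(idx) + aff[1:3, 4])
}
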