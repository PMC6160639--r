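# Quality control: DVARS, ART-style outlier detection, gross-motion
# participant exclusion.

#' Framewise DVARS
#'
#' Root-mean-square over masked voxels of the frame-to-frame signal
#' difference, after rescaling the volume so the modal masked intensity of
#' the mean image is 1000.
#'
#' @param vol a `volume4d` (T >= 2) or T x V matrix
#' @param mask optional logical mask (vector or 3D array)
#' @return numeric vector of length T - 1
#' @export
compute_dvars <- function(vol, mask = NULL) {
  Y <- if (inherits(vol, "volume4d")) vol_matrix(vol) else as.matrix(vol)
  if (inherits(vol, "volume4d") && is.null(mask)) mask <- vol$mask
  if (!is.null(mask)) {
    mask <- as.vector(mask)
    if (!any(mask)) stopf("empty mask")
    Y <- Y[, mask, drop = FALSE]
  }
  if (ncol(Y) == 0) stopf("empty mask")
  if (nrow(Y) < 2) stopf("need at least 2 frames")
  mimg <- colMeans(Y)
  mode_val <- intensity_mode(mimg)
  if (mode_val != 0) Y <- Y * (1000 / mode_val)
  dif <- Y[-1, , drop = FALSE] - Y[-nrow(Y), , drop = FALSE]
  sqrt(rowMeans(dif^2))
}

# modal value of an intensity distribution (density peak; exact value for
# a degenerate distribution)
intensity_mode <- function(x) {
  if (stats::sd(x) == 0) return(x[1])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Framewise displacement
#'
#' Sum of absolute frame-to-frame translation differences plus rotation
#' differences scaled by a sphere radius (Power convention).
#'
#' @param motion T x 6 matrix: 3 translations (mm), 3 rotations (radians)
#' @param rotation_radius_mm head-sphere radius (default 50 mm)
#' @return vector of length T (first frame 0)
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' ART-style motion/intensity outlier frames
#'
#' Flags a frame when framewise displacement exceeds `fd_max` or the
#' global-signal z score exceeds `gz_max` in magnitude (conservative Conn
#' defaults 0.9 mm / 5).
#'
#' @param motion T x 6 motion-parameter matrix
#' @param global_signal optional per-frame global mean signal
#' @param fd_max framewise-displacement threshold (mm)
#' @param gz_max global-signal |z| threshold
#' @return logical vector of length T
#' @export
detect_outliers <- function(motion, global_signal = NULL, fd_max = 0.9,
                            gz_max = 5) {
  fd <- framewise_displacement(motion)
  flags <- fd > fd_max
  if (!is.null(global_signal)) {
    s <- stats::sd(global_signal)
    if (s > 0) {
      z <- (global_signal - mean(global_signal)) / s
      flags <- flags | abs(z) > gz_max
    }
  }
  flags
}

#' Gross-motion participant exclusion
#'
#' Excludes a participant when strictly more than `max_fraction` of frames
#' show any absolute translation strictly above `limit_mm`.
#'
#' @param motion T x 6 motion matrix (or rbind of runs)
#' @param limit_mm translation limit (default 3 mm)
#' @param max_fraction tolerated fraction of violating frames (default 0.25)
#' @return `TRUE` if the participant should be excluded
#' @export
motion_exclusion <- function(motion, limit_mm = 3, max_fraction = 0.25) {
  motion <- as.matrix(motion)
  viol <- apply(abs(motion[, 1:3, drop = FALSE]) > limit_mm, 1, any)
  mean(viol) > max_fraction
}

#' Per-run quality-control report
#'
#' @param vol a `volume4d`
#' @param motion T x 6 motion matrix
#' @param ... thresholds passed to [detect_outliers()]
#' @return a `qc_report` list: `dvars`, `outlier_flags`, `max_abs_motion`,
#'   `excluded`, `reason`
#' @export
qc_report <- function(vol, motion, ...) {
  Y <- vol_matrix(vol)
  gs <- rowMeans(Y[, as.vector(vol$mask), drop = FALSE])
  excl <- motion_exclusion(motion)
  structure(list(dvars = compute_dvars(vol),
                 outlier_flags = detect_outliers(motion, gs, ...),
                 max_abs_motion = apply(abs(motion[, 1:3, drop = FALSE]), 1, max),
                 excluded = excl,
                 reason = if (excl) "gross motion in > 25% of frames" else ""),
            class = "qc_report")
}
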