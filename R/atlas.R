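# Planted activation maps with controlled pairwise overlap.
#
# The "true" activated region of a planted blob is defined as the voxel set
# where the *expected group t statistic* of the analysis pipeline exceeds
# the group height threshold:
#
#   t_exp(x) = sqrt(n) * m(x) / sqrt(tau^2 m(x)^2 + sigma_w^2)
#
# with m the analysis-smoothed amplitude map, tau the between-participant
# amplitude SD (multiplicative), sigma_w the deterministic standard error
# of a participant's smoothed contrast estimate, and n the cohort size.
# A t-threshold detection region is intrinsically a function of the noise
# level, so this large-sample detection set is the only target the noisy
# estimate converges to; overlap targets are solved against it by bisecting
# on blob-centre displacement (monotone in distance).

blob_on_grid <- function(center_mm, radius_mm, acq, soften_fwhm = 3) {
  co <- voxel_coords_mm(acq)
  d2 <- (co[, 1] - center_mm[1])^2 + (co[, 2] - center_mm[2])^2 +
    (co[, 3] - center_mm[3])^2
  ball <- array(as.numeric(d2 <= radius_mm^2), acq$grid_shape)
  if (soften_fwhm > 0)
    ball <- smooth_gaussian(ball, soften_fwhm, acq$voxel_size_mm)
  ball
}

expected_t_set <- function(amp_map, acq, tau, sigma_w, n_group, t_thr,
                           analysis_fwhm) {
  m <- smooth_gaussian(amp_map, analysis_fwhm, acq$voxel_size_mm)
  texp <- sqrt(n_group) * m / sqrt(tau^2 * m^2 + sigma_w^2)
  texp > t_thr
}

set_overlap_fraction <- function(A, B) {
  na <- sum(A); nb <- sum(B)
  if (na == 0 || nb == 0) return(0)
  ni <- sum(A & B)
  mean(c(ni / na, ni / nb))
}

# overlap fraction of two detection sets as a function of centre distance
# det_args_i / det_args_j allow per-map detection parameters
pair_overlap_at_distance <- function(d, dir, acq, radius_mm, amplitude,
                                     det_args_i, det_args_j, center0) {
  c1 <- center0 - dir * d / 2
  c2 <- center0 + dir * d / 2
  A <- do.call(expected_t_set, c(list(
    amp_map = amplitude * blob_on_grid(c1, radius_mm, acq), acq = acq),
    det_args_i))
  B <- do.call(expected_t_set, c(list(
    amp_map = amplitude * blob_on_grid(c2, radius_mm, acq), acq = acq),
    det_args_j))
  set_overlap_fraction(A, B)
}

solve_pair_distance <- function(target, acq, radius_mm, amplitude,
                                det_args_i, det_args_j, center0, r_det) {
  if (target >= 1) return(0)
  if (target <= 0) return(2.4 * r_det)
  dir <- c(1, 0, 0)
  lo <- 0; hi <- 2.4 * r_det
  f <- function(d) pair_overlap_at_distance(d, dir, acq, radius_mm,
                                            amplitude, det_args_i,
                                            det_args_j, center0)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target) < 0.005 || (hi - lo) < 0.05) return(mid)
    if (v > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# embed 4 points with the requested pairwise distances (classical MDS);
# errors when the distance matrix is not Euclidean-realizable in 3D
embed_centers <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values), 1))
    stopf("infeasible overlap-target combination (triangle-type inconsistency): the implied pairwise distances are not realizable in 3D")
  lam <- pmax(e$values[1:3], 0)
  e$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
}

#' Planted per-contrast activation maps with controlled pairwise overlap
#'
#' Generates four smooth spherical blobs (one per executive contrast) whose
#' expected-detection-set pairwise overlap fractions match the target
#' matrix to within +/- 0.03 (checked; refined iteratively). Returns the
#' raw amplitude maps along with the detection sets and realized overlap.
#'
#' @param acq the simulation grid ([acq_spec()])
#' @param targets scalar or symmetric 4x4 matrix of target overlap
#'   fractions in `[0, 1]` (diagonal 1)
#' @param amplitude planted activation amplitude (percent-signal units)
#' @param radius_mm blob radius
#' @param tau between-participant multiplicative amplitude SD
#' @param sigma_w expected participant contrast SE at matched smoothing
#'   (see [expected_contrast_se()])
#' @param n_group cohort size entering the group t
#' @param t_thr group height threshold
#' @param analysis_fwhm smoothing the analysis will apply (mm)
#' @param contrast_names names for the four maps
#' @return an `activation_atlas`: `maps` (named list of 3D arrays),
#'   `detection_sets`, `realized` overlap matrix, `centers_mm`, `targets`,
#'   and the detection parameters
#' @export
make_activation_atlas <- function(acq, targets, amplitude = 1,
                                  radius_mm = 12, tau = 0.5,
                                  sigma_w = 0.59, n_group = 12,
                                  t_thr = 2.7, analysis_fwhm = 6,
                                  contrast_names = TASK_TYPES) {
  if (length(targets) == 1) {
    targets <- matrix(targets, 4, 4); diag(targets) <- 1
  }
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) == 4, ncol(targets) == 4)
  if (any(targets < 0 | targets > 1)) stopf("overlap targets must be in [0,1]")
  if (max(abs(targets - t(targets))) > 1e-12) stopf("targets must be symmetric")
  sigma_w <- rep(sigma_w, length.out = 4)
  det_args <- lapply(1:4, function(i)
    list(tau = tau, sigma_w = sigma_w[i], n_group = n_group,
         t_thr = t_thr, analysis_fwhm = analysis_fwhm))
  center0 <- drop(acq$affine[1:3, 1:3] %*% ((acq$grid_shape - 1) / 2) +
                    acq$affine[1:3, 4])

  # detection radius of a single centred blob
  A0 <- do.call(expected_t_set, c(list(
    amp_map = amplitude * blob_on_grid(center0, radius_mm, acq), acq = acq),
    det_args[[1]]))
  if (sum(A0) == 0)
    stopf("no voxel reaches the expected group threshold; amplitude too small for the configured noise")
  r_det <- (3 * sum(A0) * prod(acq$voxel_size_mm) / (4 * pi))^(1 / 3)

  D <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    D[i, j] <- D[j, i] <- solve_pair_distance(targets[i, j], acq, radius_mm,
                                              amplitude, det_args[[i]],
                                              det_args[[j]], center0, r_det)
  }

  build <- function(D) {
    pts <- embed_centers(D)
    centers <- sweep(pts, 2, -center0) # centre the configuration mid-grid
    maps <- lapply(seq_len(4), function(i)
      amplitude * blob_on_grid(centers[i, ], radius_mm, acq))
    sets <- lapply(seq_len(4), function(i)
      do.call(expected_t_set, c(list(amp_map = maps[[i]], acq = acq),
                                det_args[[i]])))
    realized <- diag(4)
    for (i in 1:3) for (j in (i + 1):4)
      realized[i, j] <- realized[j, i] <-
        set_overlap_fraction(sets[[i]], sets[[j]])
    list(maps = maps, sets = sets, realized = realized, centers = centers)
  }

  res <- build(D)
  for (iter in 1:10) {
    err <- res$realized - targets
    free <- targets > 0 & targets < 1 & upper.tri(targets)
    if (all(abs(err[upper.tri(err)]) <= 0.02)) break
    # increasing distance decreases overlap; damped proportional update
    idx <- which(free, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      D[i, j] <- D[j, i] <- max(0, D[i, j] + 1.2 * r_det * err[i, j])
    }
    res <- build(D)
  }
  if (max(abs((res$realized - targets)[upper.tri(targets)])) > 0.03)
    stopf("could not realize the overlap targets within +/-0.03; max error %.3f",
          max(abs((res$realized - targets)[upper.tri(targets)])))
  # every detection set must live inside the grid
  for (s in res$sets) {
    d <- dim(s)
    if (any(s[c(1, d[1]), , ]) || any(s[, c(1, d[2]), ]) ||
        any(s[, , c(1, d[3])]))
      stopf("planted activation overflows the grid; reduce radius or spread")
  }
  names(res$maps) <- names(res$sets) <- contrast_names
  dimnames(res$realized) <- list(contrast_names, contrast_names)
  structure(list(maps = res$maps, detection_sets = res$sets,
                 realized = res$realized, targets = targets,
                 centers_mm = res$centers, amplitude = amplitude,
                 radius_mm = radius_mm, detection = det_args),
            class = "activation_atlas")
}
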