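# Mass-univariate GLM: dummy removal, spatial smoothing, OLS fitting,
# executive contrasts, group-level one-sample t.

#' Remove initial dummy volumes
#'
#' @param vol a `volume4d`
#' @param n_dummy number of initial frames to drop
#' @param events optional `event_table`; if given, onsets are shifted onto
#'   the post-dummy clock and the shifted table returned as attribute
#'   `"events"`
#' @return the truncated `volume4d`
#' @export
drop_dummies <- function(vol, n_dummy, events = NULL) {
  tdim <- n_frames(vol)
  n_dummy <- as.integer(n_dummy)
  if (n_dummy >= tdim) stopf("n_dummy (%d) >= number of frames (%d)",
                             n_dummy, tdim)
  out <- vol
  if (n_dummy > 0)
    out$data <- vol$data[, , , -seq_len(n_dummy), drop = FALSE]
  if (!is.null(events))
    attr(out, "events") <- shift_events(events, n_dummy, vol$tr_seconds)
  out
}

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# multiply a dense smoothing matrix along one axis of a 3D/4D array
axis_apply <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  a <- M %*% matrix(a, d[axis])
  a <- array(a, d[perm])
  aperm(a, order(perm))
}

smoothing_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1) / 2
  M <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    ok <- idx + off >= 1 & idx + off <= n
    M[cbind(idx[ok], (idx + off)[ok])] <- kernel[off + r + 1]
  }
  # renormalize truncated rows so constants pass through unchanged
  M / rowSums(M)
}

#' Spatial Gaussian smoothing
#'
#' Separable per-frame 3D convolution with a Gaussian of the given full
#' width at half maximum; the kernel is normalized to unit sum per axis, so
#' interior mass is conserved (zero padding at the grid boundary).
#'
#' @param vol a `volume4d` or 3D array
#' @param fwhm_mm kernel FWHM in mm (0 returns the input unchanged)
#' @param voxel_size_mm voxel size per axis (taken from the affine for a
#'   `volume4d`)
#' @return smoothed object of the same type
#' @export
smooth_gaussian <- function(vol, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  if (fwhm_mm < 0) stopf("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  isvol <- inherits(vol, "volume4d")
  if (isvol) {
    voxel_size_mm <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
    arr <- vol$data
  } else arr <- vol
  d <- dim(arr)
  for (ax in 1:3) {
    M <- smoothing_matrix(d[ax], gaussian_kernel_1d(fwhm_mm,
                                                    voxel_size_mm[ax]))
    arr <- axis_apply(arr, M, ax)
  }
  if (isvol) { vol$data <- arr; vol } else arr
}

#' Fit the mass-univariate GLM by ordinary least squares
#'
#' @param vol a `volume4d` or a T x V response matrix
#' @param X a `design_matrix` (T x P, full column rank)
#' @return a `glm_fit`: `betas` (P x V), `sigma2` (unbiased residual
#'   variance per voxel), `df` = T - rank(X), `xtx_inv`, plus the grid
#'   metadata when `vol` was a `volume4d`
#' @export
fit_glm_ols <- function(vol, X) {
  Y <- if (inherits(vol, "volume4d")) vol_matrix(vol) else as.matrix(vol)
  X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qx, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - qx$rank
  sigma2 <- colSums(resid^2) / df
  o <- order(qx$pivot)
  xtx_inv <- chol2inv(qr.R(qx))[o, o, drop = FALSE]
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, df = df, xtx_inv = xtx_inv,
                 colnames = colnames(X),
                 template = if (inherits(vol, "volume4d")) vol else NULL),
            class = "glm_fit")
}

#' Executive contrast specifications
#'
#' Builds weight vectors over the design columns for the four executive
#' contrasts: divided vs distracted attention (DivA), distracted vs
#' undistracted attention (DistrA), 1-/2-back vs 0-back on nonswitch trials
#' (WM), and post- vs pre-switch trials of the 1-/2-back levels (ModSwi).
#' Each side averages its member columns with equal weight, so difference
#' contrasts sum to zero.
#'
#' @param X a `design_matrix`
#' @param which_tasks subset of `c("DivA","DistrA","WM","ModSwi")`
#' @return named list of weight vectors (length `ncol(X)`)
#' @export
make_executive_contrasts <- function(X, which_tasks = TASK_TYPES) {
  cn <- colnames(X)
  att_cols <- function(conds) as.vector(outer(
    paste0("cond_", conds), c("_cong", "_incong"), paste0))
  nb_cols <- function(levels, sw) as.vector(outer(
    paste0("cond_", levels, "_", sw), c("_visual", "_auditory"), paste0))
  side <- function(members) which(cn %in% members)
  defs <- list(
    DivA   = list(plus = att_cols("divided"),
                  minus = att_cols(DISTRACTED_CONDITIONS)),
    DistrA = list(plus = att_cols(DISTRACTED_CONDITIONS),
                  minus = att_cols(UNDISTRACTED_CONDITIONS)),
    WM     = list(plus = nb_cols(c("nback1", "nback2"), "non"),
                  minus = nb_cols("nback0", "non")),
    ModSwi = list(plus = nb_cols(c("nback1", "nback2"), "post"),
                  minus = nb_cols(c("nback1", "nback2"), "pre")))
  out <- list()
  for (nm in which_tasks) {
    d <- defs[[nm]]
    p <- side(d$plus); m <- side(d$minus)
    if (length(p) == 0 || length(m) == 0)
      stopf("cannot build contrast %s: missing member column(s)", nm)
    w <- numeric(length(cn)); names(w) <- cn
    w[p] <- 1 / length(p)
    w[m] <- -1 / length(m)
    out[[nm]] <- w
  }
  out
}

#' Contrast map from a fitted GLM
#'
#' @param fit a `glm_fit`
#' @param w contrast weight vector (length P)
#' @return a `contrast_map` with 3D `effect`, `t` and `se` arrays (or plain
#'   vectors when the fit came from a matrix), `df`, and `var_unit` =
#'   \eqn{w' (X'X)^{-1} w}
#' @export
contrast_map <- function(fit, w) {
  stopifnot(length(w) == nrow(fit$betas))
  eff <- drop(crossprod(w, fit$betas))
  vu <- drop(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(vu * fit$sigma2)
  tval <- ifelse(se > 0, eff / se, 0)
  shape3 <- function(v) {
    if (is.null(fit$template)) v
    else array(v, dim(fit$template$data)[1:3])
  }
  structure(list(effect = shape3(eff), t = shape3(tval), se = shape3(se),
                 df = fit$df, var_unit = vu,
                 mask = if (!is.null(fit$template)) fit$template$mask else NULL,
                 level = "participant"),
            class = "contrast_map")
}

#' Group-level one-sample t map
#'
#' Voxelwise one-sample t of participant contrast effects against zero
#' (df = n - 1). Voxels with zero between-participant variance and a
#' nonzero mean are capped at +/- `cap` with a warning.
#'
#' @param effects list of 3D participant effect arrays (same grid)
#' @param cap sentinel for infinite t
#' @return a `contrast_map` with `level = "group"`
#' @export
group_level_t <- function(effects, cap = 1e6) {
  n <- length(effects)
  if (n < 2) stopf("need at least 2 participant maps")
  d1 <- dim(effects[[1]])
  for (e in effects) if (!identical(dim(e), d1)) stopf("grid mismatch between participant maps")
  Y <- vapply(effects, as.vector, numeric(prod(d1)))
  m <- rowMeans(Y)
  sd <- sqrt(pmax(rowSums((Y - m)^2) / (n - 1), 0))
  tval <- numeric(length(m))
  ok <- sd > 0
  tval[ok] <- m[ok] / (sd[ok] / sqrt(n))
  zv <- !ok & m != 0
  if (any(zv)) {
    warnf("%d voxel(s) with zero between-participant variance; t capped", sum(zv))
    tval[zv] <- sign(m[zv]) * cap
  }
  structure(list(effect = array(m, d1), t = array(tval, d1),
                 se = array(sd / sqrt(n), d1), df = n - 1, level = "group"),
            class = "contrast_map")
}

# deterministic per-unit-sigma noise multiplier of a smoothing kernel
# (the factor by which iid voxel noise SD shrinks under 3D smoothing)
kernel_noise_factor <- function(fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  if (fwhm_mm == 0) return(1)
  prod(vapply(voxel_size_mm, function(v)
    sqrt(sum(gaussian_kernel_1d(fwhm_mm, v)^2)), numeric(1)))
}

#' Expected standard error of a participant contrast estimate
#'
#' Deterministic design analysis: for temporal noise SD `sigma`, analysis
#' smoothing `fwhm_mm`, and run designs `Xs` with contrast weights `ws`
#' (one per run), the SE of the run-averaged contrast estimate at a voxel
#' is `sigma * kernel_noise_factor * sqrt(mean(w'(X'X)^-1 w) / R)`.
#'
#' @param Xs list of design matrices
#' @param ws list of matching contrast weight vectors
#' @param sigma temporal noise SD
#' @param fwhm_mm analysis smoothing FWHM
#' @param voxel_size_mm voxel size
#' @return expected SE (scalar)
#' @export
expected_contrast_se <- function(Xs, ws, sigma, fwhm_mm = 6,
                                 voxel_size_mm = c(3, 3, 3)) {
  v <- mapply(function(X, w) {
    xtx_inv <- chol2inv(chol(crossprod(as.matrix(X))))
    drop(t(w) %*% xtx_inv %*% w)
  }, Xs, ws)
  sigma * kernel_noise_factor(fwhm_mm, voxel_size_mm) *
    sqrt(mean(v) / length(Xs))
}
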