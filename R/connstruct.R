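# Planted cross-task connectivity structure.
#
# The four task correlation matrices are assembled from exactly
# orthonormalized components in connection (off-diagonal entry) space:
#
#   g_k = mu * 1 + L * ( sqrt(s) Q0 + sqrt(1-s) E_k ) + b_k * 1
#
# with Q0, E_1..E_4 orthonormal and centred. Because Pearson correlation
# centres each vector, the uniform task offsets b_k and the mean level mu
# drop out and the pairwise similarity of off-diagonal entries equals s
# *exactly*, for any offset magnitude. The offsets model a global
# task-level modulation of coupling (tasks differ in overall coupling
# strength); their magnitude is constant in s (vanishing only at the
# degenerate s = 1, where the matrices must be identical). They are what
# makes connection-by-connection similarity — and hence the spread of the
# MDS embedding — change with s: the connection-specific task deviations
# shrink as s grows while the shared modulation does not, so the 28
# connections co-vary more and more across tasks.

#' Planted per-task ROI correlation matrices with controlled similarity
#'
#' Generates one positive-definite `n_rois` x `n_rois` correlation matrix
#' per task type such that every unordered pair of matrices has Pearson
#' correlation of off-diagonal entries equal to `s` (checked to +/- 0.05,
#' exact up to clip-free construction).
#'
#' @param s target cross-task similarity in `[0, 1]`
#' @param n_rois number of ROIs (>= 2; default 8 gives 28 connections)
#' @param seed RNG seed
#' @param mu mean connectivity level (r units)
#' @param sd_entry SD of the planted connectivity pattern across
#'   connections
#' @param tau_mod strength of the global task-level coupling modulation
#' @param task_names names for the four matrices
#' @param min_eig minimum eigenvalue enforced by uniform shrinkage
#' @return a `connectivity_structure`: `matrices` (named list), `realized`
#'   4x4 similarity matrix, `s`, and the construction parameters
#' @export
make_connectivity_structure <- function(s, n_rois = 8L, seed = 1L,
                                        mu = 0.30, sd_entry = 0.15,
                                        tau_mod = 0.8,
                                        task_names = TASK_TYPES,
                                        min_eig = 0.02) {
  if (s < 0 || s > 1) stopf("s must be in [0, 1]")
  if (n_rois < 2) stopf("n_rois must be >= 2")
  m <- n_rois * (n_rois - 1) / 2
  if (m < 6) stopf("need at least 4 ROIs for orthonormal task components")
  with_rng(child_seed(seed, 77L), {
    raw <- matrix(stats::rnorm(m * 5), m, 5)
    raw <- sweep(raw, 2, colMeans(raw)) # centred
    Q <- qr.Q(qr(raw))                  # orthonormal, still centred
    Q0 <- Q[, 1]; E <- Q[, 2:5, drop = FALSE]
    L <- sd_entry * sqrt(m)
    B <- if (s >= 1) 0 else tau_mod * L / sqrt(m)
    a_k <- c(1, 1, -1, -1) # unit-RMS, zero-mean task modulation pattern
    g <- sapply(1:4, function(k)
      mu + L * (sqrt(s) * Q0 + sqrt(1 - s) * E[, k]) + B * a_k[k])
    # keep entries inside (-0.95, 0.95) by a common rescale of the
    # centred parts (preserves pairwise Pearson similarity exactly)
    dev <- sweep(g, 2, rep(mu, 4))
    mx <- max(abs(mu + dev))
    if (mx > 0.95) g <- mu + dev * (0.95 - abs(mu)) / (mx - abs(mu))

    mats <- lapply(1:4, function(k) {
      C <- diag(n_rois)
      C[upper.tri(C)] <- 0
      # fill in the same (row-major upper triangle) order used throughout
      idx <- which(upper.tri(C), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      C[idx] <- g[, k]
      C <- C + t(C); diag(C) <- 1
      ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min < min_eig) {
        lambda <- (min_eig - ev_min) / (1 - min_eig)
        C <- (C + lambda * diag(n_rois)) / (1 + lambda)
      }
      C
    })
    names(mats) <- task_names
    realized <- diag(4)
    for (i in 1:3) for (j in (i + 1):4)
      realized[i, j] <- realized[j, i] <-
        stats::cor(mats[[i]][upper.tri(mats[[i]])],
                   mats[[j]][upper.tri(mats[[j]])])
    dimnames(realized) <- list(task_names, task_names)
    if (s < 1 && max(abs(realized[upper.tri(realized)] - s)) > 0.05)
      stopf("construction check failed: realized similarity off target by %.3f",
            max(abs(realized[upper.tri(realized)] - s)))
    structure(list(matrices = mats, realized = realized, s = s,
                   n_rois = as.integer(n_rois), mu = mu,
                   sd_entry = sd_entry, tau_mod = tau_mod),
              class = "connectivity_structure")
  })
}
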