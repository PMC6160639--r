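# Representational similarity of connectivity patterns: task-by-task
# similarity matrices, connection-by-connection similarity, permutation
# tests, classical MDS, and labelled distance tables.

#' Cross-task similarity of one participant's connectivity vectors
#'
#' Pearson correlation over the 28 Fisher-z values for each unordered task
#' pair.
#'
#' @param vectors named list of 4 `connectivity_vector`s (names = tasks)
#' @return 4x4 symmetric correlation matrix, diagonal 1
#' @export
participant_task_similarity <- function(vectors) {
  if (is.null(names(vectors)) || !setequal(names(vectors), TASK_TYPES))
    stopf("need the four task vectors: %s", paste(TASK_TYPES, collapse = ", "))
  vectors <- vectors[TASK_TYPES]
  len <- unique(vapply(vectors, length, integer(1)))
  if (length(len) != 1) stopf("connectivity vectors differ in length")
  M <- stats::cor(do.call(cbind, lapply(vectors, as.numeric)))
  dimnames(M) <- list(TASK_TYPES, TASK_TYPES)
  M
}

#' Connection-by-connection similarity across tasks
#'
#' Entry (i, j) is the Pearson correlation between connection i's and
#' connection j's (cohort-averaged) z values across the four task types.
#' Zero-variance connections produce 0 entries with a warning.
#'
#' @param z_table connections x tasks numeric matrix (e.g. 28 x 4)
#' @return symmetric similarity matrix with unit diagonal
#' @export
cohort_connection_similarity <- function(z_table) {
  z_table <- as.matrix(z_table)
  n <- nrow(z_table)
  sds <- apply(z_table, 1, stats::sd)
  M <- matrix(0, n, n, dimnames = list(rownames(z_table), rownames(z_table)))
  ok <- sds > 0
  if (any(!ok)) warnf("%d zero-variance connection(s); entries set to 0",
                      sum(!ok))
  if (any(ok)) M[ok, ok] <- stats::cor(t(z_table[ok, , drop = FALSE]))
  diag(M) <- 1
  M
}

#' Compare two similarity matrices
#'
#' Reports the Pearson correlation `r` over upper triangles plus two
#' permutation p values: `p_correlation` tests whether the matrices share
#' structure (null: node labels of `b` randomly permuted) and
#' `p_difference` tests whether they differ (paired sign-flip null on the
#' entrywise differences of the upper triangles, two-sided on the mean
#' difference).
#'
#' @param a,b square similarity matrices of equal dimension
#' @param n_perm permutation draws (warning below 100)
#' @param seed RNG seed
#' @return list with `r`, `p_correlation`, `p_difference`, `n_perm`
#' @export
matrix_similarity_test <- function(a, b, n_perm = 999L, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("dimension mismatch")
  if (n_perm < 100) warnf("n_perm < 100 gives a coarse p value")
  ua <- upper_tri_vec(a); ub <- upper_tri_vec(b)
  r_obs <- stats::cor(ua, ub)
  d <- ua - ub
  t_obs <- abs(mean(d))
  n <- nrow(a)
  with_rng(seed, {
    r_null <- numeric(n_perm); t_null <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      r_null[k] <- stats::cor(ua, upper_tri_vec(b[p, p]))
      t_null[k] <- abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
    }
    list(r = r_obs,
         p_correlation = (1 + sum(r_null >= r_obs)) / (n_perm + 1),
         p_difference = (1 + sum(t_null >= t_obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm))
  })
}

#' Classical (Torgerson) multidimensional scaling of a similarity matrix
#'
#' Converts similarity to dissimilarity (`1 - r` by default), double
#' centres `-d^2/2`, and embeds on the top eigenvectors scaled by the
#' square root of their eigenvalues. Negative eigenvalue mass is truncated
#' with a message.
#'
#' @param S similarity matrix (diagonal 1), or a dissimilarity matrix when
#'   `is_distance = TRUE`
#' @param dim embedding dimension (default 2; must be <= n - 1)
#' @param transform `"one_minus_r"` (default) or `"sqrt_two_one_minus_r"`
#' @param is_distance treat `S` as a distance matrix directly
#' @return list: `points` (n x dim), `eigenvalues` (sorted descending),
#'   `negative_mass`
#' @export
mds_embed <- function(S, dim = 2L, transform = c("one_minus_r",
                                                 "sqrt_two_one_minus_r"),
                      is_distance = FALSE) {
  transform <- match.arg(transform)
  S <- as.matrix(S)
  n <- nrow(S)
  if (dim < 1 || dim > n - 1) stopf("dim must be in [1, n-1]")
  D <- if (is_distance) S
       else if (transform == "one_minus_r") 1 - S
       else sqrt(2 * (1 - S))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  neg <- sum(pmin(ev, 0))
  if (neg < -1e-8 * max(abs(ev)))
    message(sprintf("mds_embed: truncating negative eigenvalue mass %.3g",
                    neg))
  lam <- pmax(ev[seq_len(dim)], 0)
  pts <- e$vectors[, seq_len(dim), drop = FALSE] %*% diag(sqrt(lam), dim)
  rownames(pts) <- rownames(S)
  list(points = pts, eigenvalues = ev, negative_mass = neg)
}

#' Hemisphere and range labels for ROI-pair connections
#'
#' Short-range connections are within-hemisphere SPL-Prc or MFG-SMA pairs;
#' everything else is long range. Hemisphere type is within-left,
#' within-right, or inter-hemispheric.
#'
#' @param rois a `roi_set` with region classes
#' @return data frame with one row per unordered ROI pair (order matches
#'   [taskwise_connectivity()]): `connection`, `roi_i`, `roi_j`,
#'   `hemisphere_type`, `range_type`
#' @export
connection_labels <- function(rois) {
  n <- length(rois$name)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hi <- rois$hemisphere[i]; hj <- rois$hemisphere[j]
    hemi <- if (hi == hj) {
      if (hi == "L") "within-left" else "within-right"
    } else "inter-hemispheric"
    regs <- sort(c(rois$region[i], rois$region[j]))
    short <- hi == hj && (identical(regs, c("Prc", "SPL")) ||
                            identical(regs, c("MFG", "SMA")))
    out[[length(out) + 1]] <- data.frame(
      connection = paste(rois$name[i], rois$name[j], sep = "-"),
      roi_i = rois$name[i], roi_j = rois$name[j],
      hemisphere_type = hemi,
      range_type = if (short) "short" else "long",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Labelled Euclidean distance table of an embedding
#'
#' All pairwise distances between embedded connection nodes, annotated
#' with both endpoints' hemisphere and range labels. A pair-level type is
#' assigned only when both endpoints share it; otherwise `"mixed"`.
#'
#' @param coords n x dim embedding (rows = connection nodes)
#' @param labels data frame from [connection_labels()] (row order matching
#'   `coords`)
#' @param cohort cohort label attached to every row
#' @return data frame with `choose(n, 2)` rows
#' @export
distance_table <- function(coords, labels = NULL, cohort = NA_character_) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    hi <- if (!is.null(labels)) labels$hemisphere_type[i] else NA_character_
    hj <- if (!is.null(labels)) labels$hemisphere_type[j] else NA_character_
    ri <- if (!is.null(labels)) labels$range_type[i] else NA_character_
    rj <- if (!is.null(labels)) labels$range_type[j] else NA_character_
    pair_type <- function(a, b) {
      if (is.na(a) || is.na(b)) NA_character_
      else if (a == b) a else "mixed"
    }
    rows[[length(rows) + 1]] <- data.frame(
      node_i = i, node_j = j, distance = d,
      hemisphere_i = hi, hemisphere_j = hj,
      hemisphere_type = pair_type(hi, hj),
      range_i = ri, range_j = rj,
      range_type = pair_type(ri, rj),
      cohort = cohort, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Participant-permutation test for cohort differences in connectivity
#' pattern similarity
#'
#' The observed statistic is the structural disagreement
#' `1 - cor(upper(S_A), upper(S_B))` between the two cohorts'
#' connection-similarity matrices (each built from the cohort-averaged
#' z table). The null distribution shuffles participants between the two
#' cohorts and recomputes both matrices.
#'
#' @param zA,zB participant z tables: arrays / lists of connections x tasks
#'   matrices, or 3D arrays (connections x tasks x participants)
#' @param n_perm permutation draws
#' @param seed RNG seed
#' @return list with `statistic`, `p`, `n_perm`
#' @export
cohort_difference_test <- function(zA, zB, n_perm = 999L, seed = 1L) {
  as_arr <- function(z) {
    if (is.array(z) && length(dim(z)) == 3) z
    else array(unlist(z), c(dim(z[[1]]), length(z)))
  }
  A <- as_arr(zA); B <- as_arr(zB)
  nA <- dim(A)[3]; nB <- dim(B)[3]
  all_z <- array(c(A, B), c(dim(A)[1], dim(A)[2], nA + nB))
  stat <- function(idxA) {
    SA <- suppressWarnings(cohort_connection_similarity(
      apply(all_z[, , idxA, drop = FALSE], c(1, 2), mean)))
    SB <- suppressWarnings(cohort_connection_similarity(
      apply(all_z[, , -idxA, drop = FALSE], c(1, 2), mean)))
    1 - stats::cor(upper_tri_vec(SA), upper_tri_vec(SB))
  }
  d_obs <- stat(seq_len(nA))
  with_rng(seed, {
    d_null <- vapply(seq_len(n_perm), function(k)
      stat(sample.int(nA + nB, nA)), numeric(1))
    list(statistic = d_obs,
         p = (1 + sum(d_null >= d_obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm))
  })
}
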