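# Independent oracles used across test files.

# connected components by iterative label minimization (independent of the
# package's BFS implementation)
label_oracle <- function(bin, connectivity) {
  d <- dim(bin)
  lab <- array(0, d)
  lab[bin] <- which(bin)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[switch(as.character(connectivity),
                      "6" = rowSums(abs(offs)) == 1,
                      "18" = rowSums(abs(offs)) <= 2,
                      "26" = rep(TRUE, nrow(offs))), , drop = FALSE]
  repeat {
    new <- lab
    for (o in seq_len(nrow(offs))) {
      dx <- offs[o, ]
      sx <- max(1, 1 + dx[1]):min(d[1], d[1] + dx[1])
      sy <- max(1, 1 + dx[2]):min(d[2], d[2] + dx[2])
      sz <- max(1, 1 + dx[3]):min(d[3], d[3] + dx[3])
      tx <- max(1, 1 - dx[1]):min(d[1], d[1] - dx[1])
      ty <- max(1, 1 - dx[2]):min(d[2], d[2] - dx[2])
      tz <- max(1, 1 - dx[3]):min(d[3], d[3] - dx[3])
      src <- lab[sx, sy, sz]
      cur <- new[tx, ty, tz]
      sel <- cur > 0 & src > 0 & src < cur
      cur[sel] <- src[sel]
      new[tx, ty, tz] <- cur
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# partitions induced by two labelings are identical
same_partition <- function(a, b, bin) {
  pa <- split(which(bin), a[bin])
  pb <- split(which(bin), b[bin])
  setequal(lapply(pa, sort), lapply(pb, sort))
}

# Procrustes residual after optimal translation + orthogonal alignment
# (Kabsch), no scaling
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sum((Y %*% R - X)^2)
}

# tiny nback-like acquisition for cheap forward-model tests
tiny_acq <- function(n_volumes = 155L)
  acq_spec(n_volumes = n_volumes, grid_shape = c(10L, 10L, 10L))

# quick seeded GLM toy problem: returns X, Y, oracle betas/t
glm_toy <- function(seed = 42, tframes = 40L, nvox = 5L, p = 4L) {
  set.seed(seed)
  X <- cbind(intercept = 1, matrix(rnorm(tframes * (p - 1)), tframes))
  colnames(X)[2:p] <- paste0("x", 1:(p - 1))
  B <- matrix(rnorm(p * nvox), p)
  Y <- X %*% B + matrix(rnorm(tframes * nvox, sd = 0.5), tframes)
  xtx_inv <- solve(t(X) %*% X)
  bh <- xtx_inv %*% t(X) %*% Y
  res <- Y - X %*% bh
  s2 <- colSums(res^2) / (tframes - p)
  tmat <- bh / sqrt(outer(diag(xtx_inv), s2))
  list(X = X, Y = Y, betas = bh, t = tmat, df = tframes - p)
}
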