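test_that("canonical HRF has the standard shape", {
  expect_equal(canonical_hrf(0), 0)
  grid <- seq(0, 30, by = 0.1)
  h <- canonical_hrf(grid)
  expect_gt(grid[which.max(h)], 4)
  expect_lt(grid[which.max(h)], 6)
  expect_equal(max(h), 1, tolerance = 1e-3)     # unit peak
  expect_lt(abs(canonical_hrf(32)), 1e-2)       # returned to baseline
  expect_error(canonical_hrf(-1))
})

test_that("DCT drift column count matches the closed form", {
  # floor(2 * duration / cutoff); 545 s at 1/128 Hz -> 8 columns
  expect_equal(execonn:::dct_column_count(545, 128), 8)
  for (dur in c(100, 377.5, 545, 900))
    for (cut in c(64, 128, 200))
      expect_equal(execonn:::dct_column_count(dur, cut), floor(2 * dur / cut))
  ev <- shift_events(build_attention_schedule(1, seed = 1), 4, 2.5)
  X <- suppressWarnings(build_design_matrix(ev, attention_acq()))
  expect_equal(sum(grepl("^dct", colnames(X))), 8)
})

test_that("empty events give a nuisance-only design with intercept", {
  acq <- acq_spec(n_volumes = 104L)
  empty <- build_attention_schedule(1, seed = 1)[0, ]
  X <- build_design_matrix(empty, acq)
  expect_true("intercept" %in% colnames(X))
  expect_false(any(grepl("^cond_", colnames(X))))
  expect_equal(nrow(X), 100)
})

test_that("a block regressor peaks ~5 s after block onset", {
  acq <- acq_spec(n_volumes = 124L, n_dummy = 0L, tr_seconds = 1)
  ev <- data.frame(onset = 20, duration = 30, task = "attention",
                   condition = "divided", modality = "both",
                   switch_flag = "n/a", congruent = TRUE, block_id = 1L,
                   response_duration = 0, correct = NA, run = 1L)
  X <- suppressWarnings(build_design_matrix(ev, acq))
  reg <- X[, "cond_divided_cong"]
  # a 30 s boxcar convolved with the HRF plateaus; the rising edge should
  # reach 90% of its max about 5-10 s after onset
  t90 <- which(reg > 0.9 * max(reg))[1] - 1
  expect_gt(t90, 23); expect_lt(t90, 33)
})

test_that("absent condition classes are omitted with a warning", {
  ev <- shift_events(build_nback_schedule(1, seed = 2), 4, 2.5)
  ev <- ev[!(ev$condition == "nback2" & ev$switch_flag == "pre_switch" &
               ev$modality == "visual"), ]
  expect_warning(X <- build_design_matrix(ev, nback_acq()),
                 "omitting absent")
  expect_false("cond_nback2_pre_visual" %in% colnames(X))
})

test_that("OLS fit matches the normal-equations oracle", {
  toy <- glm_toy(seed = 42)
  fit <- fit_glm_ols(toy$Y, toy$X)
  expect_lt(max(abs(fit$betas - toy$betas)), 1e-8)
  for (j in seq_len(ncol(toy$X))) {
    w <- numeric(ncol(toy$X)); w[j] <- 1
    cm <- contrast_map(fit, w)
    expect_lt(max(abs(cm$t - toy$t[j, ])), 1e-8)
  }
  expect_equal(fit$df, toy$df)
})

test_that("noiseless data are interpolated exactly and fits are linear", {
  set.seed(3)
  X <- cbind(1, rnorm(30), rnorm(30)); colnames(X) <- c("i", "a", "b")
  B <- matrix(c(2, -1, 0.5, 4, 0, 1), 3)
  fit <- fit_glm_ols(X %*% B, X)
  expect_lt(max(abs(fit$betas - B)), 1e-10)
  Y <- X %*% B + matrix(rnorm(60), 30)
  f1 <- fit_glm_ols(Y, X); f2 <- fit_glm_ols(3.5 * Y, X)
  expect_equal(f2$betas, 3.5 * f1$betas, tolerance = 1e-12)
})

test_that("rank-deficient designs error and name collinear columns", {
  X <- cbind(a = rep(1, 20), b = rnorm(20))
  X <- cbind(X, dup = X[, "b"])
  expect_error(fit_glm_ols(matrix(rnorm(20)), X), "dup|b")
})

test_that("executive contrasts have the published structure", {
  evA <- shift_events(build_attention_schedule(1, seed = 1), 4, 2.5)
  XA <- suppressWarnings(build_design_matrix(evA, attention_acq()))
  wsA <- make_executive_contrasts(XA, c("DivA", "DistrA"))
  for (w in wsA) expect_lt(abs(sum(w)), 1e-12)
  expect_true(all(wsA$DivA[grep("divided", names(wsA$DivA))] > 0))
  expect_true(all(wsA$DistrA[grep("disvis|disaud|dismusic",
                                  names(wsA$DistrA))] > 0))
  # undistracted columns are negative in DistrA and untouched by DivA
  und <- grep("^cond_att_(aud|vis)_(cong|incong)$", names(wsA$DistrA))
  expect_true(all(wsA$DistrA[und] < 0))
  expect_true(all(wsA$DivA[und] == 0))
  evN <- shift_events(build_nback_schedule(1, seed = 1), 4, 2.5)
  XN <- suppressWarnings(build_design_matrix(evN, nback_acq()))
  wsN <- make_executive_contrasts(XN, c("WM", "ModSwi"))
  # WM excludes every switch-flagged column
  sw <- grep("_(pre|post)_", names(wsN$WM))
  expect_true(all(wsN$WM[sw] == 0))
  expect_error(make_executive_contrasts(XN, "DivA"), "DivA")
})

test_that("group-level t matches the direct formula and caps zero variance", {
  set.seed(8)
  maps <- lapply(1:10, function(i) array(rnorm(27), c(3, 3, 3)))
  g <- group_level_t(maps)
  Y <- sapply(maps, as.vector)
  m <- rowMeans(Y); s <- apply(Y, 1, sd)
  expect_lt(max(abs(as.vector(g$t) - m / (s / sqrt(10)))), 1e-10)
  same <- lapply(1:4, function(i) array(1, c(2, 2, 2)))
  expect_warning(gc2 <- group_level_t(same), "capped")
  expect_true(all(gc2$t == 1e6))
  alt <- lapply(1:4, function(i) array(c(-1, 1)[i %% 2 + 1], c(2, 2, 2)))
  expect_true(all(group_level_t(alt)$t == 0))
  expect_error(group_level_t(list(array(0, c(2, 2, 2)),
                                  array(0, c(3, 2, 2)))), "mismatch")
})

test_that("dummy removal shifts onsets and validates bounds", {
  vol <- volume4d(array(rnorm(2 * 2 * 2 * 10), c(2, 2, 2, 10)), diag(4), 2.5)
  ev <- data.frame(onset = 10, duration = 2.5, task = "attention",
                   condition = "divided", modality = "both",
                   switch_flag = "n/a", congruent = TRUE, block_id = 1L,
                   response_duration = 1.5, correct = NA, run = 1L)
  out <- drop_dummies(vol, 4, events = ev)
  expect_equal(dim(out$data)[4], 6)
  expect_equal(attr(out, "events")$onset, 0)
  expect_identical(drop_dummies(vol, 0)$data, vol$data)
  expect_error(drop_dummies(vol, 10), ">=")
})

test_that("smoothing conserves interior mass and matches the separable oracle", {
  arr <- array(0, c(15, 15, 15)); arr[8, 8, 8] <- 1
  sm <- smooth_gaussian(arr, 6, c(3, 3, 3))
  expect_lt(abs(sum(sm) - 1), 1e-6)
  # separable-product oracle at a probe set of voxels
  k <- execonn:::gaussian_kernel_1d(6, 3)
  r <- (length(k) - 1) / 2
  for (probe in list(c(8, 8, 8), c(7, 9, 8), c(10, 8, 6))) {
    off <- probe - 8
    expected <- if (all(abs(off) <= r))
      prod(k[off + r + 1]) else 0
    expect_equal(sm[probe[1], probe[2], probe[3]], expected,
                 tolerance = 1e-12)
  }
  expect_identical(smooth_gaussian(arr, 0), arr)
  cst <- array(3.2, c(6, 6, 6))
  expect_equal(smooth_gaussian(cst, 6, c(3, 3, 3)), cst, tolerance = 1e-12)
  expect_error(smooth_gaussian(arr, -1), ">=")
})
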