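test_that("DVARS is zero for constant volumes and localizes spikes", {
  vol <- volume4d(array(500, c(4, 4, 4, 12)), diag(4), 2.5)
  dv <- compute_dvars(vol)
  expect_length(dv, 11)
  expect_true(all(dv == 0))
  arr <- array(100, c(4, 4, 4, 12)); arr[, , , 7] <- 140
  dv2 <- compute_dvars(volume4d(arr, diag(4), 2.5))
  expect_setequal(which(dv2 == max(dv2)), c(6, 7))  # into and out of frame 7
  expect_error(compute_dvars(vol, mask = array(FALSE, c(4, 4, 4))),
               "empty mask")
})

test_that("DVARS of white noise matches the analytic prediction", {
  set.seed(21)
  n <- 80; v <- 4000; sigma <- 5; baseline <- 200
  Y <- baseline + matrix(rnorm(n * v, 0, sigma), n)
  dv <- compute_dvars(Y)
  scale_f <- 1000 / execonn:::intensity_mode(colMeans(Y))
  pred <- sqrt(2) * sigma * scale_f
  expect_lt(abs(mean(dv) - pred) / pred, 0.05)
})

test_that("outlier detection follows the FD formula", {
  motion <- matrix(0, 50, 6)
  expect_false(any(detect_outliers(motion, rep(1, 50))))
  motion[20, 1] <- 2   # 2 mm translation jump (in and out)
  fd <- framewise_displacement(motion)
  expect_equal(fd[20], 2); expect_equal(fd[21], 2)
  flags <- detect_outliers(motion)
  expect_true(flags[20] && flags[21])
  expect_false(any(detect_outliers(motion, fd_max = Inf, gz_max = Inf)))
  # rotations scale by the 50 mm sphere radius
  rot <- matrix(0, 10, 6); rot[5, 4] <- 0.02
  expect_equal(framewise_displacement(rot)[5], 1)
})

test_that("motion exclusion is strict on both bounds", {
  m <- matrix(0, 100, 6)
  m[1:25, 1] <- 3.5   # exactly 25% violating
  expect_false(motion_exclusion(m))
  m[26, 1] <- 3.5     # 26%
  expect_true(motion_exclusion(m))
  expect_false(motion_exclusion(matrix(0, 100, 6)))
  m2 <- matrix(0, 100, 6); m2[1:30, 2] <- 3  # |t| exactly 3 is tolerated
  expect_false(motion_exclusion(m2))
})

test_that("ROI extraction matches a brute-force membership check", {
  acq <- acq_spec(n_volumes = 20L, grid_shape = c(12L, 12L, 12L))
  rois <- roi_set(c("rA", "lA"), rbind(c(7, 0, 0), c(-7, 0, 0)),
                  radius_mm = 7)
  set.seed(4)
  vol <- volume4d(array(rnorm(12^3 * 20), c(12, 12, 12, 20)), acq$affine,
                  2.5)
  ts <- extract_roi_timecourses(vol, rois)
  co <- voxel_coords_mm(vol)
  Y <- execonn:::vol_matrix(vol)
  for (i in 1:2) {
    inside <- which(sqrt(colSums((t(co) - rois$centers_mm[i, ])^2)) <= 7)
    expect_equal(ts[, i], rowMeans(Y[, inside, drop = FALSE]))
  }
  # single-voxel ROI returns that voxel's series (centre on a voxel)
  tiny <- roi_set("pt", matrix(c(1.5, 1.5, 1.5), 1), radius_mm = 1)
  idx <- which(co[, 1] == 1.5 & co[, 2] == 1.5 & co[, 3] == 1.5)
  expect_equal(as.numeric(extract_roi_timecourses(vol, tiny)),
               Y[, idx])
  far <- roi_set("out", matrix(c(500, 0, 0), 1), radius_mm = 2)
  expect_error(extract_roi_timecourses(vol, far), "out")
})

test_that("confound regression residualizes exactly", {
  set.seed(6)
  n <- 60
  conf <- cbind(rnorm(n), rnorm(n))
  ts <- cbind(a = conf[, 1] * 2 + 3, b = rnorm(n))
  res <- regress_confounds(ts, conf)
  expect_lt(max(abs(res[, "a"])), 1e-10)
  expect_lt(max(abs(crossprod(conf, res))), 1e-8)
  expect_lt(max(abs(colMeans(res))), 1e-10)
  expect_equal(dim(res), dim(ts))
  # redundant confounds are tolerated (pivoted QR)
  expect_silent(regress_confounds(ts, cbind(conf, conf[, 1])))
})

test_that("Fisher z transform matches atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-4)
  expect_message(z1 <- fisher_z(1), "clipping")
  expect_true(is.finite(z1))
})

test_that("taskwise connectivity recovers a planted correlation", {
  set.seed(11)
  C <- matrix(0.4, 8, 8); diag(C) <- 1
  R <- chol(C)
  tframes <- 3000
  resid <- matrix(rnorm(tframes * 8), tframes) %*% R
  colnames(resid) <- paste0("roi", 1:8)
  ev <- data.frame(onset = 0, duration = 1, task = "attention",
                   condition = "divided", modality = "both",
                   switch_flag = "n/a", congruent = TRUE, block_id = 1L,
                   response_duration = tframes * 2.5 - 10, correct = NA,
                   run = 1L)
  z <- taskwise_connectivity(resid, ev, "DivA", hrf_lag_frames = 0)
  expect_length(z, 28)
  expect_lt(max(abs(attr(z, "r") - 0.4)), 0.05)
  expect_gte(attr(z, "n_frames"), tframes - 5)
  # affine rescaling of an ROI series leaves z unchanged
  resid2 <- resid; resid2[, 3] <- 5 * resid2[, 3] + 7
  z2 <- taskwise_connectivity(resid2, ev, "DivA", hrf_lag_frames = 0)
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  # too few frames / zero variance
  expect_error(taskwise_connectivity(resid[1:5, ], ev, "DivA",
                                     hrf_lag_frames = 0), "fewer than 8")
  bad <- resid; bad[, 2] <- 1
  expect_error(taskwise_connectivity(bad, ev, "DivA", hrf_lag_frames = 0),
               "roi2")
})

test_that("ModSwi frame selection takes post-switch windows", {
  ev <- shift_events(build_nback_schedule(1, seed = 3), 4, 2.5)
  nf <- 151
  fr <- execonn:::frames_for_task(ev, "ModSwi", 2.5, nf, hrf_lag_frames = 2)
  post <- ev[ev$condition %in% c("nback1", "nback2") &
               ev$switch_flag == "post_switch", ]
  expect_gt(length(fr), 8)
  # every selected frame is within 3 frames after some lagged post-switch
  starts <- floor(post$onset / 2.5) + 1 + 2
  expect_true(all(vapply(fr, function(f)
    any(f >= starts & f <= starts + 2), logical(1))))
  wm <- execonn:::frames_for_task(ev, "WM", 2.5, nf, hrf_lag_frames = 2)
  expect_gt(length(wm), 30)
})
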