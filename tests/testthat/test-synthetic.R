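test_that("acquisition specs enforce their invariants", {
  expect_error(acq_spec(n_dummy = 300), "n_dummy")
  expect_error(acq_spec(affine = matrix(0, 4, 4)), "invertible")
  acq <- attention_acq()
  expect_equal(acq$n_volumes, 222L)
  expect_equal(nback_acq()$n_volumes, 155L)
  expect_equal(acq$tr_seconds, 2.5)
  expect_equal(acq$n_dummy, 4L)
  # default affine centres the grid on the origin
  co <- voxel_coords_mm(acq)
  expect_lt(max(abs(colMeans(co))), 1e-9)
  expect_error(volume4d(array(0, c(2, 2, 2, 3)), diag(4), 2.5,
                        mask = array(TRUE, c(3, 2, 2))), "mask")
})

test_that("NIfTI volumes round trip (plain and gzipped)", {
  acq <- tiny_acq()
  arr <- array(rnorm(10 * 10 * 10 * 3), c(10, 10, 10, 3))
  vol <- volume4d(arr, acq$affine, 2.5)
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_nifti(vol, path)
    back <- read_nifti(path)
    expect_equal(dim(back$data), dim(arr))
    expect_lt(max(abs(back$data - arr)), 1e-5)  # float32 precision
    expect_equal(back$affine[1:3, ], acq$affine[1:3, ], tolerance = 1e-6)
    expect_equal(back$tr_seconds, 2.5, tolerance = 1e-6)
  }
})

test_that("activation atlas hits overlap targets on its detection sets", {
  acq <- attention_acq()
  at <- make_activation_atlas(acq, 0.40, sigma_w = 0.59)
  ut <- at$realized[upper.tri(at$realized)]
  expect_true(all(ut >= 0.37 & ut <= 0.43))
  expect_length(at$maps, 4)
  # identity and disjoint degenerate cases
  at1 <- make_activation_atlas(acq, 1)
  expect_equal(at1$maps$DivA, at1$maps$ModSwi)
  expect_true(all(at1$realized == 1))
  at0 <- make_activation_atlas(acq, 0)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(sum(at0$detection_sets[[i] ] & at0$detection_sets[[j]]), 0)
  expect_error(make_activation_atlas(acq, 1.2), "\\[0,1\\]")
  expect_error(make_activation_atlas(acq, matrix(runif(16), 4)), "symmetric")
})

test_that("infeasible overlap target combinations error before simulation", {
  acq <- attention_acq()
  # three pairs identical (overlap 1) but the remaining pairs disjoint is
  # geometrically impossible
  tg <- matrix(1, 4, 4)
  tg[1, 4] <- tg[4, 1] <- 0
  expect_error(make_activation_atlas(acq, tg), "infeasible|0.03")
})

test_that("connectivity structure realizes the similarity target exactly", {
  for (s in c(0, 0.3, 0.6, 0.9)) {
    cs <- make_connectivity_structure(s, seed = 5)
    ut <- cs$realized[upper.tri(cs$realized)]
    expect_true(all(abs(ut - s) <= 0.05))
    for (C in cs$matrices) {
      expect_equal(diag(C), rep(1, 8))
      expect_gt(min(eigen(C, symmetric = TRUE)$values), 0)
      expect_equal(length(C[upper.tri(C)]), 28)
    }
  }
  cs1 <- make_connectivity_structure(1, seed = 5)
  expect_equal(cs1$matrices[[1]], cs1$matrices[[4]])
  expect_error(make_connectivity_structure(1.5), "\\[0, 1\\]")
  expect_error(make_connectivity_structure(0.5, n_rois = 1), "n_rois")
})

test_that("BOLD simulation is deterministic and respects degenerate inputs", {
  acq <- tiny_acq()
  ev <- build_nback_schedule(1, acq = acq, seed = 2)
  s1 <- simulate_bold(ev, acq, noise_sd = 0.5, drift_sd = 0.2, seed = 7)
  s2 <- simulate_bold(ev, acq, noise_sd = 0.5, drift_sd = 0.2, seed = 7)
  expect_identical(s1$vol$data, s2$vol$data)     # bit-identical
  expect_identical(s1$motion, s2$motion)
  s3 <- simulate_bold(ev, acq, noise_sd = 0.5, seed = 8)
  expect_false(identical(s1$vol$data, s3$vol$data))
  # zero noise + empty schedule -> constant volumes
  s0 <- simulate_bold(ev[0, ], acq, noise_sd = 0, drift_sd = 0, seed = 1)
  expect_true(all(s0$vol$data == 100))
  expect_equal(dim(s1$motion), c(155L, 6L))
})

test_that("the GLM recovers planted amplitudes exactly at zero noise", {
  acq <- tiny_acq()
  ev <- build_nback_schedule(1, acq = acq, seed = 4)
  amp <- array(0, acq$grid_shape); amp[3:6, 3:6, 3:6] <- 0.8
  cls <- unique(execonn:::event_class(execonn:::trial_rows(ev)))
  maps <- setNames(lapply(cls, function(x) amp), cls)
  sim <- simulate_bold(ev, acq, amplitude_maps = maps, noise_sd = 0,
                       drift_sd = 0, seed = 1)
  vol <- drop_dummies(sim$vol, acq$n_dummy)
  evs <- shift_events(ev, acq$n_dummy, acq$tr_seconds)
  X <- suppressWarnings(build_design_matrix(evs, acq))
  fit <- fit_glm_ols(vol, X)
  for (cl in cls) {
    b <- array(fit$betas[paste0("cond_", cl), ], acq$grid_shape)
    expect_lt(max(abs(b - amp)), 1e-6 + 1e-6 * max(amp))
  }
  # planted amplitude zero -> near-zero betas (numerical floor)
  sim0 <- simulate_bold(ev, acq, amplitude_maps = NULL, noise_sd = 0,
                        drift_sd = 0, seed = 1)
  fit0 <- fit_glm_ols(drop_dummies(sim0$vol, 4), X)
  expect_lt(max(abs(fit0$betas[grep("^cond_", rownames(fit0$betas)), ])),
            1e-8)
})

test_that("ROI-structured noise carries the planted correlation", {
  acq <- acq_spec(n_volumes = 404L, n_dummy = 4L,
                  grid_shape = c(14L, 14L, 8L))
  rois <- roi_set(paste0("roi", 1:8),
                  cbind(c(-13, 0, 13, -13, 13, -13, 0, 13),
                        c(-13, -13, -13, 0, 0, 13, 13, 13),
                        rep(0, 8)),
                  radius_mm = 5)
  C <- matrix(0.5, 8, 8); diag(C) <- 1
  ev <- data.frame(onset = 10, duration = 2.5, task = "attention",
                   condition = "divided", modality = "both",
                   switch_flag = "n/a", congruent = TRUE, block_id = 1L,
                   response_duration = 980, correct = NA, run = 1L)
  sim <- simulate_bold(ev, acq, rois = rois,
                       conn_matrices = list(DivA = C), noise_sd = 0.3,
                       roi_noise_sd = 1, seed = 3, drift_sd = 0)
  vol <- drop_dummies(sim$vol, 4)
  ts <- extract_roi_timecourses(vol, rois)
  evs <- shift_events(ev, 4, 2.5)
  z <- taskwise_connectivity(regress_confounds(ts), evs, "DivA")
  expect_lt(max(abs(attr(z, "r") - 0.5)), 0.15)
  expect_gt(min(attr(z, "r")), 0.2)
})

test_that("behavior simulation honours its parameters", {
  expect_equal(behavior_defaults()$task_means[["DivA"]], 73.82)
  ev <- build_attention_schedule(1, seed = 1)
  perfect <- behavior_defaults()
  perfect$task_means[] <- 100
  perfect$filler_means[] <- 100
  perfect$block_sd <- 0
  out <- simulate_behavior(ev, seed = 1, params = perfect)
  expect_true(all(out$correct[out$task == "attention"]))
  # cohort ordering: middle adolescents lowest at moderate n
  bd <- behavior_defaults()
  sched <- rbind(build_attention_schedule(1, seed = 1),
                 build_nback_schedule(1, seed = 1))
  means <- sapply(c("middle_adolescent", "late_adolescent", "young_adult"),
                  function(lab) {
    sc <- replicate(60, {
      sh <- bd$cohort_shifts[[lab]] + rnorm(1, 0, bd$participant_sd)
      ev2 <- simulate_behavior(sched, seed = sample.int(1e6, 1),
                               participant_shift = sh)
      mean(suppressWarnings(compute_task_scores(ev2)), na.rm = TRUE)
    })
    mean(sc)
  })
  expect_lt(means["middle_adolescent"], means["late_adolescent"])
  expect_lt(means["middle_adolescent"], means["young_adult"])
})

test_that("motion simulation produces plausible random walks with spikes", {
  m <- simulate_motion(100, seed = 3, spike_frames = 50, spike_mm = 2)
  expect_equal(dim(m), c(100L, 6L))
  fd <- framewise_displacement(m)
  expect_equal(which.max(fd), 50)
  expect_identical(m, simulate_motion(100, seed = 3, spike_frames = 50,
                                      spike_mm = 2))
})

test_that("child seeds are stable and stay below 2^31", {
  expect_identical(child_seed(1, 2, 3), child_seed(1, 2, 3))
  expect_false(child_seed(1, 2, 3) == child_seed(1, 3, 2))
  seeds <- sapply(1:500, function(k) child_seed(123, k))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
})
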