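# Forward simulation of BOLD runs, motion parameters, and behavior.

#' Cohort configuration
#'
#' @param label cohort label (`"middle_adolescent"`, `"late_adolescent"`,
#'   `"young_adult"`, or custom)
#' @param n_participants cohort size (>= 2)
#' @param prop_female fraction of female participants
#' @param overlap_target planted pairwise activation-overlap fraction
#' @param similarity_target planted cross-task connectivity similarity s
#' @param accuracy_shift additive shift (percentage points) applied to all
#'   task accuracy means for this cohort
#' @param noise_sd temporal white-noise SD, or `"auto"` to calibrate so a
#'   participant's smoothed contrast SE puts the expected group-t contour
#'   at half the planted amplitude (see the methods vignette)
#' @param roi_noise_sd SD of the shared ROI latent series
#' @param motion_step_mm random-walk step SD of the translations
#' @param seed cohort seed (participant/run streams derive from it)
#' @return a `cohort_config`
#' @export
cohort_config <- function(label, n_participants = 12L, prop_female = 0.5,
                          overlap_target = 0.25, similarity_target = 0.6,
                          accuracy_shift = 0, noise_sd = "auto",
                          roi_noise_sd = 1, motion_step_mm = 0.02,
                          seed = 1L) {
  if (n_participants < 2) stopf("n_participants must be >= 2")
  structure(list(label = label, n_participants = as.integer(n_participants),
                 prop_female = prop_female, overlap_target = overlap_target,
                 similarity_target = similarity_target,
                 accuracy_shift = accuracy_shift, noise_sd = noise_sd,
                 roi_noise_sd = roi_noise_sd,
                 motion_step_mm = motion_step_mm, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Synthesize motion parameters
#'
#' Random-walk translations (mm) and rotations (radians), with optional
#' spike frames.
#'
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param step_mm,step_rad random-walk step SDs
#' @param spike_frames optional frame indices receiving a `spike_mm` jump
#' @param spike_mm spike amplitude
#' @return T x 6 matrix (tx, ty, tz, rx, ry, rz)
#' @export
simulate_motion <- function(n_frames, seed = 1L, step_mm = 0.02,
                            step_rad = 4e-4, spike_frames = NULL,
                            spike_mm = 2) {
  with_rng(seed, {
    m <- cbind(
      apply(matrix(stats::rnorm(n_frames * 3, 0, step_mm), n_frames), 2,
            cumsum),
      apply(matrix(stats::rnorm(n_frames * 3, 0, step_rad), n_frames), 2,
            cumsum))
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    for (f in spike_frames) m[f, 1] <- m[f, 1] + spike_mm
    m
  })
}

#' Default behavioral accuracy parameters
#'
#' Grand task-type means (percent correct) follow the published adult
#' values; filler-trial categories and the cohort/gender structure are
#' package defaults documented in the methods vignette (middle adolescents
#' lowest, females slightly higher).
#'
#' @return list of parameters used by [simulate_behavior()]
#' @export
behavior_defaults <- function() {
  list(task_means = c(DivA = 73.82, DistrA = 88.33, WM = 86.23,
                      ModSwi = 90.08),
       filler_means = c(undistracted = 93, nback0 = 95, nback1_non = 92),
       cohort_shifts = c(middle_adolescent = -4.5, late_adolescent = 1.5,
                         young_adult = 3.0),
       gender_shift = c(female = 0.9, male = -0.9),
       participant_sd = 5, block_sd = 5)
}

rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

trial_accuracy_mean <- function(events, params) {
  mns <- numeric(nrow(events))
  tm <- params$task_means; fm <- params$filler_means
  cond <- events$condition; sw <- events$switch_flag
  mns[cond == "divided"] <- tm[["DivA"]]
  mns[cond %in% DISTRACTED_CONDITIONS] <- tm[["DistrA"]]
  mns[cond %in% UNDISTRACTED_CONDITIONS] <- fm[["undistracted"]]
  mns[cond == "nback0"] <- fm[["nback0"]]
  mns[cond == "nback1" & sw != "post_switch"] <- fm[["nback1_non"]]
  mns[cond == "nback2" & sw != "post_switch"] <- tm[["WM"]]
  mns[cond %in% c("nback1", "nback2") & sw == "post_switch"] <- tm[["ModSwi"]]
  mns
}

#' Fill the correctness column of a schedule
#'
#' Each block draws an accuracy deviation from a truncated normal; each
#' trial is then Bernoulli with probability
#' `(category mean + participant shift + block deviation) / 100` clamped to
#' `[0, 1]`.
#'
#' @param events an `event_table`
#' @param seed RNG seed
#' @param participant_shift additive accuracy shift for this participant
#'   (cohort + gender + individual ability), percentage points
#' @param params parameter list (see [behavior_defaults()])
#' @return the `event_table` with `correct` filled for task trials
#' @export
simulate_behavior <- function(events, seed = 1L, participant_shift = 0,
                              params = behavior_defaults()) {
  with_rng(seed, {
    tri <- which(events$task %in% c("attention", "nback"))
    if (length(tri) == 0) return(events)
    mns <- trial_accuracy_mean(events[tri, , drop = FALSE], params)
    blocks <- interaction(events$run[tri], events$block_id[tri], drop = TRUE)
    bdev <- stats::setNames(
      rtruncnorm01(nlevels(blocks), 0, params$block_sd, -50, 50),
      levels(blocks))
    p <- (mns + participant_shift + bdev[as.character(blocks)]) / 100
    p <- pmin(1, pmax(0, p))
    events$correct[tri] <- stats::runif(length(tri)) < p
    events
  })
}

# --- BOLD forward model -------------------------------------------------

# corner background boxes acting as white-matter / CSF proxy regions
proxy_regions <- function(acq, size = 3L) {
  d <- acq$grid_shape
  lin <- function(i, j, k) {
    g <- as.matrix(expand.grid(i = i, j = j, k = k))
    g[, 1] + (g[, 2] - 1) * d[1] + (g[, 3] - 1) * d[1] * d[2]
  }
  list(wm = lin(1:size, 1:size, 1:size),
       csf = lin(d[1] - size + 1:size, d[2] - size + 1:size,
                 d[3] - size + 1:size))
}

# frame ownership for ROI-noise injection, on the full (dummy-included)
# frame grid; ModSwi windows take precedence inside the 1-/2-back blocks
frame_ownership <- function(events, acq, hrf_lag_frames = 2) {
  tpost <- acq$n_volumes - acq$n_dummy
  ev <- shift_events(events, acq$n_dummy, acq$tr_seconds)
  own <- rep(NA_character_, tpost)
  for (task in c("DivA", "DistrA", "WM")) {
    fr <- frames_for_task(ev, task, acq$tr_seconds, tpost, hrf_lag_frames)
    own[fr] <- task
  }
  fr <- frames_for_task(ev, "ModSwi", acq$tr_seconds, tpost, hrf_lag_frames)
  own[fr] <- "ModSwi"
  # remaining trial frames (undistracted, 0-back) share the base structure
  other <- c(UNDISTRACTED_CONDITIONS, "nback0")
  rows <- ev[ev$condition %in% other, , drop = FALSE]
  ft <- (seq_len(tpost) - 1) * acq$tr_seconds
  for (b in unique(rows$block_id)) {
    blk <- rows[rows$block_id == b, , drop = FALSE]
    t0 <- min(blk$onset) + hrf_lag_frames * acq$tr_seconds
    t1 <- max(blk$onset + blk$duration + blk$response_duration) +
      hrf_lag_frames * acq$tr_seconds
    sel <- ft >= t0 & ft < t1 & is.na(own)
    own[sel] <- "base"
  }
  c(rep(NA_character_, acq$n_dummy), own)
}

#' Simulate one BOLD run
#'
#' Voxel signal = baseline + sum over condition classes of (HRF-convolved
#' regressor x planted amplitude map) + slow drift + ROI-structured latent
#' noise (all voxels of an ROI share a latent series drawn with the
#' planted per-task correlation, injected blockwise) + white noise.
#' Deterministic given (inputs, seed).
#'
#' @param events the run schedule (scanner clock)
#' @param acq the run's [acq_spec()]
#' @param amplitude_maps named list of 3D amplitude arrays, keyed by
#'   condition class (see `event_class`), or `NULL`
#' @param rois optional `roi_set` receiving structured noise
#' @param conn_matrices named list of per-task ROI correlation matrices
#'   (plus optionally `"base"`); required when `rois` is given
#' @param noise_sd white temporal noise SD
#' @param roi_noise_sd SD of the shared ROI latent series
#' @param baseline mean signal level
#' @param drift_sd SD of the random low-frequency drift coefficients
#' @param seed RNG seed
#' @param motion_step_mm motion random-walk step
#' @param hrf_lag_frames lag used for blockwise noise injection (matches
#'   the analysis default)
#' @return list: `vol` (`volume4d`), `motion`, `events`, `proxies`
#' @export
simulate_bold <- function(events, acq, amplitude_maps = NULL, rois = NULL,
                          conn_matrices = NULL, noise_sd = 2,
                          roi_noise_sd = 1, baseline = 100, drift_sd = 0.5,
                          seed = 1L, motion_step_mm = 0.02,
                          hrf_lag_frames = 2) {
  tfull <- acq$n_volumes
  nvox <- prod(acq$grid_shape)
  ft_full <- (seq_len(tfull) - 1) * acq$tr_seconds
  tr_ev <- trial_rows(events)
  last <- if (nrow(tr_ev) > 0)
    max(tr_ev$onset + tr_ev$duration + tr_ev$response_duration) else 0
  if (last > tfull * acq$tr_seconds)
    stopf("schedule overflows the acquisition window")

  Y <- matrix(baseline, tfull, nvox)
  if (!is.null(amplitude_maps) && nrow(tr_ev) > 0) {
    cls <- event_class(tr_ev)
    for (nm in names(amplitude_maps)) {
      sel <- cls == nm
      if (!any(sel)) next
      reg <- convolve_events(tr_ev$onset[sel], tr_ev$duration[sel], ft_full)
      Y <- Y + tcrossprod(reg, as.vector(amplitude_maps[[nm]]))
    }
  }
  with_rng(seed, {
    # drift spanned by the analysis DCT basis (post-dummy frames)
    tpost <- tfull - acq$n_dummy
    dct <- dct_basis(tpost, 3L)
    if (drift_sd > 0 && ncol(dct) > 0) {
      co <- stats::rnorm(ncol(dct), 0, drift_sd)
      drift <- c(rep(0, acq$n_dummy), as.vector(dct %*% co))
      Y <- Y + drift
    }
    if (!is.null(rois)) {
      if (is.null(conn_matrices)) stopf("conn_matrices required with rois")
      members <- roi_membership(rois, acq)
      own <- frame_ownership(events, acq, hrf_lag_frames)
      chol_list <- lapply(conn_matrices, chol)
      for (task in unique(stats::na.omit(own))) {
        Ck <- chol_list[[task]] %||% chol_list[["base"]]
        if (is.null(Ck)) next
        fr <- which(own == task)
        lat <- matrix(stats::rnorm(length(fr) * length(members)),
                      length(fr)) %*% Ck
        for (i in seq_along(members))
          Y[fr, members[[i]]] <- Y[fr, members[[i]]] +
            roi_noise_sd * lat[, i]
      }
    }
    if (noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(tfull * nvox, 0, noise_sd), tfull)
    motion <- simulate_motion(tfull, seed = child_seed(seed, 9L),
                              step_mm = motion_step_mm)
    if (any(!is.finite(Y))) stopf("non-finite values in simulated volume")
    vol <- volume4d(array(t(Y), c(acq$grid_shape, tfull)), acq$affine,
                    acq$tr_seconds)
    list(vol = vol, motion = motion, events = events,
         proxies = proxy_regions(acq))
  })
}
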