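# ROI time-course extraction, confound regression, and taskwise
# Fisher-z ROI-to-ROI connectivity.

#' Extract mean ROI time courses
#'
#' Unweighted mean over masked voxels whose centre lies within the sphere
#' radius of each ROI centre.
#'
#' @param vol a `volume4d`
#' @param rois a `roi_set`
#' @return T x (n ROIs) matrix with ROI names as columns
#' @export
extract_roi_timecourses <- function(vol, rois) {
  Y <- vol_matrix(vol)
  members <- roi_membership(rois, vol)
  maskv <- as.vector(vol$mask)
  out <- matrix(NA_real_, nrow(Y), length(rois$name),
                dimnames = list(NULL, rois$name))
  for (i in seq_along(members)) {
    m <- members[[i]][maskv[members[[i]]]]
    if (length(m) == 0) stopf("ROI %s contains no masked voxels", rois$name[i])
    out[, i] <- if (length(m) == 1) Y[, m] else rowMeans(Y[, m, drop = FALSE])
  }
  out
}

#' Regress confounds out of ROI series
#'
#' Per-ROI OLS residuals against the confound columns plus an intercept.
#' Including the task/rest effect columns makes the residual correlations
#' background connectivity (task-evoked covariance removed).
#'
#' @param ts T x R matrix of ROI series
#' @param confounds T x C matrix / data frame (may have zero columns)
#' @return T x R residual matrix
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  ts <- as.matrix(ts)
  X <- cbind(intercept = rep(1, nrow(ts)),
             if (!is.null(confounds)) as.matrix(confounds))
  qx <- qr(X) # pivoted QR: redundant confound columns are tolerated
  ts - qr.fitted(qx, ts)
}

#' Build the standard confound set for one run
#'
#' Six motion parameters, white-matter and CSF proxy series, the convolved
#' task/rest effect columns of the design, and one indicator column per
#' outlier frame.
#'
#' @param motion T x 6 motion matrix
#' @param wm,csf proxy series (or `NULL`)
#' @param design a `design_matrix`; its condition/response/instruction
#'   columns are used as task-effect confounds
#' @param outlier_flags logical vector of flagged frames
#' @return T x C numeric matrix
#' @export
confound_set <- function(motion = NULL, wm = NULL, csf = NULL,
                         design = NULL, outlier_flags = NULL) {
  parts <- list()
  if (!is.null(motion)) parts$motion <- as.matrix(motion)
  if (!is.null(wm)) parts$wm <- wm
  if (!is.null(csf)) parts$csf <- csf
  if (!is.null(design)) {
    task_cols <- grep("^(cond_|response$|instruction$)", colnames(design))
    if (length(task_cols) > 0)
      parts$task <- as.matrix(design)[, task_cols, drop = FALSE]
  }
  if (!is.null(outlier_flags) && any(outlier_flags)) {
    ind <- sapply(which(outlier_flags), function(j) {
      v <- numeric(length(outlier_flags)); v[j] <- 1; v
    })
    parts$outliers <- matrix(ind, ncol = sum(outlier_flags))
  }
  if (length(parts) == 0) return(NULL)
  do.call(cbind, parts)
}

#' Fisher r-to-z transform with clipping
#'
#' @param r correlation(s); |r| is clipped to `1 - eps` before `atanh`
#' @param eps clipping margin (default 1e-7)
#' @return z value(s)
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(abs(r) >= 1 - eps))
    message("fisher_z: clipping |r| >= 1 - eps before atanh")
  atanh(pmin(pmax(r, -(1 - eps)), 1 - eps))
}

# map task type -> condition labels defining its blocks
task_block_conditions <- function(task) {
  switch(task,
         DivA = "divided",
         DistrA = DISTRACTED_CONDITIONS,
         WM = c("nback1", "nback2"),
         ModSwi = NULL, # event-type task: post-switch windows
         stopf("unknown task type %s", task))
}

# frame indices (1-based, post-dummy clock) belonging to one task in one run
frames_for_task <- function(events, task, tr_seconds, n_frames,
                            hrf_lag_frames = 2) {
  tr <- tr_seconds
  ft <- (seq_len(n_frames) - 1) * tr
  sel <- logical(n_frames)
  if (task == "ModSwi") {
    rows <- events[events$task == "nback" &
                     events$condition %in% c("nback1", "nback2") &
                     events$switch_flag == "post_switch", , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      j0 <- floor(rows$onset[i] / tr) + 1 + hrf_lag_frames
      sel[j0:min(n_frames, j0 + 2)] <- TRUE
    }
  } else {
    conds <- task_block_conditions(task)
    rows <- events[events$condition %in% conds, , drop = FALSE]
    if (nrow(rows) > 0) for (b in unique(rows$block_id)) {
      blk <- rows[rows$block_id == b, , drop = FALSE]
      t0 <- min(blk$onset) + hrf_lag_frames * tr
      t1 <- max(blk$onset + blk$duration + blk$response_duration) +
        hrf_lag_frames * tr
      sel[ft >= t0 & ft < t1] <- TRUE
    }
  }
  which(sel & seq_len(n_frames) >= 1 & seq_len(n_frames) <= n_frames)
}

#' Taskwise ROI-to-ROI connectivity
#'
#' Concatenates, across runs, the frames belonging to the task's blocks
#' (shifted by the hemodynamic lag; for the event-type ModSwi "task", the
#' 3-frame windows following each post-switch trial), correlates every ROI
#' pair over those frames, and applies the Fisher z transform.
#'
#' @param resid_list list of T x R residual ROI-series matrices (one per run)
#' @param events_list matching list of `event_table`s (post-dummy clock)
#' @param task one of `"DivA"`, `"DistrA"`, `"WM"`, `"ModSwi"`
#' @param tr_seconds repetition time
#' @param hrf_lag_frames hemodynamic lag in frames (default 2 = 5 s at TR
#'   2.5 s)
#' @return a `connectivity_vector`: numeric vector of length
#'   `choose(R, 2)` of z values, with attributes `r`, `pairs`
#'   (two-column matrix of ROI names) and `n_frames`
#' @export
taskwise_connectivity <- function(resid_list, events_list, task,
                                  tr_seconds = 2.5, hrf_lag_frames = 2) {
  if (!is.list(resid_list)) resid_list <- list(resid_list)
  if (!is.list(events_list) || is.data.frame(events_list))
    events_list <- list(events_list)
  seg <- list()
  for (k in seq_along(resid_list)) {
    fr <- frames_for_task(events_list[[k]], task, tr_seconds,
                          nrow(resid_list[[k]]), hrf_lag_frames)
    if (length(fr) > 0) seg[[length(seg) + 1]] <-
        resid_list[[k]][fr, , drop = FALSE]
  }
  dat <- do.call(rbind, seg)
  if (is.null(dat) || nrow(dat) < 8)
    stopf("task %s selects fewer than 8 frames", task)
  sds <- apply(dat, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance ROI series for task %s: %s", task,
          paste(colnames(dat)[sds == 0], collapse = ", "))
  C <- stats::cor(dat)
  nm <- colnames(dat)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  r <- C[ut]
  z <- fisher_z(r)
  pairs <- cbind(nm[ut[, 1]], nm[ut[, 2]])
  names(z) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  structure(z, r = r, pairs = pairs, n_frames = nrow(dat), task = task,
            class = "connectivity_vector")
}
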