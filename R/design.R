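# Design-matrix construction: condition regressors (boxcars convolved with
# the canonical HRF), response and instruction nuisance regressors, six
# motion columns, a discrete-cosine drift basis implementing the high-pass
# filter, and an intercept.

# canonical regressor classes per task, used to warn on absent classes
attention_classes <- function() {
  as.vector(outer(ATTENTION_CONDITIONS, c("cong", "incong"),
                  function(a, b) paste(a, b, sep = "_")))
}
nback_classes <- function() {
  as.vector(outer(NBACK_CONDITIONS,
                  as.vector(outer(c("pre", "post", "non"),
                                  c("visual", "auditory"), paste, sep = "_")),
                  paste, sep = "_"))
}

event_class <- function(events) {
  cls <- character(nrow(events))
  att <- events$task == "attention"
  cls[att] <- paste(events$condition[att],
                    ifelse(events$congruent[att], "cong", "incong"), sep = "_")
  nb <- events$task == "nback"
  sw <- c(pre_switch = "pre", post_switch = "post", nonswitch = "non")
  cls[nb] <- paste(events$condition[nb], sw[events$switch_flag[nb]],
                   events$modality[nb], sep = "_")
  cls
}

# number of DCT drift columns for a high-pass cutoff (SPM convention)
dct_column_count <- function(duration_seconds, hp_cutoff_seconds) {
  max(0L, floor(2 * duration_seconds / hp_cutoff_seconds))
}

dct_basis <- function(n_frames, k_max) {
  if (k_max < 1) return(matrix(0, n_frames, 0))
  j <- seq_len(n_frames) - 1
  b <- sapply(seq_len(k_max), function(k)
    cos(pi * (2 * j + 1) * k / (2 * n_frames)))
  b <- matrix(b, n_frames, k_max)
  colnames(b) <- paste0("dct", seq_len(k_max))
  b
}

#' Build a first-level design matrix
#'
#' Condition columns are event boxcars (stimulus duration) convolved with
#' [canonical_hrf()] and sampled at frame acquisition times. Attention
#' conditions are split by sentence congruency; n-back conditions expand to
#' level x (pre/post/non switch) x modality. Nuisance columns: convolved
#' response events, convolved instruction periods, six motion parameters,
#' a discrete-cosine drift basis up to `1/hp_cutoff_seconds` Hz, and an
#' intercept. Events must already be on the analysis clock (see
#' [shift_events()]).
#'
#' @param events an `event_table` for one run
#' @param acq the run's [acq_spec()] (frame count after dummy removal)
#' @param motion optional T x 6 motion-parameter matrix
#' @param hp_cutoff_seconds high-pass cutoff (default 128 s)
#' @param warn_missing warn about canonical condition classes absent from
#'   this run (their columns are omitted, never zero-filled)
#' @return a `design_matrix`: numeric T x P matrix with attributes
#'   `convolved` (logical per column) and `frame_times`
#' @export
build_design_matrix <- function(events, acq, motion = NULL,
                                hp_cutoff_seconds = 128,
                                warn_missing = TRUE) {
  tframes <- acq$n_volumes - acq$n_dummy
  frame_times <- (seq_len(tframes) - 1) * acq$tr_seconds
  dur <- run_duration(acq)
  tr <- trial_rows(events)
  if (nrow(tr) > 0 && max(tr$onset + tr$duration + tr$response_duration) > dur)
    stopf("events extend past the run duration (%.1f s)", dur)

  cols <- list(); convolved <- logical(0)
  add <- function(name, x, conv) {
    cols[[name]] <<- x
    convolved[name] <<- conv
  }
  if (nrow(tr) > 0) {
    cls <- event_class(tr)
    expected <- if (all(tr$task == "nback")) nback_classes()
                else if (all(tr$task == "attention")) attention_classes()
                else c(attention_classes(), nback_classes())
    if (warn_missing) {
      miss <- setdiff(expected, unique(cls))
      if (length(miss) > 0)
        warnf("omitting absent condition column(s): %s",
              paste(miss, collapse = ", "))
    }
    for (cl in intersect(expected, unique(cls))) {
      sel <- cls == cl
      add(paste0("cond_", cl),
          convolve_events(tr$onset[sel], tr$duration[sel], frame_times), TRUE)
    }
    # responses: the window that follows each stimulus
    add("response", convolve_events(tr$onset + tr$duration,
                                    tr$response_duration, frame_times), TRUE)
  }
  ins <- events[events$task == "instruction", , drop = FALSE]
  if (nrow(ins) > 0)
    add("instruction", convolve_events(ins$onset, ins$duration, frame_times),
        TRUE)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == tframes, ncol(motion) == 6)
    for (k in 1:6) add(paste0("motion", k), motion[, k], FALSE)
  }
  dct <- dct_basis(tframes, dct_column_count(dur, hp_cutoff_seconds))
  for (k in seq_len(ncol(dct))) add(colnames(dct)[k], dct[, k], FALSE)
  add("intercept", rep(1, tframes), FALSE)

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(X, convolved = convolved, frame_times = frame_times,
            class = c("design_matrix", "matrix"))
}

condition_columns <- function(X) grep("^cond_", colnames(X), value = TRUE)
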