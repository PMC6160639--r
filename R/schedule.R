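# Event schedules for the two task protocols.
#
# Onsets are on the scanner clock (dummies included); drop_dummies() shifts
# them onto the analysis clock. One row per trial, plus one row per
# instruction period and one per rest block. `duration` is the stimulus
# duration; `response_duration` the response window that completes the trial.

ATTENTION_CONDITIONS <- c("att_aud", "att_vis",            # undistracted
                          "att_aud_disvis", "att_vis_disaud",
                          "att_vis_dismusic",              # distracted
                          "divided")
DISTRACTED_CONDITIONS <- c("att_aud_disvis", "att_vis_disaud",
                           "att_vis_dismusic")
UNDISTRACTED_CONDITIONS <- c("att_aud", "att_vis")
NBACK_CONDITIONS <- c("nback0", "nback1", "nback2")
TASK_TYPES <- c("DivA", "DistrA", "WM", "ModSwi")

ATTENTION_MODALITY <- c(att_aud = "auditory", att_vis = "visual",
                        att_aud_disvis = "both", att_vis_disaud = "both",
                        att_vis_dismusic = "both", divided = "both")

event_row <- function(onset, duration, task, condition, modality,
                      switch_flag, congruent, block_id, response_duration) {
  data.frame(onset = onset, duration = duration, task = task,
             condition = condition, modality = modality,
             switch_flag = switch_flag, congruent = congruent,
             block_id = block_id, response_duration = response_duration,
             correct = NA, stringsAsFactors = FALSE)
}

finish_schedule <- function(rows, run_index, acq, task) {
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev$run <- run_index
  run_end <- acq$n_volumes * acq$tr_seconds
  last <- max(ev$onset + ev$duration + ev$response_duration)
  if (last > run_end)
    stopf("%s run %d schedule overflows the acquisition: last event ends at %.1f s but the run is %.1f s",
          task, run_index, last, run_end)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Build one attention-run schedule
#'
#' Each run holds one rest block and seven task blocks (one per condition,
#' the divided-attention condition twice), each task block 12 sentence
#' trials of 2.5 s stimulus plus a 1.5 s response window. Blocks are
#' separated by 2.5 s instruction periods and preceded by a 6 s run
#' instruction; block order is randomized per seed, block composition is
#' fixed.
#'
#' @param run_index run number, 1-3
#' @param acq an [acq_spec()]; defaults to [attention_acq()]
#' @param seed RNG seed controlling block order and congruency
#' @param stimulus_seconds,response_seconds trial timing
#' @return an `event_table` data frame
#' @export
build_attention_schedule <- function(run_index, acq = attention_acq(),
                                     seed = 1L, stimulus_seconds = 2.5,
                                     response_seconds = 1.5) {
  if (!run_index %in% 1:3) stopf("run_index must be in 1..3")
  with_rng(child_seed(seed, 101L, run_index), {
    blocks <- sample(c(ATTENTION_CONDITIONS, "divided", "rest"))
    trial_len <- stimulus_seconds + response_seconds
    n_trials <- 12L
    block_len <- n_trials * trial_len
    t <- acq$n_dummy * acq$tr_seconds
    rows <- list(event_row(t, 6, "instruction", "instruction", "none",
                           "n/a", NA, 0L, 0))
    t <- t + 6
    for (b in seq_along(blocks)) {
      if (b > 1) {
        rows[[length(rows) + 1]] <- event_row(t, 2.5, "instruction",
                                              "instruction", "none", "n/a",
                                              NA, 0L, 0)
        t <- t + 2.5
      }
      cond <- blocks[b]
      if (cond == "rest") {
        rows[[length(rows) + 1]] <- event_row(t, block_len, "rest", "rest",
                                              "none", "n/a", NA, b, 0)
      } else {
        congr <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
        for (k in seq_len(n_trials)) {
          rows[[length(rows) + 1]] <- event_row(
            t + (k - 1) * trial_len, stimulus_seconds, "attention", cond,
            ATTENTION_MODALITY[[cond]], "n/a", congr[k], b, response_seconds)
        }
      }
      t <- t + block_len
    }
    finish_schedule(rows, run_index, acq, "attention")
  })
}

# modality stream with run lengths drawn uniformly from {3,4,5,7}
sample_modality_stream <- function(n_trials) {
  mods <- character(0)
  cur <- sample(c("visual", "auditory"), 1)
  while (length(mods) < n_trials) {
    len <- sample(c(3L, 4L, 5L, 7L), 1)
    mods <- c(mods, rep(cur, len))
    cur <- if (cur == "visual") "auditory" else "visual"
  }
  mods[seq_len(n_trials)]
}

switch_flags <- function(mods) {
  n <- length(mods)
  post <- c(FALSE, mods[-1] != mods[-n])
  pre <- c(post[-1], FALSE)
  ifelse(post, "post_switch", ifelse(pre, "pre_switch", "nonswitch"))
}

#' Build one n-back-run schedule
#'
#' Three blocks (0-, 1-, 2-back; order randomized per seed) of 32 vowel
#' trials each, 0.5 s stimulus plus 2.5 s retention. The stimulus modality
#' alternates between visual and auditory with run lengths drawn uniformly
#' from \{3, 4, 5, 7\}; trials are flagged `pre_switch`, `post_switch` or
#' `nonswitch`. 1- and 2-back blocks are regenerated until they contain at
#' least one n-back match.
#'
#' @inheritParams build_attention_schedule
#' @export
build_nback_schedule <- function(run_index, acq = nback_acq(), seed = 1L,
                                 stimulus_seconds = 0.5,
                                 response_seconds = 2.5) {
  if (!run_index %in% 1:2) stopf("run_index must be in 1..2")
  with_rng(child_seed(seed, 202L, run_index), {
    levels_order <- sample(0:2)
    n_trials <- 32L
    trial_len <- stimulus_seconds + response_seconds
    block_len <- n_trials * trial_len
    t <- acq$n_dummy * acq$tr_seconds
    rows <- list(event_row(t, 6, "instruction", "instruction", "none",
                           "n/a", NA, 0L, 0))
    t <- t + 6
    for (b in seq_along(levels_order)) {
      if (b > 1) {
        rows[[length(rows) + 1]] <- event_row(t, 2.5, "instruction",
                                              "instruction", "none", "n/a",
                                              NA, 0L, 0)
        t <- t + 2.5
      }
      lev <- levels_order[b]
      mods <- sample_modality_stream(n_trials)
      vowels <- sample(c("a", "e", "u", "y"), n_trials, replace = TRUE)
      if (lev > 0) {
        for (try in 1:100) {
          if (any(vowels[-seq_len(lev)] ==
                  vowels[seq_len(n_trials - lev)])) break
          vowels <- sample(c("a", "e", "u", "y"), n_trials, replace = TRUE)
        }
      }
      flags <- switch_flags(mods)
      for (k in seq_len(n_trials)) {
        rows[[length(rows) + 1]] <- event_row(
          t + (k - 1) * trial_len, stimulus_seconds, "nback",
          paste0("nback", lev), mods[k], flags[k], NA, b, response_seconds)
      }
      t <- t + block_len
    }
    finish_schedule(rows, run_index, acq, "nback")
  })
}

# trial rows only (no instruction / rest)
trial_rows <- function(events) events[events$task %in% c("attention", "nback"), ,
                                      drop = FALSE]

#' Shift an event table onto the post-dummy analysis clock
#'
#' @param events an `event_table`
#' @param n_dummy number of dummy volumes removed
#' @param tr_seconds repetition time
#' @return the shifted `event_table`
#' @export
shift_events <- function(events, n_dummy, tr_seconds) {
  events$onset <- events$onset - n_dummy * tr_seconds
  events
}

#' Write / read events as TSV
#'
#' @param events an `event_table`
#' @param path file path
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  ev$switch_flag[is.na(ev$switch_flag)] <- "n/a"
  class(ev) <- c("event_table", "data.frame")
  ev
}
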