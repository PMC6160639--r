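# End-to-end orchestration: simulate -> GLM -> thresholding/overlap ->
# connectivity -> similarity -> behavioral stats, under one seeded config.

#' Pipeline configuration
#'
#' @param cohorts list of [cohort_config()]s
#' @param acq_attention,acq_nback acquisition specs (must share a grid)
#' @param n_runs_attention,n_runs_nback runs per participant
#' @param group_threshold,participant_threshold [threshold_spec()]s; the
#'   desk-scale defaults keep the published height thresholds (2.7 / 1.3)
#'   but scale the extent thresholds to the small grid (k > 25 / k > 10)
#' @param roi_mode `"planted"` (synthetic desk centres), `"paper"`
#'   (published MNI centres; needs a covering grid), or a `roi_set`
#' @param analysis_fwhm spatial smoothing applied by the analysis (mm)
#' @param amplitude,radius_mm,tau planted activation parameters
#' @param hp_cutoff_seconds high-pass cutoff
#' @param hrf_lag_frames hemodynamic lag for connectivity frame selection
#' @param mds_dim embedding dimension for distance tables
#' @param n_perm permutation draws for matrix comparisons
#' @param seed master seed
#' @param out_dir optional output directory for the report bundle
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(cohorts,
                            acq_attention = attention_acq(),
                            acq_nback = nback_acq(),
                            n_runs_attention = 3L, n_runs_nback = 2L,
                            group_threshold = threshold_spec(2.7, 25L),
                            participant_threshold =
                              threshold_spec(1.3, 10L, level = "participant"),
                            roi_mode = "planted",
                            analysis_fwhm = 6, amplitude = 1,
                            radius_mm = 12, tau = 0.5,
                            hp_cutoff_seconds = 128, hrf_lag_frames = 2L,
                            mds_dim = 2L, n_perm = 999L, seed = 1L,
                            out_dir = NULL) {
  structure(list(cohorts = cohorts, acq_attention = acq_attention,
                 acq_nback = acq_nback,
                 n_runs_attention = as.integer(n_runs_attention),
                 n_runs_nback = as.integer(n_runs_nback),
                 group_threshold = group_threshold,
                 participant_threshold = participant_threshold,
                 roi_mode = roi_mode, analysis_fwhm = analysis_fwhm,
                 amplitude = amplitude, radius_mm = radius_mm, tau = tau,
                 hp_cutoff_seconds = hp_cutoff_seconds,
                 hrf_lag_frames = as.integer(hrf_lag_frames),
                 mds_dim = as.integer(mds_dim), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Default desk-scale three-cohort configuration
#'
#' Three cohorts of 12 participants with planted activation overlaps
#' 0.10 / 0.25 / 0.40 and planted cross-task connectivity similarities
#' 0.3 / 0.6 / 0.9 (middle adolescents lowest on both, mirroring the
#' age-cohort pattern the generator emulates), on the 24x28x24 desk grid.
#'
#' @param seed master seed
#' @param n_per_cohort participants per cohort
#' @param ... overrides passed to [pipeline_config()]
#' @export
default_desk_config <- function(seed = 1L, n_per_cohort = 12L, ...) {
  labs <- c("middle_adolescent", "late_adolescent", "young_adult")
  ovl <- c(0.10, 0.25, 0.40)
  sim <- c(0.3, 0.6, 0.9)
  shift <- c(-4.5, 1.5, 3.0)
  cohorts <- lapply(1:3, function(i)
    cohort_config(labs[i], n_participants = n_per_cohort,
                  overlap_target = ovl[i], similarity_target = sim[i],
                  accuracy_shift = shift[i],
                  seed = child_seed(seed, 500L + i)))
  pipeline_config(cohorts, seed = seed, ...)
}

#' Validate a pipeline configuration
#'
#' Cross-field checks run before any stage: schedule feasibility, grid
#' compatibility, ROI placement, cohort sizes.
#'
#' @param config a `pipeline_config`
#' @return data frame of findings (`level` = "error"/"warning"); invisibly
#'   signals nothing. Use `stop_on_error = TRUE` to raise.
#' @param stop_on_error raise an error when any error-level finding exists
#' @export
validate_config <- function(config, stop_on_error = FALSE) {
  findings <- list()
  note <- function(level, msg)
    findings[[length(findings) + 1]] <<- data.frame(level = level,
                                                    message = msg)
  if (!identical(config$acq_attention$grid_shape, config$acq_nback$grid_shape))
    note("error", "attention and n-back grids differ")
  for (co in config$cohorts) {
    if (co$n_participants < 2)
      note("error", sprintf("cohort %s has fewer than 2 participants",
                            co$label))
    if (co$overlap_target < 0 || co$overlap_target > 1)
      note("error", sprintf("cohort %s overlap target outside [0,1]",
                            co$label))
  }
  sched_ok <- tryCatch({
    build_attention_schedule(1, config$acq_attention, seed = 1)
    build_nback_schedule(1, config$acq_nback, seed = 1)
    TRUE
  }, error = function(e) {
    note("error", conditionMessage(e)); FALSE
  })
  rois <- resolve_rois(config)
  vox <- config$acq_attention$voxel_size_mm
  if (rois$radius_mm < max(vox))
    note("warning", "ROI radius below voxel size; spheres may be empty")
  co <- voxel_coords_mm(config$acq_attention)
  lo <- apply(co, 2, min); hi <- apply(co, 2, max)
  for (i in seq_along(rois$name)) {
    c_i <- rois$centers_mm[i, ]
    if (any(c_i - rois$radius_mm < lo - 1e-9) ||
        any(c_i + rois$radius_mm > hi + 1e-9))
      note("warning", sprintf("ROI %s extends outside the grid",
                              rois$name[i]))
  }
  out <- if (length(findings) > 0) do.call(rbind, findings)
         else data.frame(level = character(0), message = character(0))
  if (stop_on_error && any(out$level == "error"))
    stopf("invalid configuration:\n%s",
          paste(out$message[out$level == "error"], collapse = "\n"))
  out
}

resolve_rois <- function(config) {
  if (inherits(config$roi_mode, "roi_set")) config$roi_mode
  else if (identical(config$roi_mode, "paper")) paper_executive_rois()
  else desk_executive_rois()
}

# per-contrast expected participant contrast SE and (optionally) the
# auto-calibrated temporal noise SD; deterministic design analysis
calibrate_noise <- function(config) {
  att_des <- lapply(seq_len(config$n_runs_attention), function(r) {
    ev <- shift_events(build_attention_schedule(r, config$acq_attention,
                                                seed = config$seed),
                       config$acq_attention$n_dummy,
                       config$acq_attention$tr_seconds)
    suppressWarnings(build_design_matrix(ev, config$acq_attention,
                                         hp_cutoff_seconds =
                                           config$hp_cutoff_seconds))
  })
  nb_des <- lapply(seq_len(config$n_runs_nback), function(r) {
    ev <- shift_events(build_nback_schedule(r, config$acq_nback,
                                            seed = config$seed),
                       config$acq_nback$n_dummy,
                       config$acq_nback$tr_seconds)
    suppressWarnings(build_design_matrix(ev, config$acq_nback,
                                         hp_cutoff_seconds =
                                           config$hp_cutoff_seconds))
  })
  vox <- config$acq_attention$voxel_size_mm
  # per-unit-sigma SE for each contrast
  k_unit <- c(
    DivA = expected_contrast_se(att_des, lapply(att_des, function(X)
      make_executive_contrasts(X, "DivA")$DivA), 1, config$analysis_fwhm, vox),
    DistrA = expected_contrast_se(att_des, lapply(att_des, function(X)
      make_executive_contrasts(X, "DistrA")$DistrA), 1,
      config$analysis_fwhm, vox),
    WM = expected_contrast_se(nb_des, lapply(nb_des, function(X)
      make_executive_contrasts(X, "WM")$WM), 1, config$analysis_fwhm, vox),
    ModSwi = expected_contrast_se(nb_des, lapply(nb_des, function(X)
      make_executive_contrasts(X, "ModSwi")$ModSwi), 1,
      config$analysis_fwhm, vox))
  # sigma that puts the expected group-t contour at half the amplitude
  n <- config$cohorts[[1]]$n_participants
  t_thr <- config$group_threshold$t_min
  target_se <- (0.5 * config$amplitude / t_thr) *
    sqrt(max(n - t_thr^2 * config$tau^2, 1e-4))
  sigma_auto <- target_se / mean(k_unit)
  # per-contrast amplitude factors: planting each contrast's amplitude in
  # proportion to its design SE gives all four maps the same detection
  # geometry (the factor cancels in the expected group t)
  amp_factors <- k_unit / mean(k_unit)
  list(k_unit = k_unit, sigma_auto = sigma_auto, amp_factors = amp_factors)
}

condition_amplitude_maps <- function(atlas, g, task) {
  # g: named per-contrast participant amplitude factors
  maps <- list()
  vz <- function(nm) g[[nm]] * atlas$maps[[nm]]
  if (task == "attention") {
    m_div <- vz("DivA") + vz("DistrA")
    m_dis <- vz("DistrA")
    for (cg in c("cong", "incong")) {
      maps[[paste0("divided_", cg)]] <- m_div
      for (cc in DISTRACTED_CONDITIONS) maps[[paste0(cc, "_", cg)]] <- m_dis
    }
  } else {
    m_wm <- vz("WM")
    m_post <- vz("WM") + vz("ModSwi")
    for (md in c("visual", "auditory")) {
      for (lv in c("nback1", "nback2")) {
        maps[[paste(lv, "non", md, sep = "_")]] <- m_wm
        maps[[paste(lv, "pre", md, sep = "_")]] <- m_wm
        maps[[paste(lv, "post", md, sep = "_")]] <- m_post
      }
    }
  }
  maps
}

simulate_participant <- function(config, cohort, atlas, conn, rois,
                                 p_index, sigma, behavior_shift,
                                 amp_factors = rep(1, 4)) {
  pseed <- child_seed(cohort$seed, 1000L, p_index)
  g <- stats::setNames(as.list(
    with_rng(child_seed(pseed, 5L), stats::rnorm(4, 1, config$tau)) *
      amp_factors),
    TASK_TYPES)
  conn_mats <- c(conn$matrices, list(base = Reduce(`+`, conn$matrices) / 4))
  runs <- list()
  spec <- list(attention = list(n = config$n_runs_attention,
                                acq = config$acq_attention,
                                build = build_attention_schedule),
               nback = list(n = config$n_runs_nback,
                            acq = config$acq_nback,
                            build = build_nback_schedule))
  for (task in names(spec)) {
    sp <- spec[[task]]
    for (r in seq_len(sp$n)) {
      rseed <- child_seed(pseed, if (task == "attention") 10L else 20L, r)
      ev <- sp$build(r, sp$acq, seed = rseed)
      ev <- simulate_behavior(ev, seed = child_seed(rseed, 2L),
                              participant_shift = behavior_shift)
      sim <- simulate_bold(ev, sp$acq,
                           amplitude_maps =
                             condition_amplitude_maps(atlas, g, task),
                           rois = rois, conn_matrices = conn_mats,
                           noise_sd = sigma,
                           roi_noise_sd = cohort$roi_noise_sd,
                           seed = child_seed(rseed, 3L),
                           motion_step_mm = cohort$motion_step_mm,
                           hrf_lag_frames = config$hrf_lag_frames)
      runs[[length(runs) + 1]] <- c(sim, list(task = task, acq = sp$acq,
                                              run_index = r))
    }
  }
  analyze_participant(config, runs, rois, g)
}

analyze_participant <- function(config, runs, rois, g = NULL) {
  eff <- list(); se2 <- list(); resid_list <- list(); ev_list <- list()
  events_all <- list(); motion_all <- list()
  dvars_mean <- numeric(0); n_outliers <- 0L
  for (run in runs) {
    acq <- run$acq
    vol <- drop_dummies(run$vol, acq$n_dummy)
    motion <- run$motion[-seq_len(acq$n_dummy), , drop = FALSE]
    ev <- shift_events(run$events, acq$n_dummy, acq$tr_seconds)
    svol <- smooth_gaussian(vol, config$analysis_fwhm)
    X <- suppressWarnings(build_design_matrix(
      ev, acq, motion = motion,
      hp_cutoff_seconds = config$hp_cutoff_seconds))
    fit <- fit_glm_ols(svol, X)
    tasks <- if (run$task == "attention") c("DivA", "DistrA")
             else c("WM", "ModSwi")
    ws <- make_executive_contrasts(X, tasks)
    for (nm in tasks) {
      cm <- contrast_map(fit, ws[[nm]])
      eff[[nm]] <- c(eff[[nm]], list(cm$effect))
      se2[[nm]] <- c(se2[[nm]], list(cm$se^2))
    }
    # connectivity side: denoise ROI series from the smoothed volume
    Ymat <- vol_matrix(svol)
    ts <- extract_roi_timecourses(svol, rois)
    gs <- rowMeans(Ymat)
    flags <- detect_outliers(motion, gs)
    n_outliers <- n_outliers + sum(flags)
    conf <- confound_set(motion = motion,
                         wm = rowMeans(Ymat[, run$proxies$wm, drop = FALSE]),
                         csf = rowMeans(Ymat[, run$proxies$csf, drop = FALSE]),
                         design = X, outlier_flags = flags)
    resid_list[[length(resid_list) + 1]] <- regress_confounds(ts, conf)
    ev_list[[length(ev_list) + 1]] <- ev
    dvars_mean <- c(dvars_mean, mean(compute_dvars(vol)))
    events_all[[length(events_all) + 1]] <- run$events
    motion_all[[length(motion_all) + 1]] <- motion
  }
  effect_maps <- lapply(eff, function(l) Reduce(`+`, l) / length(l))
  # run-averaged participant t: mean effect over its combined-run SE
  t_maps <- lapply(names(eff), function(nm) {
    R <- length(eff[[nm]])
    se <- sqrt(Reduce(`+`, se2[[nm]])) / R
    tm <- effect_maps[[nm]] / se
    tm[!is.finite(tm)] <- 0
    tm
  })
  names(t_maps) <- names(eff)
  zvecs <- lapply(stats::setNames(TASK_TYPES, TASK_TYPES), function(task)
    taskwise_connectivity(resid_list, ev_list, task,
                          tr_seconds = runs[[1]]$acq$tr_seconds,
                          hrf_lag_frames = config$hrf_lag_frames))
  events <- do.call(rbind, events_all)
  motion <- do.call(rbind, motion_all)
  list(effect_maps = effect_maps, t_maps = t_maps, zvecs = zvecs,
       events = events,
       blocks = block_scores(events),
       excluded = motion_exclusion(motion),
       dvars_mean = mean(dvars_mean), n_outliers = n_outliers,
       amplitude_factors = g)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes, per cohort: planted-atlas and connectivity-structure
#' construction, participant-level simulation (attention + n-back runs,
#' behavior, motion), GLM contrast estimation, group thresholding and
#' overlap, taskwise ROI connectivity; then cross-cohort similarity,
#' MDS distance tables, permutation comparisons, and the behavioral
#' repeated-measures ANCOVA. Deterministic given the config (master seed
#' expands to counter-based substreams).
#'
#' @param config a [pipeline_config()]
#' @param progress print stage timings to stderr
#' @return a `run_report` list; see the methods vignette for the layout
#' @export
run_pipeline <- function(config, progress = FALSE) {
  t0 <- Sys.time()
  say <- function(fmt, ...) if (progress)
    message(sprintf("[%6.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            sprintf(fmt, ...))
  validate_config(config, stop_on_error = TRUE)
  rois <- resolve_rois(config)
  labels <- connection_labels(rois)
  cal <- calibrate_noise(config)
  say("calibrated noise: sigma_auto = %.3f", cal$sigma_auto)

  cohort_results <- list()
  for (ci in seq_along(config$cohorts)) {
    cohort <- config$cohorts[[ci]]
    sigma <- if (identical(cohort$noise_sd, "auto")) cal$sigma_auto
             else cohort$noise_sd
    atlas <- make_activation_atlas(
      config$acq_attention, cohort$overlap_target,
      amplitude = config$amplitude, radius_mm = config$radius_mm,
      tau = config$tau, sigma_w = sigma * mean(cal$k_unit),
      n_group = cohort$n_participants,
      t_thr = config$group_threshold$t_min,
      analysis_fwhm = config$analysis_fwhm)
    conn <- make_connectivity_structure(cohort$similarity_target,
                                        n_rois = length(rois$name),
                                        seed = child_seed(cohort$seed, 7L))
    say("cohort %s: atlas + structure planted", cohort$label)
    participants <- list()
    demo <- with_rng(child_seed(cohort$seed, 3L), {
      nfem <- round(cohort$prop_female * cohort$n_participants)
      gender <- sample(rep(c("female", "male"),
                           c(nfem, cohort$n_participants - nfem)))
      data.frame(gender = gender,
                 gpa = round(pmin(10, pmax(7, stats::rnorm(
                   cohort$n_participants, 8.7, 0.6))), 1),
                 ability = stats::rnorm(cohort$n_participants, 0,
                                        behavior_defaults()$participant_sd))
    })
    bd <- behavior_defaults()
    for (p in seq_len(cohort$n_participants)) {
      shift <- cohort$accuracy_shift +
        bd$gender_shift[[demo$gender[p]]] + demo$ability[p]
      participants[[p]] <- simulate_participant(config, cohort, atlas, conn,
                                                rois, p, sigma, shift,
                                                cal$amp_factors)
      say("cohort %s participant %d/%d", cohort$label, p,
          cohort$n_participants)
    }
    cohort_results[[cohort$label]] <- list(cohort = cohort, atlas = atlas,
                                           conn = conn, demo = demo,
                                           participants = participants)
  }

  report <- summarize_pipeline(config, cohort_results, rois, labels, cal)
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  say("done")
  report
}

summarize_pipeline <- function(config, cohort_results, rois, labels, cal) {
  task_names <- TASK_TYPES
  per_cohort <- list()
  group_conj_all4 <- list()
  zt_by_cohort <- list()
  for (lab in names(cohort_results)) {
    cr <- cohort_results[[lab]]
    parts <- cr$participants
    # group-level activation analysis
    cls <- list()
    for (nm in task_names) {
      gmap <- group_level_t(lapply(parts, function(p) p$effect_maps[[nm]]))
      cls[[nm]] <- threshold_and_cluster(gmap, config$group_threshold,
                                         affine =
                                           config$acq_attention$affine)
    }
    ovl <- overlap_matrix(cls)
    conj <- conjunction_count_map(cls)
    group_conj_all4[[lab]] <- conj == 4
    # participant-level overlap at the liberal threshold
    p_ovl <- lapply(parts, function(p)
      participant_overlap_analysis(
        lapply(p$t_maps, function(tm)
          structure(list(t = tm, mask = NULL), class = "contrast_map")),
        spec = config$participant_threshold))
    p_overlap <- do.call(rbind, lapply(p_ovl, `[[`, "overlaps"))
    p_counts <- do.call(rbind, lapply(p_ovl, `[[`, "counts"))
    # cohort z table: connections x tasks, averaged over participants
    zt <- sapply(task_names, function(task)
      rowMeans(sapply(parts, function(p) as.numeric(p$zvecs[[task]]))))
    rownames(zt) <- labels$connection
    zt_by_cohort[[lab]] <- zt
    csim <- cohort_connection_similarity(zt)
    emb <- mds_embed(csim, dim = config$mds_dim)
    dt <- distance_table(emb$points, labels, cohort = lab)
    # co-emitted alternatives: full-rank embedding and raw 1 - r distances
    emb_full <- mds_embed(csim, dim = nrow(csim) - 1)
    dt_full <- distance_table(emb_full$points, labels, cohort = lab)
    # participant-level cross-task similarity, averaged
    psim <- Reduce(`+`, lapply(parts, function(p)
      participant_task_similarity(p$zvecs))) / length(parts)
    z_arr <- array(unlist(lapply(parts, function(p)
      sapply(task_names, function(task) as.numeric(p$zvecs[[task]])))),
      c(nrow(zt), 4, length(parts)))
    per_cohort[[lab]] <- list(
      overlap = ovl, realized_truth = cr$atlas$realized,
      conn_similarity = csim, embedding = emb, distances = dt,
      mean_distance = mean(dt$distance),
      mean_distance_fullrank = mean(dt_full$distance),
      mean_correlation_distance = mean(1 - csim[upper.tri(csim)]),
      participant_task_similarity = psim,
      planted_similarity = cr$conn$realized,
      participant_overlap = p_overlap,
      participant_counts = p_counts,
      mean_participant_overlap = mean(p_overlap),
      z_participants = z_arr,
      cluster_tables = lapply(cls, `[[`, "table"),
      qc = data.frame(
        dvars_mean = vapply(parts, `[[`, numeric(1), "dvars_mean"),
        n_outliers = vapply(parts, `[[`, numeric(1), "n_outliers"),
        excluded = vapply(parts, `[[`, logical(1), "excluded")))
  }

  # cross-cohort similarity-matrix comparisons
  labs <- names(cohort_results)
  comparisons <- list()
  for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
    key <- paste(labs[i], labs[j], sep = " vs ")
    cmp <- matrix_similarity_test(
      per_cohort[[labs[i]]]$conn_similarity,
      per_cohort[[labs[j]]]$conn_similarity,
      n_perm = config$n_perm,
      seed = child_seed(config$seed, 40L, i, j))
    cmp$p_difference_participants <- cohort_difference_test(
      per_cohort[[labs[i]]]$z_participants,
      per_cohort[[labs[j]]]$z_participants,
      n_perm = config$n_perm,
      seed = child_seed(config$seed, 41L, i, j))$p
    # Bonferroni union of the level-offset and structure tests: valid at
    # level alpha, powerful against either kind of cohort difference
    cmp$p_difference_combined <- min(1, 2 * min(cmp$p_difference,
                                                cmp$p_difference_participants))
    comparisons[[key]] <- cmp
  }

  # distance ANOVAs (mixed-type rows excluded from the type factor)
  all_dist <- do.call(rbind, lapply(per_cohort, `[[`, "distances"))
  hemi_rows <- all_dist[all_dist$hemisphere_type != "mixed", , drop = FALSE]
  range_rows <- all_dist[all_dist$range_type != "mixed", , drop = FALSE]
  anova_hemi <- univariate_anova(hemi_rows, "distance",
                                 c("cohort", "hemisphere_type"))
  anova_range <- univariate_anova(range_rows, "distance",
                                  c("cohort", "range_type"))

  # behavioral analysis with the published exclusion rule
  beh_long <- list(); blocks_all <- list()
  for (lab in labs) {
    cr <- cohort_results[[lab]]
    for (p in seq_along(cr$participants)) {
      bl <- cr$participants[[p]]$blocks
      bl$participant <- paste(lab, p, sep = "_")
      blocks_all[[length(blocks_all) + 1]] <- bl
    }
  }
  blocks_all <- do.call(rbind, blocks_all)
  excl <- exclude_outlier_blocks(blocks_all)
  for (lab in labs) {
    cr <- cohort_results[[lab]]
    for (p in seq_along(cr$participants)) {
      pid <- paste(lab, p, sep = "_")
      keep <- excl$retained[excl$retained$participant == pid, , drop = FALSE]
      sc <- suppressWarnings(
        compute_task_scores(cr$participants[[p]]$events, keep))
      beh_long[[length(beh_long) + 1]] <- data.frame(
        participant = pid, cohort = lab,
        gender = cr$demo$gender[p], gpa = cr$demo$gpa[p],
        task = names(sc), score = as.numeric(sc),
        stringsAsFactors = FALSE)
    }
  }
  beh_long <- do.call(rbind, beh_long)
  beh_anova <- rm_ancova(beh_long, dv = "score", within = "task",
                         id = "participant", between = c("cohort", "gender"),
                         covariate = "gpa")

  # derived ROIs from the all-four conjunctions (reported, not re-used)
  derived <- tryCatch(
    derive_executive_rois(group_conj_all4, config$acq_attention$affine,
                          prototypes = rois),
    warning = function(w) roi_set(character(0), matrix(numeric(0), 0, 3), 7))

  structure(list(
    config_summary = list(seed = config$seed,
                          n_cohorts = length(config$cohorts),
                          grid = config$acq_attention$grid_shape,
                          sigma_auto = cal$sigma_auto,
                          config_hash = config_hash(config)),
    rois = rois, connection_labels = labels,
    per_cohort = per_cohort, comparisons = comparisons,
    anova_hemisphere = anova_hemi, anova_range = anova_range,
    behavior = list(long = beh_long, anova = beh_anova,
                    cutoffs = excl$cutoffs,
                    n_excluded_blocks = nrow(excl$excluded)),
    derived_rois = derived,
    zt_by_cohort = zt_by_cohort),
    class = "run_report")
}

# stable hash of a configuration (FNV-1a over its serialization)
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw[seq(1, length(raw), by = 7)])) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a run report to disk
#'
#' JSON summary plus CSV/TSV tables (overlap matrices, similarity
#' matrices, embeddings, distance tables, behavioral scores).
#'
#' @param report a `run_report`
#' @param dir output directory (created if needed)
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(report$per_cohort)) {
    pc <- report$per_cohort[[lab]]
    utils::write.csv(pc$overlap, file.path(dir,
                                           paste0("overlap_", lab, ".csv")))
    utils::write.csv(pc$conn_similarity,
                     file.path(dir, paste0("conn_similarity_", lab, ".csv")))
    emb <- data.frame(node = rownames(pc$embedding$points) %||%
                        seq_len(nrow(pc$embedding$points)),
                      pc$embedding$points)
    utils::write.table(emb, file.path(dir, paste0("embedding_", lab, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(pc$distances,
                       file.path(dir, paste0("distances_", lab, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(report$behavior$long,
                     file.path(dir, "behavior_scores.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary <- list(
    config = report$config_summary,
    mean_distance = lapply(report$per_cohort, `[[`, "mean_distance"),
    overlap = lapply(report$per_cohort, `[[`, "overlap"),
    planted_overlap = lapply(report$per_cohort, `[[`, "realized_truth"),
    comparisons = report$comparisons,
    behavior_cutoffs = report$behavior$cutoffs,
    behavior_effects = report$behavior$anova$effects)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Behavioral power study
#'
#' Repeatedly simulates full-cohort behavior at the published scale
#' (57/57/53 participants) with the generator defaults, runs the
#' repeated-measures ANCOVA, and reports how often the Age Cohort main
#' effect is significant with the middle-adolescent cohort lowest and
#' Bonferroni-separated from both older cohorts.
#'
#' @param n_reps replicates
#' @param n_per_cohort cohort sizes
#' @param seed master seed
#' @param alpha significance level
#' @return list: `success_rate`, plus per-replicate detail
#' @export
behavior_power_study <- function(n_reps = 100L,
                                 n_per_cohort = c(57L, 57L, 53L),
                                 seed = 1L, alpha = 0.05) {
  labs <- c("middle_adolescent", "late_adolescent", "young_adult")
  bd <- behavior_defaults()
  schedules <- c(lapply(1:3, function(r)
    build_attention_schedule(r, seed = child_seed(seed, 61L, r))),
    lapply(1:2, function(r)
      build_nback_schedule(r, seed = child_seed(seed, 62L, r))))
  events0 <- do.call(rbind, schedules)
  ok <- logical(n_reps)
  detail <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    rows <- list()
    for (ci in 1:3) for (p in seq_len(n_per_cohort[ci])) {
      pseed <- child_seed(seed, 70L, rep, ci, p)
      gender <- if (p %% 2 == 0) "female" else "male"
      shift <- bd$cohort_shifts[[labs[ci]]] + bd$gender_shift[[gender]] +
        with_rng(child_seed(pseed, 1L),
                 stats::rnorm(1, 0, bd$participant_sd))
      ev <- simulate_behavior(events0, seed = child_seed(pseed, 2L),
                              participant_shift = shift)
      bl <- block_scores(ev)
      bl$participant <- paste(ci, p, sep = "_")
      rows[[length(rows) + 1]] <- list(ev = ev, bl = bl,
                                       cohort = labs[ci], gender = gender,
                                       gpa = with_rng(child_seed(pseed, 3L),
                                         round(stats::rnorm(1, 8.7, 0.6), 1)))
    }
    blocks <- do.call(rbind, lapply(rows, `[[`, "bl"))
    excl <- exclude_outlier_blocks(blocks)
    long <- do.call(rbind, lapply(rows, function(rr) {
      pid <- rr$bl$participant[1]
      keep <- excl$retained[excl$retained$participant == pid, , drop = FALSE]
      sc <- suppressWarnings(compute_task_scores(rr$ev, keep))
      data.frame(participant = pid, cohort = rr$cohort, gender = rr$gender,
                 gpa = rr$gpa, task = names(sc), score = as.numeric(sc),
                 stringsAsFactors = FALSE)
    }))
    an <- rm_ancova(long, dv = "score", within = "task", id = "participant",
                    between = c("cohort", "gender"), covariate = "gpa")
    eff <- an$effects
    p_cohort <- eff$p_used[eff$term == "cohort"]
    means <- tapply(long$score, long$cohort, mean, na.rm = TRUE)
    ph <- an$posthoc$cohort
    sep <- all(ph$p_bonferroni[grepl("middle", ph$pair)] < alpha)
    ok[rep] <- is.finite(p_cohort) && p_cohort < alpha &&
      which.min(means[labs]) == 1 && sep
    detail[[rep]] <- list(p_cohort = p_cohort, means = means, ok = ok[rep])
  }
  list(success_rate = mean(ok), detail = detail)
}
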