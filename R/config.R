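# Plain-text configuration (flat TOML dialect) and the command-line
# entry point logic. The CLI wrapper script lives in inst/cli/execonn.R.

#' Read a flat TOML-dialect configuration file
#'
#' Supports `[section]` headers, `key = value` pairs with strings, numbers,
#' booleans and flat arrays, and `#` comments. Nested tables are not
#' supported (the pipeline configuration is flat).
#'
#' @param path file path
#' @return nested named list (one element per section; top-level keys under
#'   `$global`)
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- "global"
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      inner <- substr(v, 2, nchar(v) - 1)
      if (trimws(inner) == "") return(list())
      parts <- strsplit(inner, ",")[[1]]
      return(unlist(lapply(parts, parse_val)))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (grepl("^'.*'$", v)) return(gsub("^'|'$", "", v))
    if (v %in% c("true", "false")) return(v == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) return(n)
    v
  }
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- trimws(substr(ln, 2, nchar(ln) - 1))
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stopf("cannot parse config line: %s", ln)
    out[[section]][[trimws(kv[2])]] <- parse_val(kv[3])
  }
  out
}

#' Build a `pipeline_config` from a parsed configuration list
#'
#' Unspecified fields fall back to the desk-scale defaults.
#'
#' @param cfg list from [read_config()] (or an empty list)
#' @param seed seed override (e.g. from the command line)
#' @param out_dir output directory override
#' @return a [pipeline_config()]
#' @export
config_from_list <- function(cfg, seed = NULL, out_dir = NULL) {
  g <- cfg$global %||% list()
  seed <- as.integer(seed %||% g$seed %||% 1L)
  n <- as.integer(g$n_per_cohort %||% 12L)
  base <- default_desk_config(seed = seed, n_per_cohort = n)
  labs <- vapply(base$cohorts, `[[`, character(1), "label")
  for (i in seq_along(base$cohorts)) {
    sec <- cfg[[labs[i]]]
    if (is.null(sec)) next
    for (f in c("n_participants", "overlap_target", "similarity_target",
                "accuracy_shift", "noise_sd", "roi_noise_sd"))
      if (!is.null(sec[[f]])) base$cohorts[[i]][[f]] <- sec[[f]]
  }
  for (f in c("analysis_fwhm", "amplitude", "radius_mm", "tau",
              "hp_cutoff_seconds", "n_perm", "mds_dim",
              "n_runs_attention", "n_runs_nback"))
    if (!is.null(g[[f]])) base[[f]] <- g[[f]]
  if (!is.null(g$group_t) || !is.null(g$group_k))
    base$group_threshold <- threshold_spec(g$group_t %||% 2.7,
                                           g$group_k %||% 25L)
  if (!is.null(g$roi_mode)) base$roi_mode <- g$roi_mode
  base$out_dir <- out_dir %||% g$out_dir
  base
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write one cohort's runs as NIfTI + events TSV +
#' motion text + ground-truth JSON), `run-all` (full pipeline + report),
#' `validate` (config checks only).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`
#' @return exit status (0 on success), invisibly
#' @export
execonn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: execonn <simulate|run-all|validate> [--config FILE]",
    "[--out DIR] [--seed INT]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(config = NULL, out = "execonn_out", seed = 1L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stopf("unknown option --%s", key)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else list()
  config <- config_from_list(cfg, seed = opt$seed, out_dir = opt$out)
  if (cmd == "validate") {
    f <- validate_config(config)
    if (nrow(f) > 0) print(f) else message("configuration ok")
    return(invisible(as.integer(any(f$level == "error"))))
  }
  if (cmd == "simulate") {
    simulate_to_dir(config, opt$out)
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    config$out_dir <- opt$out
    run_pipeline(config, progress = TRUE)
    message("report written to ", opt$out)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}

#' Write one cohort of simulated raw data to disk
#'
#' One NIfTI file per run, events as TSV, motion parameters as 6-column
#' whitespace-delimited text, and the planted ground truth as JSON.
#'
#' @param config a `pipeline_config` (first cohort is written)
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  validate_config(config, stop_on_error = TRUE)
  cohort <- config$cohorts[[1]]
  rois <- resolve_rois(config)
  cal <- calibrate_noise(config)
  sigma <- if (identical(cohort$noise_sd, "auto")) cal$sigma_auto
           else cohort$noise_sd
  atlas <- make_activation_atlas(
    config$acq_attention, cohort$overlap_target,
    amplitude = config$amplitude, radius_mm = config$radius_mm,
    tau = config$tau, sigma_w = sigma * mean(cal$k_unit),
    n_group = cohort$n_participants, t_thr = config$group_threshold$t_min,
    analysis_fwhm = config$analysis_fwhm)
  conn <- make_connectivity_structure(cohort$similarity_target,
                                      n_rois = length(rois$name),
                                      seed = child_seed(cohort$seed, 7L))
  bd <- behavior_defaults()
  conn_mats <- c(conn$matrices, list(base = Reduce(`+`, conn$matrices) / 4))
  for (p in seq_len(cohort$n_participants)) {
    pseed <- child_seed(cohort$seed, 1000L, p)
    g <- stats::setNames(as.list(
      with_rng(child_seed(pseed, 5L), stats::rnorm(4, 1, config$tau)) *
        cal$amp_factors),
      TASK_TYPES)
    specs <- list(attention = list(n = config$n_runs_attention,
                                   acq = config$acq_attention,
                                   build = build_attention_schedule),
                  nback = list(n = config$n_runs_nback,
                               acq = config$acq_nback,
                               build = build_nback_schedule))
    for (task in names(specs)) {
      sp <- specs[[task]]
      for (r in seq_len(sp$n)) {
        rseed <- child_seed(pseed, if (task == "attention") 10L else 20L, r)
        ev <- sp$build(r, sp$acq, seed = rseed)
        ev <- simulate_behavior(ev, seed = child_seed(rseed, 2L),
                                participant_shift = cohort$accuracy_shift)
        sim <- simulate_bold(ev, sp$acq,
                             amplitude_maps =
                               condition_amplitude_maps(atlas, g, task),
                             rois = rois, conn_matrices = conn_mats,
                             noise_sd = sigma,
                             roi_noise_sd = cohort$roi_noise_sd,
                             seed = child_seed(rseed, 3L),
                             motion_step_mm = cohort$motion_step_mm)
        stem <- file.path(dir, sprintf("sub-%02d_task-%s_run-%d", p, task, r))
        write_nifti(sim$vol, paste0(stem, "_bold.nii.gz"))
        write_events_tsv(ev, paste0(stem, "_events.tsv"))
        utils::write.table(sim$motion, paste0(stem, "_motion.txt"),
                           row.names = FALSE, col.names = FALSE)
      }
    }
  }
  jsonlite::write_json(
    list(seed = config$seed, cohort = cohort$label,
         overlap_targets = atlas$targets,
         realized_overlap = atlas$realized,
         planted_similarity = conn$realized,
         roi_centers = rois$centers_mm,
         sigma = sigma),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
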