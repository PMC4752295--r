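# Pipeline orchestration: per-window feature extraction over a cohort,
# the feature manifest, the end-to-end run directory, and a small CLI.

META_COLUMNS <- c("subject_id", "window_index", "stage", "severity",
                  "severity_cont", "label")

#' Feature columns of a feature table
#'
#' @param table feature table data frame.
#' @return character vector of non-meta column names.
#' @export
feature_columns <- function(table) setdiff(names(table), META_COLUMNS)

#' The frozen feature manifest
#'
#' Enumerates every feature the pipeline emits, with its family tag:
#' 554 `morphology`, 64 `tautstring`, 120 `dtcwt`, 10 `hrv_traditional`
#' (748 in total).
#'
#' @param eps_grid taut-string epsilon grid (must match extraction).
#' @return data frame `name`, `family`.
#' @export
feature_manifest <- function(eps_grid = c(4, 8, 16, 32, 64, 128, 256, 512)) {
  rbind(
    data.frame(name = morphology_feature_names(), family = "morphology"),
    data.frame(name = ts_feature_names(eps_grid), family = "tautstring"),
    data.frame(name = dtcwt_feature_names(), family = "dtcwt"),
    data.frame(name = hrv_feature_names(), family = "hrv_traditional")
  )
}

#' Names of the "presented" feature group
#'
#' The novel families (morphology + taut string + DTCWT), as opposed to
#' the 10 traditional HRV indices.
#'
#' @param eps_grid taut-string epsilon grid.
#' @return character vector.
#' @export
presented_feature_names <- function(eps_grid = c(4, 8, 16, 32, 64, 128, 256, 512)) {
  c(morphology_feature_names(), ts_feature_names(eps_grid),
    dtcwt_feature_names())
}

# Extract all features from one processed window.
window_features <- function(wf_samples, fs, r_loc, eps_grid) {
  fid <- delineate_pqst(wf_samples, fs, r_loc)
  fid <- augment_missing_peaks(fid)
  norm <- normalize_amplitude(wf_samples, fid, fs)
  z <- rr_series(r_times = r_loc)
  c(
    morphology_features(norm$fiducials),
    ts_feature_set(z, eps_grid),
    dtcwt_feature_set(dtcwt_decompose(norm$samples)),
    hrv_features(z)
  )
}

#' Build the windows-by-features table for a cohort
#'
#' For each record: a provisional R-peak pass (wavelet filter + detector)
#' on the full record defines beat positions; tumbling beat-count windows
#' are cut; each window is baseline-corrected (degree-6 polynomial),
#' Savitzky-Golay smoothed, wavelet high-pass filtered, re-delineated,
#' normalized, and passed to the four feature extractors. Window rows are
#' tagged with subject, window index, stage (midpoint rule), quantized
#' severity and class label; final-stage windows carry an `NA` label.
#'
#' @param cohort list of `ecg_record`.
#' @param beats_per_window window size in beats (default 120).
#' @param baseline_degree polynomial degree for baseline removal.
#' @param sg_frame,sg_order Savitzky-Golay parameters.
#' @param eps_grid taut-string epsilon grid (ms).
#' @param verbose print per-record progress.
#' @return feature table data frame (meta columns + 748 features).
#' @export
build_feature_table <- function(cohort, beats_per_window = 120L,
                                baseline_degree = 6L,
                                sg_frame = 15L, sg_order = 2L,
                                eps_grid = c(4, 8, 16, 32, 64, 128, 256, 512),
                                verbose = FALSE) {
  rows <- list()
  for (rec in cohort) {
    if (verbose) message("record ", rec$subject_id)
    filt <- filter_lowfreq_wavelet(rec$samples, rec$fs)
    r_times <- detect_r_peaks(filt, rec$fs)
    if (length(r_times) < beats_per_window) {
      warning("record ", rec$subject_id, " has too few beats; skipped")
      next
    }
    wins <- segment_windows(rec, r_times, beats_per_window)
    n_stages_total <- length(rec$stage_boundaries)
    lab <- make_labels(n_stages_total)
    for (w in wins) {
      feats <- tryCatch({
        dt <- remove_baseline_poly(w, baseline_degree)
        sm <- smooth_savitzky_golay(dt$samples, sg_frame, sg_order)
        wf <- filter_lowfreq_wavelet(sm, w$fs)
        r_loc <- detect_r_peaks(wf, w$fs)
        if (length(r_loc) < max(10, beats_per_window / 2)) {
          stop("window re-detection failed")
        }
        window_features(wf, w$fs, r_loc, eps_grid)
      }, error = function(e) {
        warning("window ", w$window_index, " of ", w$subject_id,
                " skipped: ", conditionMessage(e))
        NULL
      })
      if (is.null(feats)) next
      li <- match(w$stage, lab$stage)
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = w$subject_id, window_index = w$window_index,
             stage = w$stage,
             severity = if (is.na(li)) NA_real_ else lab$severity[li],
             severity_cont = if (is.na(li)) NA_real_ else lab$severity_cont[li],
             label = if (is.na(li)) NA_character_ else lab$label[li]),
        as.list(feats)
      )
    }
  }
  if (length(rows) == 0) stop("no usable windows in cohort")
  tab <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

# Small deterministic config hash (FNV-1a over the deparsed config).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

#' Default demonstration pipeline configuration
#'
#' A small synthetic cohort sized so the full pipeline completes in a few
#' minutes on one CPU.
#'
#' @param out_dir run directory.
#' @param seed master seed.
#' @return named list of configuration keys.
#' @export
demo_config <- function(out_dir = tempfile("hemowatch_run_"), seed = 1L) {
  list(
    n_subjects = 12L, seed = as.integer(seed),
    stage_duration = 60, final_stage_range = c(30, 60),
    snr_db = 20, wander_amp = 0.08,
    beats_per_window = 30L, baseline_degree = 6L,
    sg_frame = 15L, sg_order = 2L,
    eps_grid = c(4, 8, 16, 32, 64, 128, 256, 512),
    corr_threshold = 0.9, select_k = 10L, select_folds = 10L,
    C_grid = 2^seq(-6, 8, by = 2),
    out_dir = out_dir
  )
}

#' Run the complete pipeline
#'
#' Simulation (or loading), feature extraction, two-stage feature
#' selection, nested-CV SVM evaluation for both feature groups, and a
#' provenance log, all written into `config$out_dir`. Identical
#' config + seed gives identical outputs.
#'
#' @param config list as produced by [demo_config()]; `input_dir` may
#'   replace the synthetic-cohort keys (directory of CSV records written
#'   by [write_ecg_csv()]).
#' @return invisibly, a list with the run artifacts (`table`,
#'   `selection`, `cv_presented`, `cv_hrv`, `comparison`, `out_dir`).
#' @export
run_pipeline <- function(config = demo_config()) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, what) {
    timings[[what]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  s <- tic()
  cohort <- if (!is.null(config$input_dir)) {
    files <- list.files(config$input_dir, pattern = "\\.csv$", full.names = TRUE)
    lapply(files, read_ecg_csv)
  } else {
    simulate_cohort(config$n_subjects, seed = config$seed,
                    stage_duration = config$stage_duration,
                    final_stage_range = config$final_stage_range,
                    snr_db = config$snr_db, wander_amp = config$wander_amp)
  }
  toc(s, "simulate")

  s <- tic()
  tab <- build_feature_table(cohort,
                             beats_per_window = config$beats_per_window,
                             baseline_degree = config$baseline_degree,
                             sg_frame = config$sg_frame,
                             sg_order = config$sg_order,
                             eps_grid = config$eps_grid)
  toc(s, "extract")
  write.csv(tab, file.path(config$out_dir, "feature_table.csv"),
            row.names = FALSE)
  write.csv(feature_manifest(config$eps_grid),
            file.path(config$out_dir, "feature_manifest.csv"),
            row.names = FALSE)

  s <- tic()
  usable <- feature_columns(tab)
  complete <- usable[vapply(usable, function(f) all(is.finite(tab[[f]])), logical(1))]
  cbar <- mean_correlation_matrix(tab, complete)
  red <- greedy_redundancy_removal(cbar, config$corr_threshold)
  sel <- forward_select(tab, response = "severity", features = red$kept,
                        k = config$select_k, folds = config$select_folds,
                        seed = config$seed)
  toc(s, "select")
  write_selection_report(sel, file.path(config$out_dir, "selection_report.csv"))

  s <- tic()
  cv_pres <- nested_cv_svm(tab, sel$selected, seed = config$seed,
                           C_grid = config$C_grid)
  cv_hrv <- nested_cv_svm(tab, intersect(hrv_feature_names(), names(tab)),
                          seed = config$seed, C_grid = config$C_grid)
  cmp <- compare_feature_sets(cv_pres, cv_hrv)
  toc(s, "train")

  hash <- config_hash(config)
  report <- list(
    config_hash = hash,
    seed = config$seed,
    n_windows = nrow(tab),
    n_labeled = sum(!is.na(tab$label)),
    selected = sel$selected,
    presented = list(mean = as.list(cv_pres$mean), ci95 = as.list(cv_pres$ci95)),
    typical_hrv = list(mean = as.list(cv_hrv$mean), ci95 = as.list(cv_hrv$ci95)),
    comparison = cmp,
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "cv_report.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(c(list(config_hash = hash), config),
                       file.path(config$out_dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(table = tab, selection = sel, cv_presented = cv_pres,
                 cv_hrv = cv_hrv, comparison = cmp, out_dir = config$out_dir))
}

read_cli_config <- function(args) {
  cfgv <- grep("^--config=", args, value = TRUE)
  cfg <- demo_config()
  if (length(cfgv)) {
    user <- jsonlite::read_json(sub("^--config=", "", cfgv[1]),
                                simplifyVector = TRUE)
    cfg[names(user)] <- user
  }
  outv <- grep("^--out=", args, value = TRUE)
  if (length(outv)) cfg$out_dir <- sub("^--out=", "", outv[1])
  seedv <- grep("^--seed=", args, value = TRUE)
  if (length(seedv)) cfg$seed <- as.integer(sub("^--seed=", "", seedv[1]))
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort as CSV + truth
#' sidecars), `run` (full pipeline), `report` (print the summary of an
#' existing run directory). Options: `--config=<json>`, `--out=<dir>`,
#' `--seed=<int>`.
#'
#' @param args character vector (defaults to command-line arguments).
#' @return invisibly, the subcommand's result.
#' @export
hemowatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: hemowatch <simulate|run|report> [--config=cfg.json]",
        "[--out=dir] [--seed=int]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  cfg <- read_cli_config(args[-1])
  switch(cmd,
    simulate = {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      cohort <- simulate_cohort(cfg$n_subjects, seed = cfg$seed,
                                stage_duration = cfg$stage_duration,
                                final_stage_range = cfg$final_stage_range,
                                snr_db = cfg$snr_db,
                                wander_amp = cfg$wander_amp)
      for (rec in cohort) {
        write_ecg_csv(rec, file.path(cfg$out_dir,
                                     paste0(rec$subject_id, ".csv")))
      }
      message("wrote ", length(cohort), " records to ", cfg$out_dir)
      invisible(cfg$out_dir)
    },
    run = {
      res <- run_pipeline(cfg)
      message("run complete: ", res$out_dir)
      invisible(res)
    },
    report = {
      path <- file.path(cfg$out_dir, "cv_report.json")
      if (!file.exists(path)) stop("no cv_report.json in ", cfg$out_dir)
      rep <- jsonlite::read_json(path, simplifyVector = TRUE)
      cat(jsonlite::toJSON(rep, pretty = TRUE, auto_unbox = TRUE, digits = NA),
          "\n")
      invisible(rep)
    },
    stop("unknown subcommand: ", cmd)
  )
}
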