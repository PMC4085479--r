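#' Default pipeline configuration
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `n_subjects`, `tasks` (battery task ids), `effects`
#'   (an [effect_config()]), `kinds` (classifier kinds to run),
#'   `selection` (`"pooled"`, `"nested"` or `"none"`), `fixed_subset`
#'   (features when `selection = "none"`), `selection_args` (tuning for
#'   [select_feature_subset()]), `fit` (`"none"` for classical measures
#'   only, `"delta"` to fit point strokes, `"full"` to fit every
#'   archetype), `invalid_frac`, `n_trials` (named per-task override),
#'   `smooth` (low-pass the speed profiles; off by default because the
#'   simulated recordings are noiseless), `rate`, `seed`, `out_dir`.
#' @return config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_subjects = 120L,
    tasks = c("2", "3", "4", "5", "6", "7", "1", "9"),
    effects = default_risk_effects(),
    kinds = c("logistic", "lda"),
    selection = "pooled",
    fixed_subset = NULL,
    selection_args = list(),
    fit = "delta",
    invalid_frac = 0.08,
    n_trials = list(),
    smooth = FALSE,
    rate = 200,
    seed = 1L,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

# Tasks #1 and #9 (signatures) are pooled into one reporting column.
matrix_task_id <- function(task_id) {
  ifelse(task_id %in% c("1", "9"), "1&9", task_id)
}

# Fit one recording according to the pipeline fit mode; NULL when the
# mode asks for classical measures only.
fit_for_mode <- function(rec, sp, cfg_task, mode) {
  if (mode == "none") return(NULL)
  if (cfg_task$archetype == "point_stroke")
    return(tryCatch(fit_delta_lognormal(sp), error = function(e) NULL))
  if (mode != "full") return(NULL)
  if (cfg_task$archetype == "stroke_sequence")
    tryCatch(fit_sigma_lognormal(sp), error = function(e) NULL)
  else
    tryCatch(fit_omega_lognormal(sp), error = function(e) NULL)
}

#' Run the full simulation-to-AUC pipeline
#'
#' Generates a cohort, simulates every subject's sessions, applies the
#' protocol validity rules, computes speed profiles (and model fits,
#' depending on the configured fit mode), aggregates the per-subject
#' feature tables and produces one AUC matrix per classifier kind.
#' Deterministic given the master seed; artifacts are stamped with the
#' seed and a config hash, and the trial log records every rejection
#' with its reasons.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `cohort`,
#'   `feature_tables` (one per reporting task column), `auc_matrices`
#'   (one per classifier kind), `trial_log`, `config`, `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  spec <- cohort_spec(n_subjects = config$n_subjects, seed = seed)
  cohort <- apply_risk_effects(generate_cohort(spec), config$effects)
  rows <- list()
  log <- list()
  for (task in config$tasks) {
    cfg_task <- task_config(task)
    for (si in seq_len(nrow(cohort))) {
      subj <- cohort[si, ]
      trials <- generate_session(
        subj, cfg_task, seed = derive_seed(seed, "trials", task),
        invalid_frac = config$invalid_frac,
        n_trials = config$n_trials[[task]], rate = config$rate)
      for (rec in trials) {
        sp <- tryCatch(compute_speed_profile(rec, smooth = config$smooth),
                       error = function(e) NULL)
        rep <- validate_trial(rec, cfg_task, sp = sp)
        if (!rep$valid) {
          log[[length(log) + 1L]] <- list(
            subject_id = subj$subject_id, task_id = task,
            trial_index = rec$meta$trial_index, reasons = rep$reasons)
          next
        }
        fit <- fit_for_mode(rec, sp, cfg_task, config$fit)
        segs <- rec$meta$segments
        pieces <- if (cfg_task$kind == "metronome" && !is.null(segs)) {
          list(`8_adaptation` = crop_recording(rec, segs$adaptation[1], segs$adaptation[2]),
               `8_steady` = crop_recording(rec, segs$steady[1], segs$steady[2]))
        } else setNames(list(rec), task)
        for (piece_id in names(pieces)) {
          prec <- pieces[[piece_id]]
          psp <- if (identical(piece_id, task)) sp else
            tryCatch(compute_speed_profile(prec, smooth = config$smooth),
                     error = function(e) NULL)
          if (is.null(psp)) next
          mrow <- tryCatch(trial_measures(prec, fit = fit, sp = psp),
                           error = function(e) NULL)
          if (is.null(mrow)) next
          mrow$subject_id <- subj$subject_id
          mrow$task_id <- piece_id
          mrow$trial_index <- rec$meta$trial_index
          mrow$valid <- TRUE
          if (!is.null(rec$meta$distance)) {
            mrow$distance <- rec$meta$distance
            mrow$width <- rec$meta$width
          }
          rows[[length(rows) + 1L]] <- mrow
        }
      }
    }
  }
  trial_df <- rbind_fill(rows)
  if (is.null(trial_df) || !nrow(trial_df)) stopf("no valid trials were produced")
  feature_tables <- list()
  for (mt in unique(matrix_task_id(trial_df$task_id))) {
    sub <- trial_df[matrix_task_id(trial_df$task_id) == mt, ]
    feature_tables[[mt]] <- build_feature_table(
      transform(sub, task_id = matrix_task_id(task_id)))
  }
  labels_df <- cohort[, c("subject_id", RISK_FACTORS)]
  matrices <- list()
  for (kind in config$kinds) {
    matrices[[kind]] <- do.call(build_auc_matrix, c(
      list(tables = feature_tables, labels_df = labels_df, kind = kind,
           selection = config$selection, fixed_subset = config$fixed_subset),
      config$selection_args))
  }
  res <- structure(list(
    cohort = cohort, feature_tables = feature_tables,
    auc_matrices = matrices, trial_log = log,
    config = config, seed = seed,
    config_hash = sprintf("%08x", derive_seed(
      0L, paste(deparse(config[setdiff(names(config), "out_dir")]),
                collapse = "")))),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

# Write feature tables, AUC matrices, per-cell ROC curves, the rejection
# log (JSON lines) and the run metadata under `dir`.
write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mt in names(res$feature_tables))
    write_feature_table(res$feature_tables[[mt]],
                        file.path(dir, sprintf("features_task_%s.csv",
                                               gsub("&", "_", mt))))
  for (kind in names(res$auc_matrices)) {
    m <- res$auc_matrices[[kind]]
    write_auc_matrix(m, file.path(dir, sprintf("auc_matrix_%s.csv", kind)))
    runs <- attr(m, "runs")
    roc_dir <- file.path(dir, paste0("roc_", kind))
    dir.create(roc_dir, showWarnings = FALSE)
    for (cell in names(runs)) {
      run <- runs[[cell]]
      rc <- roc_curve(run$prob, run$labels)
      write.csv(data.frame(threshold = rc$thresholds, fpr = rc$fpr,
                           tpr = rc$tpr),
                file.path(roc_dir, paste0(gsub("[:&]", "_", cell), ".csv")),
                row.names = FALSE)
    }
  }
  con <- file(file.path(dir, "rejections.jsonl"), "w")
  for (e in res$trial_log)
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE), con)
  close(con)
  jsonlite::write_json(list(seed = res$seed, config_hash = res$config_hash,
                            n_subjects = res$config$n_subjects,
                            tasks = res$config$tasks,
                            fit = res$config$fit,
                            selection = res$config$selection),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
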