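#' Classical kinematic measures and flattened model parameters of a trial
#'
#' Computes the per-trial quantities that feed the subject feature
#' table: reaction time (motion onset minus stimulus onset), kinematic
#' reaction time (fitted command onset minus stimulus onset), movement
#' duration (5%-of-peak onset to offset), peak speed, time to peak speed
#' (from motion onset) and end-to-end amplitude, plus the fitted model
#' parameters — the seven delta-lognormal parameters for point strokes,
#' or component count and mean amplitude/log-delay/log-spread aggregates
#' for sigma- and omega-lognormal fits.
#'
#' @param rec a [trial_recording()].
#' @param fit optional `fit_result`; when omitted only the classical
#'   measures are returned.
#' @param sp optional precomputed [compute_speed_profile()].
#' @return one-row `data.frame` of measures.
#' @export
trial_measures <- function(rec, fit = NULL, sp = NULL) {
  if (!inherits(rec, "trial_recording")) stopf("rec must be a trial_recording")
  if (is.null(sp)) sp <- compute_speed_profile(rec)
  task <- as.character(rec$meta$task_id %||% NA)
  has_stim <- !identical(task_stimulus_kind(task), "none")
  stim <- rec$meta$stimulus_onset
  if (has_stim && is.null(stim))
    stopf("stimulus onset missing for stimulus task %s", task)
  onset <- motion_onset(sp$t, sp$v)
  offset <- motion_offset(sp$t, sp$v)
  ip <- which.max(sp$v)
  down <- which(rec$pen_down)
  amp <- if (length(down) >= 2L)
    sqrt((rec$x[down[length(down)]] - rec$x[down[1]])^2 +
           (rec$y[down[length(down)]] - rec$y[down[1]])^2) else 0
  out <- data.frame(
    reaction_time = if (has_stim && !is.na(onset)) onset - stim else NA_real_,
    movement_duration = if (!is.na(onset)) offset - onset else NA_real_,
    peak_speed = max(sp$v),
    time_to_peak = if (!is.na(onset)) sp$t[ip] - onset else NA_real_,
    amplitude = amp)
  if (!is.null(fit)) {
    p <- fit$params
    if (inherits(p, "delta_lognormal_params")) {
      out$t0 <- p$t0
      out$kinematic_rt <- if (has_stim) p$t0 - stim else NA_real_
      out$D1 <- p$agonist$D;     out$mu1 <- p$agonist$mu
      out$sigma1 <- p$agonist$sigma
      out$D2 <- p$antagonist$D;  out$mu2 <- p$antagonist$mu
      out$sigma2 <- p$antagonist$sigma
    } else {
      comps <- model_components(p)
      out$n_components <- length(comps)
      out$mean_D <- mean(vapply(comps, `[[`, 0, "D"))
      out$mean_mu <- mean(vapply(comps, `[[`, 0, "mu"))
      out$mean_sigma <- mean(vapply(comps, `[[`, 0, "sigma"))
      first_t0 <- min(vapply(comps, `[[`, 0, "t0"))
      out$t0 <- first_t0
      out$kinematic_rt <- if (has_stim) first_t0 - stim else NA_real_
    }
    out$fit_snr_db <- fit$snr_db
  }
  out
}

# Stimulus kind for a task id without building the full config (tolerates
# segment-suffixed oscillation task ids such as "8_adaptation").
task_stimulus_kind <- function(task_id) {
  root <- sub("_.*$", "", as.character(task_id))
  if (is.na(root) || !root %in% as.character(1:9)) return("none")
  task_config(root)$stimulus
}

#' Aggregate trial measures into one subject-task feature row
#'
#' For every measure `m` over the valid trials of one subject and task,
#' two robust features are emitted: the central tendency `med_m`
#' (median) and the spread `mad_m` (median of the absolute deviations
#' from the median, unscaled).  Both are permutation-invariant over
#' trials; a single trial yields a MAD of zero.
#'
#' @param trials `data.frame` of [trial_measures()] rows (valid trials
#'   only).
#' @return one-row `data.frame` of `med_*` and `mad_*` features plus
#'   `n_valid_trials`, or `NULL` when no valid trial is available (the
#'   missing subject-task marker; excluded downstream).
#' @export
aggregate_subject <- function(trials) {
  if (is.null(trials) || !nrow(trials)) return(NULL)
  num <- vapply(trials, is.numeric, TRUE)
  out <- list()
  for (nm in names(trials)[num]) {
    x <- trials[[nm]]
    x <- x[is.finite(x)]
    if (!length(x)) next
    med <- median(x)
    out[[paste0("med_", nm)]] <- med
    out[[paste0("mad_", nm)]] <- median(abs(x - med))
  }
  out$n_valid_trials <- nrow(trials)
  as.data.frame(out)
}

#' Build the per-subject, per-task feature table
#'
#' One row per subject per task, containing the `med_`/`mad_` features
#' of [aggregate_subject()].  Only trials flagged valid contribute.  Two
#' task-specific refinements: the speed/accuracy trade-off task (#5)
#' additionally gets the per-subject slope of movement duration against
#' the Fitts index of difficulty `log2(2 * distance / width)`
#' (`fitts_slope`); the synchronized-oscillation task (#8) is split into
#' an adaptation segment (paced, first 10 s) and a steady-state segment
#' (unpaced continuation), carried as task ids `8_adaptation` and
#' `8_steady`.
#'
#' @param trial_df `data.frame` with columns `subject_id`, `task_id`,
#'   `valid` (logical) and measure columns; for task #5 also `distance`
#'   and `width`.
#' @return wide `data.frame`, one row per subject-task.
#' @export
build_feature_table <- function(trial_df) {
  stopifnot(all(c("subject_id", "task_id") %in% names(trial_df)))
  if ("valid" %in% names(trial_df)) trial_df <- trial_df[trial_df$valid %in% TRUE, ]
  if (!nrow(trial_df)) stopf("no valid trials to aggregate")
  drop_cols <- c("subject_id", "task_id", "valid", "trial_index")
  rows <- list()
  for (task in unique(trial_df$task_id)) {
    dt <- trial_df[trial_df$task_id == task, ]
    for (subj in unique(dt$subject_id)) {
      ds <- dt[dt$subject_id == subj, ]
      feats <- aggregate_subject(ds[, setdiff(names(ds), c(drop_cols, "distance", "width")),
                                    drop = FALSE])
      if (is.null(feats)) next
      if (identical(sub("_.*$", "", as.character(task)), "5") &&
          all(c("distance", "width", "movement_duration") %in% names(ds))) {
        id <- log2(2 * ds$distance / ds$width)
        ok <- is.finite(id) & is.finite(ds$movement_duration)
        feats$fitts_slope <- if (sum(ok) >= 3L && var(id[ok]) > 0)
          unname(coef(stats::lm(ds$movement_duration[ok] ~ id[ok]))[2]) else NA_real_
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject_id = subj, task_id = as.character(task),
                         stringsAsFactors = FALSE), feats)
    }
  }
  out <- do.call(rbind_fill, list(rows))
  if (anyDuplicated(out[, c("subject_id", "task_id")]))
    stopf("integrity error: duplicate subject/task rows")
  out
}

# rbind data.frames with possibly different columns, filling with NA.
rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Write / read a feature table
#'
#' The wide form (one row per subject-task) and a flat long form
#' (`subject_id`, `task_id`, `feature`, `value`) are both supported and
#' round-trip through each other.
#'
#' @param table wide feature table from [build_feature_table()].
#' @param path CSV file path.
#' @param long write the flat long form instead of the wide form.
#' @export
write_feature_table <- function(table, path, long = FALSE) {
  if (long) {
    keys <- c("subject_id", "task_id")
    vals <- setdiff(names(table), keys)
    long_df <- do.call(rbind, lapply(vals, function(f)
      data.frame(subject_id = table$subject_id, task_id = table$task_id,
                 feature = f, value = table[[f]], stringsAsFactors = FALSE)))
    write.csv(long_df, path, row.names = FALSE)
  } else {
    write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("feature", "value") %in% names(df))) {
    wide <- stats::reshape(df, idvar = c("subject_id", "task_id"),
                           timevar = "feature", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    wide$task_id <- as.character(wide$task_id)
    wide
  } else {
    df$task_id <- as.character(df$task_id)
    df
  }
}
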