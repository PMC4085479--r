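#' Configuration of the nine-task pen-tablet battery
#'
#' Returns the protocol parameters of one task of the battery: archetype
#' (`point_stroke`, `stroke_sequence` or `oscillation`), geometry, trial
#' counts, stimulus kind and validity rules.  Tasks: #1 initial
#' signatures, #2 visual simple-reaction stroke (SRT), #3 choice-reaction
#' stroke (CRT), #4 auditory SRT, #5 speed/accuracy trade-off (SAT,
#' 4 distances x 4 target widths x 2 repetitions), #6 triangular
#' three-stroke sequences (2 rotations x 3 sizes x 2 repetitions),
#' #7 maximal-speed oscillations (10 s), #8 metronome-synchronized
#' oscillations (10 s paced + 5 s continuation), #9 final signatures.
#' SRT/CRT guiding-sheet geometry imposes a minimum valid movement
#' amplitude of 130 mm.
#'
#' @param task_id task identifier, `"1"` to `"9"`.
#' @return a list of class `task_config`.
#' @export
task_config <- function(task_id) {
  task_id <- as.character(task_id)
  cfg <- switch(task_id,
    "1" = list(archetype = "stroke_sequence", kind = "signature",
               n_trials = 4L, stimulus = "none"),
    "2" = list(archetype = "point_stroke", kind = "srt",
               n_trials = 18L, min_valid_trials = 15L,
               stimulus = "visual", min_amplitude = 130,
               target_amplitude = 150),
    "3" = list(archetype = "point_stroke", kind = "crt",
               n_trials = 30L, stimulus = "visual_choice",
               min_amplitude = 130, target_amplitude = 150,
               decision_delay = 0.08),
    "4" = list(archetype = "point_stroke", kind = "srt",
               n_trials = 18L, min_valid_trials = 15L,
               stimulus = "auditory", min_amplitude = 130,
               target_amplitude = 150),
    "5" = list(archetype = "point_stroke", kind = "sat",
               stimulus = "auditory",
               distances = c(45, 90, 135, 180),
               widths = c(30, 22.5, 15, 7.5), repetitions = 2L),
    "6" = list(archetype = "stroke_sequence", kind = "triangle",
               stimulus = "auditory", sizes = c(135, 90, 45),
               rotations = c("cw", "ccw"), repetitions = 2L,
               target_diameter = 15),
    "7" = list(archetype = "oscillation", kind = "max_speed",
               stimulus = "auditory", duration = 10, n_trials = 1L),
    "8" = list(archetype = "oscillation", kind = "metronome",
               stimulus = "auditory", duration = 10, continuation = 5,
               half_period = 0.5, n_trials = 2L),
    "9" = list(archetype = "stroke_sequence", kind = "signature",
               n_trials = 1L, stimulus = "none"),
    stopf("unknown task id '%s' (expected \"1\"..\"9\")", task_id))
  cfg$task_id <- task_id
  # default speed floor used by the too-slow rejection rule (mm/s)
  cfg$min_peak_speed <- if (cfg$archetype == "point_stroke") 100 else 50
  structure(cfg, class = "task_config")
}

#' Validate a trial against its task's protocol rules
#'
#' Applies the automatic rejection rules of the acquisition protocol:
#' movements that are too slow, movements not stopped before the pen
#' lift, missing pen lift between trials, anticipated starts (motion
#' onset before the stimulus), and — for the SRT/CRT strokes — an
#' end-to-end amplitude below the 130 mm guiding-sheet minimum.
#' Learning-phase trials are rejected outright.  The check is pure: the
#' same recording and rules always yield the same report.
#'
#' @param rec a [trial_recording()].
#' @param rules a [task_config()]; defaults to the config of
#'   `rec$meta$task_id`.
#' @param sp optional precomputed [compute_speed_profile()] of `rec`.
#' @return a list of class `validity_report` with fields `valid` and
#'   `reasons` (subset of `too_slow`, `no_stop_before_lift`,
#'   `no_pen_lift_between_trials`, `anticipated_start`,
#'   `amplitude_below_minimum`, `learning_trial`).
#' @export
validate_trial <- function(rec, rules = NULL, sp = NULL) {
  if (!inherits(rec, "trial_recording")) stopf("rec must be a trial_recording")
  if (is.null(rules)) {
    if (is.null(rec$meta$task_id))
      stopf("configuration error: no task rules and no task id on the recording")
    rules <- task_config(rec$meta$task_id)
  }
  reasons <- character(0)
  if (isTRUE(rec$meta$learning)) reasons <- c(reasons, "learning_trial")
  down <- which(rec$pen_down)
  if (is.null(sp))
    sp <- tryCatch(compute_speed_profile(rec), error = function(e) NULL)
  if (is.null(sp)) {
    reasons <- c(reasons, "too_slow")
  } else {
    peak <- max(sp$v)
    if (peak < rules$min_peak_speed) reasons <- c(reasons, "too_slow")
    # the pen must be at rest before the lift
    if (sp$v[length(sp$v)] > 0.1 * peak)
      reasons <- c(reasons, "no_stop_before_lift")
    # anticipated start: motion onset before the stimulus
    if (!identical(rules$stimulus, "none")) {
      stim <- rec$meta$stimulus_onset
      if (is.null(stim)) stopf("metadata error: stimulus onset missing for task %s",
                               rules$task_id)
      onset <- motion_onset(sp$t, sp$v)
      if (!is.na(onset) && onset < stim) reasons <- c(reasons, "anticipated_start")
    }
    if (!is.null(rules$min_amplitude) && length(down)) {
      amp <- sqrt((rec$x[down[length(down)]] - rec$x[down[1]])^2 +
                    (rec$y[down[length(down)]] - rec$y[down[1]])^2)
      if (amp < rules$min_amplitude) reasons <- c(reasons, "amplitude_below_minimum")
    }
  }
  # the pen must leave the tablet between trials: the recording has to
  # end with a pen-up segment
  if (length(down) && down[length(down)] == length(rec$t))
    reasons <- c(reasons, "no_pen_lift_between_trials")
  structure(list(valid = length(reasons) == 0L, reasons = reasons),
            class = "validity_report")
}
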