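TRIAL_FORMAT_VERSION <- "1.0"

#' Write / read a trial recording
#'
#' The on-disk trial format is a CSV body with columns `t`, `x`, `y`,
#' `pen_down` plus a JSON sidecar (same path with extension `.json`)
#' holding the format version and the metadata.  Numbers are written
#' with full precision so the round trip is lossless.
#'
#' @param rec a [trial_recording()].
#' @param path CSV file path (the sidecar path is derived from it).
#' @return `write_trial`: the path, invisibly; `read_trial`: the
#'   [trial_recording()].
#' @export
write_trial <- function(rec, path) {
  if (!inherits(rec, "trial_recording")) stopf("rec must be a trial_recording")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,x,y,pen_down", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%d",
                     rec$t, rec$x, rec$y, as.integer(rec$pen_down)), con)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(c(list(format_version = TRIAL_FORMAT_VERSION),
                         rec$meta),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial
#' @param path CSV file path written by `write_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stopf("trial file not found: %s", path)
  df <- read.csv(path, colClasses = c("numeric", "numeric", "numeric",
                                      "integer"))
  need <- c("t", "x", "y", "pen_down")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("format error: missing column(s) %s in %s",
          paste(miss, collapse = ", "), path)
  if (any(diff(df$t) <= 0))
    stopf("format error: non-monotone sample times in %s", path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar))
    stopf("format error: missing metadata sidecar %s", sidecar)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  meta$format_version <- NULL
  task <- meta$task_id
  if (!is.null(task) && !identical(task_stimulus_kind(task), "none") &&
      is.null(meta$stimulus_onset))
    stopf("metadata error: stimulus onset missing for task %s in %s",
          task, sidecar)
  trial_recording(df$t, df$x, df$y, df$pen_down == 1, meta = meta)
}

# Restrict a recording to a time window (used to split the synchronized
# oscillation task into adaptation and steady-state segments).
crop_recording <- function(rec, from, to) {
  keep <- rec$t >= from & rec$t <= to
  if (sum(keep) < 2L) stopf("window [%g, %g] contains too few samples", from, to)
  trial_recording(rec$t[keep], rec$x[keep], rec$y[keep], rec$pen_down[keep],
                  meta = rec$meta)
}
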