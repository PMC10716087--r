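#' Read and write the long-format samples table
#'
#' Samples tables are comma-separated text with columns `participant_id`,
#' `trial_index`, `t_ms`, `pupil`, `gaze_x_deg`, `gaze_y_deg`, `blink_flag`.
#' The current preprocessing stage travels with the table as a `#`-prefixed
#' header line so that re-running a preprocessing step on already-processed
#' data can be refused after a round trip through disk.
#'
#' @param samples samples table (data.frame/data.table).
#' @param path file path.
#' @return `write_samples()` returns `path` invisibly; `read_samples()`
#'   returns a data.table with the recorded `pupil_stage` attribute.
#' @export
write_samples <- function(samples, path) {
  stage <- attr(samples, "pupil_stage") %||% "raw"
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# pupil_stage: ", stage), con)
  utils::write.csv(as.data.frame(samples), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  first <- readLines(path, n = 1)
  stage <- "raw"
  skip <- 0L
  if (startsWith(first, "# pupil_stage:")) {
    stage <- trimws(sub("# pupil_stage:", "", first))
    skip <- 1L
  }
  out <- data.table::fread(path, skip = skip, header = TRUE)
  attr(out, "pupil_stage") <- stage
  out
}

#' Read and write the trial-level behavioral table
#'
#' Comma-separated text: the trial-schedule fields plus `participant_id`,
#' `target_opacity_pct`, `accuracy`, `rt_ms`, `baseline_pupil`, `excluded`
#' and `exclusion_reason`.
#'
#' @param trials trial table.
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
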