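#' Pupil preprocessing parameters
#'
#' Parameters of the fixed preprocessing chain: blink interpolation ->
#' downsampling -> millimetre conversion -> baseline correction -> baseline
#' outlier flagging. The arbitrary-unit-to-millimetre conversion is an affine
#' map `mm = mm_coeff_a * au + mm_coeff_b` whose coefficients are
#' recorder-specific and must be supplied (for data from
#' [generate_dataset()], the inverse of the generator's `au_gain`/`au_offset`).
#'
#' @param downsample_factor integer >= 1; consecutive samples averaged per
#'   output sample (10 turns 1000 Hz into 100 Hz).
#' @param baseline_window_ms two-element numeric, the half-open baseline
#'   window \[start, end) in ms post cue onset.
#' @param z_threshold baseline z-score beyond which a trial is flagged as an
#'   outlier.
#' @param mm_coeff_a,mm_coeff_b affine au -> mm coefficients.
#' @param blink_margin_ms margin added on both sides of each detected blink
#'   before interpolation (ms).
#' @param blink_min_duration_ms minimum duration of a zero/missing-pupil run
#'   to count as a blink (ms).
#' @return A `preproc_params` list.
#' @export
preproc_params <- function(downsample_factor = 10L,
                           baseline_window_ms = c(0, 50),
                           z_threshold = 2,
                           mm_coeff_a = NULL,
                           mm_coeff_b = NULL,
                           blink_margin_ms = 50,
                           blink_min_duration_ms = 20) {
  stopifnot(downsample_factor >= 1, downsample_factor == round(downsample_factor),
            z_threshold > 0, length(baseline_window_ms) == 2,
            baseline_window_ms[1] < baseline_window_ms[2])
  structure(as.list(environment()), class = "preproc_params")
}

proc_stage <- function(samples) attr(samples, "pupil_stage") %||% "raw"

require_stage <- function(samples, expected, step) {
  st <- proc_stage(samples)
  if (!identical(st, expected))
    stop(sprintf("%s expects samples at processing stage '%s' but got '%s'; ",
                 step, expected, st),
         "the preprocessing order is fixed (interpolate -> downsample -> ",
         "mm-convert -> baseline-correct -> flag) and steps cannot be re-run.",
         call. = FALSE)
}

# interpolate one trial's blink runs; returns pupil vector, all-NA if the
# whole trial is blinked
interp_one_trial <- function(pupil, blink_flag, min_samp, margin_samp) {
  n <- length(pupil)
  bad <- blink_flag | is.na(pupil) | pupil == 0
  bad[is.na(bad)] <- TRUE
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- rep(FALSE, n)
  for (k in which(r$values)) {
    flagged <- any(blink_flag[starts[k]:ends[k]], na.rm = TRUE)
    if (r$lengths[k] >= min_samp || flagged) {
      a <- max(1L, starts[k] - margin_samp)
      b <- min(n, ends[k] + margin_samp)
      mask[a:b] <- TRUE
    }
  }
  if (!any(mask)) return(pupil)
  if (all(mask)) return(rep(NA_real_, n))
  idx <- seq_len(n)
  pupil[mask] <- stats::approx(idx[!mask], pupil[!mask], xout = idx[mask],
                               rule = 2)$y
  pupil
}

#' Interpolate blinks in a raw samples table
#'
#' Blink episodes (flagged samples, or runs of zero/missing pupil at least
#' `blink_min_duration_ms` long) are extended by `blink_margin_ms` on both
#' sides and replaced by linear interpolation between the flanking valid
#' samples; leading/trailing blinks are filled with the nearest valid value.
#' A trial that is blinked in its entirety is marked missing (all samples set
#' to `NA`) rather than interpolated. Non-blink samples are unchanged.
#'
#' @param samples raw samples table.
#' @param params a `preproc_params` object.
#' @return The samples table at stage `"blinks_interpolated"`, with a
#'   `blink_report` attribute (trials touched, samples interpolated, trials
#'   fully missing).
#' @export
interpolate_blinks <- function(samples, params = preproc_params()) {
  require_stage(samples, "raw", "interpolate_blinks()")
  x <- data.table::copy(data.table::as.data.table(samples))
  pupil <- blink_flag <- trial_index <- participant_id <- NULL
  dt_ms <- x[, t_ms[2] - t_ms[1]]
  min_samp <- max(1L, ceiling(params$blink_min_duration_ms / dt_ms))
  margin_samp <- max(0L, round(params$blink_margin_ms / dt_ms))
  bad <- x$blink_flag | is.na(x$pupil) | x$pupil == 0
  n_before <- sum(bad)
  badtrials <- unique(x[bad, list(participant_id, trial_index)])
  if (nrow(badtrials) > 0) {
    x[badtrials, on = c("participant_id", "trial_index"),
      pupil := interp_one_trial(pupil, blink_flag, min_samp, margin_samp),
      by = .EACHI]
  }
  n_missing <- if (nrow(badtrials) > 0)
    nrow(x[badtrials, on = c("participant_id", "trial_index"),
           list(all_na = all(is.na(pupil))), by = .EACHI][all_na == TRUE]) else 0L
  attr(x, "pupil_stage") <- "blinks_interpolated"
  attr(x, "blink_report") <- list(trials_with_blinks = nrow(badtrials),
                                  samples_flagged = n_before,
                                  trials_fully_missing = n_missing)
  x
}

#' Downsample a samples table by block averaging
#'
#' Each output sample is the mean of `factor` consecutive input samples
#' within a trial (block means, not decimation); the output timestamp is the
#' first timestamp of each block. A trailing block shorter than `factor`
#' samples is dropped. `factor = 1` is the identity.
#'
#' @param samples samples table at stage `"blinks_interpolated"`.
#' @param factor positive integer downsampling factor.
#' @return Downsampled samples table at stage `"downsampled"`.
#' @export
downsample_samples <- function(samples, factor = 10L) {
  require_stage(samples, "blinks_interpolated", "downsample_samples()")
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) { # identity apart from the stage marker
    out <- data.table::copy(data.table::as.data.table(samples))
    attr(out, "pupil_stage") <- "downsampled"
    return(out)
  }
  x <- data.table::copy(data.table::as.data.table(samples))
  t_ms <- pupil <- gaze_x_deg <- gaze_y_deg <- blink_flag <- NULL
  bin__ <- n__ <- NULL
  x[, bin__ := (seq_len(.N) - 1L) %/% as.integer(factor),
    by = c("participant_id", "trial_index")]
  out <- x[, list(t_ms = t_ms[1], pupil = mean(pupil),
                  gaze_x_deg = mean(gaze_x_deg), gaze_y_deg = mean(gaze_y_deg),
                  blink_flag = any(blink_flag), n__ = .N),
           by = c("participant_id", "trial_index", "bin__")]
  out <- out[n__ == as.integer(factor)]
  out[, c("bin__", "n__") := NULL]
  attr(out, "pupil_stage") <- "downsampled"
  out
}

#' Convert pupil size from arbitrary units to millimetres
#'
#' Applies the recorder-specific affine map `mm = a * au + b` samplewise.
#'
#' @param samples samples table at stage `"downsampled"`.
#' @param params a `preproc_params` with `mm_coeff_a` and `mm_coeff_b` set.
#' @return Samples table in mm at stage `"mm"`.
#' @export
au_to_mm <- function(samples, params) {
  require_stage(samples, "downsampled", "au_to_mm()")
  a <- params$mm_coeff_a; b <- params$mm_coeff_b
  if (is.null(a) || is.null(b) || is.na(a) || is.na(b))
    stop("au->mm conversion coefficients are missing; supply them as the ",
         "config keys 'mm_coeff_a' and 'mm_coeff_b' (preproc section)",
         call. = FALSE)
  x <- data.table::copy(data.table::as.data.table(samples))
  pupil <- NULL
  x[, pupil := a * pupil + b]
  attr(x, "pupil_stage") <- "mm"
  x
}

#' Baseline-correct pupil traces trial by trial
#'
#' Subtracts each trial's mean pupil size over the baseline window (by
#' default the first 50 ms after cue onset, half-open \[0, 50)) from all of
#' that trial's samples, and stores the baseline in the trial table's
#' `baseline_pupil` column. Trials with no valid samples in the baseline
#' window are marked missing.
#'
#' @param samples samples table in mm (stage `"mm"`), time locked to cue
#'   onset at `t_ms = 0`.
#' @param trials matching trial table.
#' @param params a `preproc_params` object.
#' @return list with the corrected `samples` (stage `"baseline_corrected"`)
#'   and the updated `trials`.
#' @export
baseline_correct <- function(samples, trials, params = preproc_params()) {
  require_stage(samples, "mm", "baseline_correct()")
  x <- data.table::as.data.table(samples)
  t_ms <- pupil <- baseline__ <- NULL
  w <- params$baseline_window_ms
  bl <- x[t_ms >= w[1] & t_ms < w[2],
          list(baseline__ = mean(pupil)),
          by = c("participant_id", "trial_index")]
  x <- bl[x, on = c("participant_id", "trial_index")]
  x[, pupil := pupil - baseline__]
  x[, baseline__ := NULL]
  tr <- as.data.frame(trials)
  key <- paste(tr$participant_id, tr$trial_index)
  blkey <- paste(bl$participant_id, bl$trial_index)
  tr$baseline_pupil <- bl$baseline__[match(key, blkey)]
  attr(x, "pupil_stage") <- "baseline_corrected"
  list(samples = x, trials = tr)
}

#' Flag trials with outlying baseline pupil size
#'
#' Baselines are z-scored within participant; trials beyond
#' `z_threshold` (default +/-2, which flags about 4.55% under normality) are
#' excluded with reason `"baseline_outlier"`. Trials with a missing baseline
#' (fully blinked or no samples in the baseline window) are excluded with
#' reason `"missing"`. Participants with fewer than 3 analyzable trials get
#' no z-flagging (with a warning).
#'
#' @param trials trial table with `baseline_pupil` populated.
#' @param params a `preproc_params` object.
#' @return The trial table with `excluded` and `exclusion_reason` set, plus
#'   an `exclusion_report` attribute.
#' @export
flag_baseline_outliers <- function(trials, params = preproc_params()) {
  tr <- as.data.frame(trials)
  if (!"baseline_pupil" %in% names(tr) || all(is.na(tr$baseline_pupil)))
    stop("baseline_pupil is not populated; run baseline_correct() first")
  tr$excluded <- FALSE
  tr$exclusion_reason <- "none"
  miss <- is.na(tr$baseline_pupil)
  tr$excluded[miss] <- TRUE
  tr$exclusion_reason[miss] <- "missing"
  for (pid in unique(tr$participant_id)) {
    sel <- tr$participant_id == pid & !miss
    if (sum(sel) < 3) {
      warning("participant ", pid, " has fewer than 3 analyzable trials; ",
              "baseline z-flagging skipped")
      next
    }
    b <- tr$baseline_pupil[sel]
    s <- stats::sd(b)
    if (s == 0) next
    z <- (b - mean(b)) / s
    out <- abs(z) > params$z_threshold
    idx <- which(sel)[out]
    tr$excluded[idx] <- TRUE
    tr$exclusion_reason[idx] <- "baseline_outlier"
  }
  attr(tr, "exclusion_report") <- list(
    n_excluded = sum(tr$excluded),
    fraction_excluded = mean(tr$excluded),
    n_missing = sum(tr$exclusion_reason == "missing"),
    n_baseline_outlier = sum(tr$exclusion_reason == "baseline_outlier"))
  tr
}

#' Run the full preprocessing chain
#'
#' Fixed order: [interpolate_blinks()], [downsample_samples()], [au_to_mm()],
#' [baseline_correct()], [flag_baseline_outliers()]. Each step checks the
#' table's processing-stage marker, so re-running a step (or running the
#' pipeline on already-processed data) is refused.
#'
#' @param samples raw samples table.
#' @param trials matching trial table.
#' @param params a `preproc_params` with the mm coefficients set.
#' @return list with processed `samples`, flagged `trials` and a `report`
#'   of per-step counts.
#' @export
preprocess_pipeline <- function(samples, trials, params) {
  s <- interpolate_blinks(samples, params)
  blink_report <- attr(s, "blink_report")
  s <- downsample_samples(s, params$downsample_factor)
  s <- au_to_mm(s, params)
  bc <- baseline_correct(s, trials, params)
  tr <- flag_baseline_outliers(bc$trials, params)
  list(samples = bc$samples, trials = tr,
       report = c(blink_report, attr(tr, "exclusion_report")))
}
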