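#' Generative parameters for synthetic pupil traces
#'
#' Parameters of the 1000-Hz synthetic pupil signal, in millimetres of
#' diameter. Each trace is a sum of piecewise-linear components: a
#' participant-specific baseline, a slight dilation during the 1000-ms cue
#' presentation that decays after noise onset, a pupillary light-response
#' constriction that begins at noise onset plus a latency and ramps to its
#' full (negative) amplitude, and the attentional-breadth effect — the
#' ordinal eccentricity code (-1/0/+1) times a participant-specific slope,
#' ramping linearly from zero at `breadth_onset_ms` to its full value at
#' `breadth_plateau_ms` and held thereafter. White measurement noise is added
#' per sample, blinks are inserted as zero-valued runs at `blink_rate_hz`,
#' and the trace is emitted in arbitrary recorder units via
#' `au = au_gain * mm + au_offset`.
#'
#' Defaults are chosen to emulate the cueing experiments: a ~5-mm baseline, a
#' breadth effect of 0.008 mm per ordinal-eccentricity unit emerging around
#' 1750 ms after cue onset and plateauing by 2500 ms, and a between-participant
#' slope SD of 0.03 mm so that roughly two-thirds of participants carry a
#' positive effect.
#'
#' @param baseline_mm_mean mean baseline pupil diameter (mm).
#' @param baseline_mm_sd_between between-participant SD of the baseline (mm).
#' @param cue_dilation_mm peak of the slight dilation during the cue (mm).
#' @param cue_decay_ms time after noise onset for the cue dilation to decay
#'   back to zero (ms).
#' @param light_response_amplitude_mm light-response amplitude (mm, negative
#'   = constriction).
#' @param light_response_latency_ms latency of the light response after noise
#'   onset (ms).
#' @param light_response_rise_ms rise time to full constriction (ms).
#' @param breadth_slope_mm population mean of the attentional-breadth effect
#'   (mm per ordinal-eccentricity unit).
#' @param breadth_onset_ms onset of the breadth effect (ms post cue onset).
#' @param breadth_plateau_ms time at which the breadth effect reaches its
#'   full value (ms post cue onset).
#' @param slope_sd_between between-participant SD of the breadth slope (mm).
#' @param sample_noise_sd_mm per-sample white-noise SD (mm).
#' @param blink_rate_hz blink rate (blinks per second).
#' @param blink_duration_ms blink duration (ms).
#' @param au_gain arbitrary units per mm.
#' @param au_offset arbitrary-unit offset.
#' @param sampling_rate_hz recorder sampling rate (Hz; 1000 emulates the
#'   eye tracker, lower rates are useful for reduced-scale simulation).
#' @param gaze_jitter_deg SD of fixational gaze jitter (degrees).
#' @param trace_end_ms optional fixed trace end (ms post cue onset); `NULL`
#'   runs each trace to target offset plus the post-target noise.
#' @return A `pupil_gen_params` list.
#' @export
pupil_gen_params <- function(baseline_mm_mean = 5,
                             baseline_mm_sd_between = 0.5,
                             cue_dilation_mm = 0.05,
                             cue_decay_ms = 500,
                             light_response_amplitude_mm = -1,
                             light_response_latency_ms = 220,
                             light_response_rise_ms = 500,
                             breadth_slope_mm = 0.008,
                             breadth_onset_ms = 1750,
                             breadth_plateau_ms = 2500,
                             slope_sd_between = 0.03,
                             sample_noise_sd_mm = 0.05,
                             blink_rate_hz = 0.1,
                             blink_duration_ms = 100,
                             au_gain = 1000,
                             au_offset = 0,
                             sampling_rate_hz = 1000,
                             gaze_jitter_deg = 0.3,
                             trace_end_ms = NULL) {
  stopifnot(breadth_onset_ms < breadth_plateau_ms, sampling_rate_hz > 0,
            blink_rate_hz >= 0, blink_duration_ms > 0, au_gain != 0)
  structure(as.list(environment()), class = "pupil_gen_params")
}

ramp01 <- function(t, a, b) pmin(1, pmax(0, (t - a) / (b - a)))

# all deterministic mm-scale components of a trace (no noise, no blinks)
trace_mean_mm <- function(t, code, params, intercept_mm, slope_mm) {
  cue_on <- params$cue_dilation_mm *
    ifelse(t < 1000, t / 1000,
           pmax(0, 1 - (t - 1000) / params$cue_decay_ms))
  lr0 <- 1000 + params$light_response_latency_ms
  light <- params$light_response_amplitude_mm *
    ramp01(t, lr0, lr0 + params$light_response_rise_ms)
  breadth <- code * slope_mm *
    ramp01(t, params$breadth_onset_ms, params$breadth_plateau_ms)
  intercept_mm + cue_on + light + breadth
}

# vectorized trace generation for all trials of one participant.
# Noise is drawn before blink placement so that regenerating with
# blink_rate_hz = 0 under the same RNG state yields the blink-free ground
# truth of the same traces.
generate_traces_block <- function(trials, params, intercept_mm, slope_mm,
                                  participant_id) {
  dt_ms <- 1000 / params$sampling_rate_hz
  end_ms <- trials$target_onset_ms + trials$target_duration_ms +
    trials$post_target_noise_ms
  if (!is.null(params$trace_end_ms)) end_ms <- pmin(end_ms, params$trace_end_ms)
  n_per <- floor(end_ms / dt_ms) + 1L
  total <- sum(n_per)
  t_ms <- (sequence(n_per) - 1) * dt_ms
  trial_index <- rep(trials$trial_index, n_per)
  code <- rep(ecc_code(trials$cued_ecc), n_per)
  mm <- trace_mean_mm(t_ms, code, params, intercept_mm, slope_mm)
  if (params$sample_noise_sd_mm > 0)
    mm <- mm + stats::rnorm(total, 0, params$sample_noise_sd_mm)
  gx <- stats::rnorm(total, 0, params$gaze_jitter_deg)
  gy <- stats::rnorm(total, 0, params$gaze_jitter_deg)
  pupil <- params$au_gain * mm + params$au_offset
  blink <- rep(FALSE, total)
  if (params$blink_rate_hz > 0) {
    offset <- cumsum(c(0L, n_per[-length(n_per)]))
    n_blinks <- stats::rpois(nrow(trials), params$blink_rate_hz * end_ms / 1000)
    has <- which(n_blinks > 0)
    if (length(has) > 0) {
      btrial <- rep(has, n_blinks[has])
      bstart <- stats::runif(length(btrial), 0,
                             pmax(0, end_ms[btrial] - params$blink_duration_ms))
      bdur_samp <- max(1L, round(params$blink_duration_ms / dt_ms))
      sidx <- offset[btrial] + floor(bstart / dt_ms) + 1L
      rows <- rep(sidx, each = bdur_samp) +
        rep(seq_len(bdur_samp) - 1L, times = length(sidx))
      lim <- rep(offset[btrial] + n_per[btrial], each = bdur_samp)
      rows <- rows[rows <= lim]
      blink[rows] <- TRUE
    }
    pupil[blink] <- 0
  }
  data.table::data.table(participant_id = participant_id,
                         trial_index = trial_index, t_ms = t_ms,
                         pupil = pupil, gaze_x_deg = gx, gaze_y_deg = gy,
                         blink_flag = blink)
}

#' Generate the pupil trace for a single trial
#'
#' See [pupil_gen_params()] for the generative model. With all noise and
#' blink terms zeroed the trace is the exact sum of its piecewise-linear
#' components; e.g. at the breadth plateau the mm-scale value equals
#' `intercept + light_response_amplitude_mm + code * slope`.
#'
#' @param trial one-row data.frame with at least `trial_index`, `cued_ecc`,
#'   `target_onset_ms`, `target_duration_ms`, `post_target_noise_ms`.
#' @param params a `pupil_gen_params` object.
#' @param participant_effects numeric vector `c(intercept_mm, slope_mm)`:
#'   this participant's realized baseline and breadth slope.
#' @param participant_id identifier stamped on the rows.
#' @return A data.table of samples (`t_ms`, `pupil` in arbitrary units,
#'   gaze, `blink_flag`) at the configured sampling rate.
#' @export
generate_trace <- function(trial, params = pupil_gen_params(),
                           participant_effects = c(params$baseline_mm_mean,
                                                   params$breadth_slope_mm),
                           participant_id = "p01") {
  generate_traces_block(trial, params, participant_effects[1],
                        participant_effects[2], participant_id)
}

#' Generate a full synthetic multi-participant dataset
#'
#' Composes the design, staircase, observer and trace generators: each
#' participant gets a fresh session design, per-eccentricity opacity
#' staircases coupled to the simulated observer (2-up-1-down for `exp1`,
#' 3-up-1-down for `exp2`/`exp3`; only validly cued trials update the
#' staircase), one behavioral response per trial, and one raw pupil trace per
#' trial. Participant-level baselines and breadth slopes are drawn from the
#' stated between-participant normal distributions. The result is fully
#' reproducible from `seed` via named substreams.
#'
#' @param n_participants number of participants (>= 2).
#' @param variant experiment variant (`"exp1"`, `"exp2"`, `"exp3"`).
#' @param observer an `observer_params` object.
#' @param pupil a `pupil_gen_params` object.
#' @param start_opacity_pct initial staircase opacity. Defaults to the
#'   observer's threshold, emulating a calibrated session in which the
#'   staircases operate in their equilibrium band throughout — the study
#'   condition of ~70% accuracy maintained on validly cued trials.
#' @param seed master integer seed.
#' @return list with `samples` (raw arbitrary-unit samples table, processing
#'   stage `"raw"`), `trials` (trial table with behavioral outcomes and
#'   opacities) and `effects` (per-participant realized intercepts/slopes).
#' @export
generate_dataset <- function(n_participants, variant = "exp1",
                             observer = observer_params(),
                             pupil = pupil_gen_params(),
                             start_opacity_pct = observer$threshold_opacity_pct,
                             seed = 1L) {
  stopifnot(n_participants >= 2)
  n_up <- if (variant == "exp1") 2L else 3L
  set.seed(substream_seed(seed, "participant-effects"))
  intercepts <- stats::rnorm(n_participants, pupil$baseline_mm_mean,
                             pupil$baseline_mm_sd_between)
  slopes <- stats::rnorm(n_participants, pupil$breadth_slope_mm,
                         pupil$slope_sd_between)
  ids <- sprintf("p%02d", seq_len(n_participants))
  all_samples <- vector("list", n_participants)
  all_trials <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    design <- build_session(variant, ids[i], seed)
    trials <- design$trials
    set.seed(substream_seed(seed, paste0("behavior:", ids[i])))
    stair <- lapply(stats::setNames(ECC_LABELS, ECC_LABELS), function(e)
      staircase_init(n_up = n_up, opacity_pct = start_opacity_pct,
                     eccentricity = e))
    n <- nrow(trials)
    opacity <- numeric(n); acc <- integer(n); rt <- numeric(n)
    for (j in seq_len(n)) {
      e <- trials$target_ecc[j]
      opacity[j] <- stair[[e]]$opacity_pct
      p <- psychometric_prob(opacity[j], observer,
                             valid = trials$validity[j] == "valid")
      acc[j] <- stats::rbinom(1, 1, p)
      if (trials$validity[j] == "valid")
        stair[[e]] <- staircase_update(stair[[e]], acc[j] == 1L)
    }
    rt <- stats::rlnorm(n, meanlog = log(observer$rt_location_ms),
                        sdlog = observer$rt_scale)
    trials$target_opacity_pct <- opacity
    trials$accuracy <- acc
    trials$rt_ms <- rt
    trials$baseline_pupil <- NA_real_
    trials$excluded <- FALSE
    trials$exclusion_reason <- "none"
    trials <- cbind(participant_id = ids[i], trials)
    set.seed(substream_seed(seed, paste0("trace:", ids[i])))
    all_samples[[i]] <- generate_traces_block(trials, pupil, intercepts[i],
                                              slopes[i], ids[i])
    all_trials[[i]] <- trials
  }
  samples <- data.table::rbindlist(all_samples)
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  attr(samples, "pupil_stage") <- "raw"
  list(samples = samples, trials = trials,
       effects = data.frame(participant_id = ids, intercept_mm = intercepts,
                            slope_mm = slopes))
}
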