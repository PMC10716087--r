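# Shared fixture builders. Datasets are generated in code and memoized for
# the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# preprocessing params matching the default generator's au scaling
test_preproc <- function(downsample_factor = 1L) {
  preproc_params(downsample_factor = downsample_factor,
                 mm_coeff_a = 0.001, mm_coeff_b = 0)
}

# small processed exp1 cohort with a clear breadth effect (slope large
# relative to its default between-participant SD so single-dataset tests are
# stable), 100 Hz, traces truncated shortly after the search range
small_cohort <- function() {
  memoize("small_cohort", {
    pg <- pupil_gen_params(sampling_rate_hz = 100, trace_end_ms = 3100,
                           breadth_slope_mm = 0.03)
    dat <- generate_dataset(10, "exp1", pupil = pg, seed = 2)
    proc <- preprocess_pipeline(dat$samples, dat$trials, test_preproc())
    c(dat, proc = list(proc))
  })
}

# small processed exp3 cohort (both breadth types), 50 Hz
exp3_cohort <- function() {
  memoize("exp3_cohort", {
    pg <- pupil_gen_params(sampling_rate_hz = 50, trace_end_ms = 3100,
                           breadth_slope_mm = 0.03)
    dat <- generate_dataset(10, "exp3", pupil = pg, seed = 4)
    proc <- preprocess_pipeline(dat$samples, dat$trials, test_preproc())
    c(dat, proc = list(proc))
  })
}

# hand-built raw samples table for precise preprocessing tests
raw_samples <- function(pupil, t_ms = seq_along(pupil) - 1,
                        blink = rep(FALSE, length(pupil)),
                        participant_id = "p01", trial_index = 1L) {
  x <- data.table::data.table(participant_id = participant_id,
                              trial_index = trial_index, t_ms = t_ms,
                              pupil = pupil, gaze_x_deg = 0, gaze_y_deg = 0,
                              blink_flag = blink)
  attr(x, "pupil_stage") <- "raw"
  x
}

# synthetic trial table with per-participant accuracy probabilities per
# eccentricity (valid experimental trials only), for behavior-module tests
accuracy_trials <- function(p_by_ecc, n_per_ecc = 20, seed = 1,
                            exact = FALSE) {
  set.seed(seed)
  rows <- list()
  for (pid in names(p_by_ecc)) {
    p <- p_by_ecc[[pid]]
    for (e in names(p)) {
      acc <- if (exact) {
        k <- round(p[[e]] * n_per_ecc)
        c(rep(1L, k), rep(0L, n_per_ecc - k))
      } else rbinom(n_per_ecc, 1, p[[e]])
      rows[[paste(pid, e)]] <- data.frame(
        participant_id = pid, phase = "experimental", validity = "valid",
        cued_ecc = e, accuracy = acc,
        rt_ms = rlnorm(n_per_ecc, log(600), 0.25), excluded = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
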