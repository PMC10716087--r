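pp0 <- function(...) preproc_params(mm_coeff_a = 1, mm_coeff_b = 0, ...)

test_that("blink interpolation is the identity on clean traces", {
  x <- raw_samples(pupil = 4 + sin(seq(0, 1, length.out = 50)))
  y <- interpolate_blinks(x, pp0())
  expect_equal(y$pupil, x$pupil)
  expect_identical(attr(y, "pupil_stage"), "blinks_interpolated")
})

test_that("a blink is replaced by the line between its flanks", {
  # flanks 4.0 and 5.0; zeroed blink in between; no margin
  pupil <- c(rep(4, 10), rep(0, 11), rep(5, 10))
  x <- raw_samples(pupil)
  y <- interpolate_blinks(x, pp0(blink_margin_ms = 0,
                                 blink_min_duration_ms = 2))
  expect_equal(y$pupil[16], 4.5) # midpoint of the gap
  expect_equal(y$pupil[c(1:10, 22:31)], pupil[c(1:10, 22:31)])
  # leading blink is filled with the nearest valid value
  x2 <- raw_samples(c(rep(0, 5), rep(3, 20)))
  y2 <- interpolate_blinks(x2, pp0(blink_margin_ms = 0,
                                   blink_min_duration_ms = 2))
  expect_equal(y2$pupil[1:5], rep(3, 5))
})

test_that("a fully blinked trial is marked missing, not interpolated", {
  x <- raw_samples(rep(0, 30))
  y <- interpolate_blinks(x, pp0())
  expect_true(all(is.na(y$pupil)))
  expect_equal(attr(y, "blink_report")$trials_fully_missing, 1)
})

test_that("interpolated traces track the blink-free ground truth", {
  pg_blink <- pupil_gen_params(sampling_rate_hz = 100, trace_end_ms = 3000,
                               blink_rate_hz = 0.5)
  pg_clean <- pupil_gen_params(sampling_rate_hz = 100, trace_end_ms = 3000,
                               blink_rate_hz = 0)
  trial <- build_session("exp1", "p01", 1)$trials[1:50, ]
  set.seed(77)
  with_blinks <- generate_trace(trial, pg_blink, c(5, 0.01))
  set.seed(77) # noise draws precede blink placement, so truth is aligned
  truth <- generate_trace(trial, pg_clean, c(5, 0.01))
  fixed <- interpolate_blinks(with_blinks, test_preproc())
  ok <- !is.na(fixed$pupil)
  rmse_mm <- sqrt(mean((fixed$pupil[ok] - truth$pupil[ok])^2)) / pg_blink$au_gain
  expect_lt(rmse_mm, pg_blink$sample_noise_sd_mm)
})

test_that("downsampling contracts length by the factor and preserves means", {
  x <- raw_samples(rep(7, 3000), t_ms = 0:2999)
  y <- downsample_samples(interpolate_blinks(x, pp0()), 10)
  expect_equal(nrow(y), 300)
  expect_true(all(y$pupil == 7))
  expect_equal(y$t_ms, seq(0, 2990, by = 10))
  # factor 1 is the identity
  x2 <- raw_samples(rnorm(100, 5), t_ms = 0:99)
  y2 <- downsample_samples(interpolate_blinks(x2, pp0()), 1)
  expect_equal(y2$pupil, x2$pupil)
  # a trailing partial block is dropped
  x3 <- raw_samples(rnorm(25, 5), t_ms = 0:24)
  y3 <- downsample_samples(interpolate_blinks(x3, pp0()), 10)
  expect_equal(nrow(y3), 2)
})

test_that("au to mm conversion is the stated affine map", {
  x <- raw_samples(rep(5000, 20))
  d <- downsample_samples(interpolate_blinks(x, pp0()), 1)
  expect_equal(au_to_mm(d, pp0())$pupil, rep(5000, 20)) # a=1, b=0
  expect_equal(au_to_mm(d, preproc_params(mm_coeff_a = 0.001,
                                          mm_coeff_b = 0))$pupil, rep(5, 20))
  expect_error(au_to_mm(d, preproc_params()), "mm_coeff_a")
})

test_that("mm conversion inverts the generator's au scaling", {
  pg <- pupil_gen_params(sampling_rate_hz = 100, trace_end_ms = 500,
                         blink_rate_hz = 0, au_gain = 1187, au_offset = 312)
  trial <- data.frame(trial_index = 1L, cued_ecc = "medium",
                      target_onset_ms = 3000, target_duration_ms = 30,
                      post_target_noise_ms = 300)
  set.seed(3)
  au <- generate_trace(trial, pg, c(5, 0.01))
  pg_mm <- pg; pg_mm$au_gain <- 1; pg_mm$au_offset <- 0
  set.seed(3)
  mm <- generate_trace(trial, pg_mm, c(5, 0.01))
  conv <- au_to_mm(downsample_samples(interpolate_blinks(au, pp0()), 1),
                   preproc_params(mm_coeff_a = 1 / 1187,
                                  mm_coeff_b = -312 / 1187))
  expect_equal(conv$pupil, mm$pupil, tolerance = 1e-10)
})

test_that("baseline correction zeroes the baseline window trial by trial", {
  dat <- small_cohort()
  s <- dat$proc$samples
  x <- data.table::as.data.table(s)
  bl <- x[t_ms >= 0 & t_ms < 50, mean(pupil), by = .(participant_id, trial_index)]
  expect_true(all(abs(bl$V1[!is.na(bl$V1)]) < 1e-10))
  # shift invariance: adding a constant to the raw trace changes nothing
  raw <- raw_samples(rnorm(200, 5000, 10), t_ms = 0:199)
  run <- function(r) {
    s <- au_to_mm(downsample_samples(interpolate_blinks(r, pp0()), 1),
                  test_preproc())
    tr <- data.frame(participant_id = "p01", trial_index = 1L,
                     phase = "experimental")
    baseline_correct(s, tr, test_preproc())
  }
  shifted <- data.table::copy(raw); shifted[, pupil := pupil + 1234]
  attr(shifted, "pupil_stage") <- "raw"
  expect_equal(run(raw)$samples$pupil, run(shifted)$samples$pupil,
               tolerance = 1e-9)
  # a constant trace corrects to all zeros
  const <- run(raw_samples(rep(4000, 100), t_ms = 0:99))
  expect_true(all(const$samples$pupil == 0))
  expect_equal(const$trials$baseline_pupil, 4)
})

test_that("baseline z-flagging excludes at the normal tail rate", {
  set.seed(123)
  n <- 1e4
  tr <- data.frame(participant_id = "p01", trial_index = seq_len(n),
                   phase = "experimental", baseline_pupil = rnorm(n))
  out <- flag_baseline_outliers(tr, preproc_params())
  # 2 * pnorm(-2) = 0.0455 under standard-normal baselines
  expect_equal(mean(out$excluded), 0.0455, tolerance = 0.008 / 0.0455)
  # zero variance: nothing flagged
  tr2 <- tr; tr2$baseline_pupil <- 5
  expect_true(!any(flag_baseline_outliers(tr2, preproc_params())$excluded))
  # one extreme baseline among normals is flagged
  tr3 <- data.frame(participant_id = "p01", trial_index = 1:50,
                    phase = "experimental",
                    baseline_pupil = c(rnorm(49), 50))
  out3 <- flag_baseline_outliers(tr3, preproc_params())
  expect_true(out3$excluded[50])
  expect_equal(out3$exclusion_reason[50], "baseline_outlier")
})

test_that("the preprocessing order is fixed and re-running is refused", {
  x <- raw_samples(rnorm(100, 5000), t_ms = 0:99)
  expect_error(downsample_samples(x, 10), "stage")
  y <- interpolate_blinks(x, pp0())
  expect_error(interpolate_blinks(y, pp0()), "stage")
  z <- downsample_samples(y, 1)
  expect_error(baseline_correct(z, data.frame(), pp0()), "stage")
  m <- au_to_mm(z, pp0())
  expect_error(au_to_mm(m, pp0()), "stage")
})

test_that("the stage marker survives a round trip through disk", {
  dat <- small_cohort()
  f <- tempfile(fileext = ".csv")
  write_samples(dat$proc$samples[1:100, ], f)
  back <- read_samples(f)
  expect_identical(attr(back, "pupil_stage"), "baseline_corrected")
  expect_error(interpolate_blinks(back, test_preproc()), "stage")
})

test_that("overall exclusion on default synthetic data is plausibly small", {
  dat <- small_cohort()
  frac <- dat$proc$report$fraction_excluded
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.10)
})
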