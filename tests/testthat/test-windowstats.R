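# hand-built baseline-corrected dataset with one trial per participant per
# eccentricity and a constant trace per trial equal to the trial's value
cellmean_data <- function(yfun, n_participants = 6, seed = 31) {
  set.seed(seed)
  eccs <- c("near", "medium", "far")
  trials <- expand.grid(participant_id = sprintf("p%02d", 1:n_participants),
                        cued_ecc = eccs, stringsAsFactors = FALSE)
  trials$trial_index <- seq_len(nrow(trials))
  trials$phase <- "experimental"
  trials$breadth_type <- "size"
  trials$validity <- "valid"
  trials$excluded <- FALSE
  trials$y <- yfun(trials)
  samples <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i)
    data.frame(participant_id = trials$participant_id[i],
               trial_index = trials$trial_index[i],
               t_ms = c(1000, 1050), pupil = trials$y[i],
               gaze_x_deg = 0, gaze_y_deg = 0, blink_flag = FALSE)))
  samples <- data.table::as.data.table(samples)
  attr(samples, "pupil_stage") <- "baseline_corrected"
  list(samples = samples, trials = trials)
}

test_that("intercepts-only window LME on cell means equals OLS", {
  d <- cellmean_data(function(tr)
    rnorm(nrow(tr), 0.1) + 0.01 * ecc_code(tr$cued_ecc) + rnorm(nrow(tr), 0, 0.05))
  fit <- fit_window_lme(d$samples, d$trials, c(1000, 1100),
                        random_slopes = FALSE)
  ols <- stats::lm(y ~ ecc_code(cued_ecc), data = d$trials)
  expect_equal(fit$b, unname(coef(ols)[2]), tolerance = 1e-7)
  expect_equal(fit$random_structure, "intercepts_only")
})

test_that("window means use analyzable experimental trials only", {
  dat <- small_cohort()
  d <- window_means(dat$proc$samples, dat$proc$trials, c(2500, 2600))
  tr <- dat$proc$trials
  # excluded and practice trials never reach the model; every analyzable
  # trial does (interpolation fills all non-missing trials)
  expect_equal(nrow(d), sum(tr$phase == "experimental" & !tr$excluded))
  expect_true(all(d$ecc %in% c(-1L, 0L, 1L)))
})

test_that("the confirmatory LME recovers a strong generative slope", {
  dat <- small_cohort()
  fit <- fit_window_lme(dat$proc$samples, dat$proc$trials, c(2500, 2600))
  realized <- mean(dat$effects$slope_mm)
  expect_lt(abs(fit$b - realized), 3 * fit$se)
  expect_lt(fit$p, 0.05)
  expect_true(fit$random_structure %in%
                c("intercepts_and_slopes", "intercepts_only"))
})

test_that("mixed-effects analyses refuse fewer than 2 participants", {
  dat <- small_cohort()
  tr1 <- dat$proc$trials[dat$proc$trials$participant_id == "p01", ]
  expect_error(fit_window_lme(dat$proc$samples, tr1, c(2500, 2600)),
               "2 participants")
})

test_that("cross-validated selection stays in range and finds the plateau", {
  dat <- small_cohort()
  cv <- crossval_select_window(dat$proc$samples, dat$proc$trials,
                               search = c(750, 3000), bin_ms = 50, seed = 5)
  expect_length(cv$fold_peaks_ms, 4)
  expect_true(cv$selected_window[1] >= 750)
  expect_true(cv$selected_window[2] <= 3000)
  expect_equal(diff(cv$selected_window), 100)
  # the generative effect plateaus at 2500 ms; with a strong slope the
  # selected window should sit late in the search range
  expect_gte(cv$selected_window[1], 2000)
  expect_lt(cv$fulldata_fit$p, 0.05)
  # held-out statistics exist for every fold
  expect_length(cv$per_fold_heldout_stats, 4)
})

test_that("cross-validation is seed-deterministic", {
  dat <- small_cohort()
  cv1 <- crossval_select_window(dat$proc$samples, dat$proc$trials,
                                search = c(750, 3000), bin_ms = 150, seed = 8)
  cv2 <- crossval_select_window(dat$proc$samples, dat$proc$trials,
                                search = c(750, 3000), bin_ms = 150, seed = 8)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  expect_identical(cv1$fold_peaks_ms, cv2$fold_peaks_ms)
  expect_identical(cv1$selected_window, cv2$selected_window)
})

test_that("a fold's peak never inspects its own held-out data", {
  dat <- small_cohort()
  cv1 <- crossval_select_window(dat$proc$samples, dat$proc$trials,
                                search = c(750, 3000), bin_ms = 150, seed = 8)
  held1 <- names(cv1$fold_assignments)[cv1$fold_assignments == 1]
  # corrupt the held-out participants of fold 1 beyond recognition
  s2 <- data.table::copy(data.table::as.data.table(dat$proc$samples))
  sel <- s2$participant_id %in% held1
  s2[sel, pupil := -10 * pupil + 3]
  attr(s2, "pupil_stage") <- "baseline_corrected"
  cv2 <- crossval_select_window(s2, dat$proc$trials,
                                search = c(750, 3000), bin_ms = 150, seed = 8)
  # fold 1's training set is untouched, so its peak must be unchanged
  expect_identical(cv2$fold_peaks_ms[1], cv1$fold_peaks_ms[1])
  # but fold 1's held-out statistic does change
  expect_false(isTRUE(all.equal(cv2$per_fold_heldout_stats[1],
                                cv1$per_fold_heldout_stats[1])))
})

test_that("cross-validation refuses cohorts too small for 4 folds", {
  dat <- small_cohort()
  keep <- dat$proc$trials$participant_id %in% sprintf("p%02d", 1:7)
  expect_error(
    crossval_select_window(dat$proc$samples, dat$proc$trials[keep, ],
                           search = c(750, 3000), bin_ms = 150, seed = 1),
    "at least 8 participants")
})

test_that("the interaction model reports all three fixed-effect terms", {
  dat <- exp3_cohort()
  res <- fit_interaction_lme(dat$proc$samples, dat$proc$trials, c(2500, 2600))
  expect_equal(res$term, c("cue_eccentricity", "breadth_type_location",
                           "eccentricity_x_breadth_type"))
  expect_true(all(res$se > 0))
  # generator has no breadth-type dependence: interaction should be weak
  expect_lt(abs(res$stat[res$term == "eccentricity_x_breadth_type"]), 3)
  # a single breadth type is refused
  size_only <- dat$proc$trials[dat$proc$trials$breadth_type == "size", ]
  expect_error(fit_interaction_lme(dat$proc$samples, size_only, c(2500, 2600)),
               "both breadth types")
})

test_that("relabeling breadth types in a symmetrized dataset fixes the slope", {
  dat <- exp3_cohort()
  tr <- dat$proc$trials
  s <- data.table::as.data.table(dat$proc$samples)
  # append a relabeled copy with fresh participant ids
  tr2 <- tr
  tr2$breadth_type <- ifelse(tr$breadth_type == "size", "location", "size")
  tr2$participant_id <- paste0(tr2$participant_id, "b")
  s2 <- data.table::copy(s)[, participant_id := paste0(participant_id, "b")]
  trials_dup <- rbind(tr, tr2)
  samples_dup <- rbind(s, s2)
  attr(samples_dup, "pupil_stage") <- "baseline_corrected"
  res1 <- fit_interaction_lme(dat$proc$samples, tr, c(2500, 2600))
  res2 <- fit_interaction_lme(samples_dup, trials_dup, c(2500, 2600))
  # in the symmetrized data the interaction vanishes and the eccentricity
  # slope equals the average of the two condition slopes
  expect_lt(abs(res2$b[res2$term == "eccentricity_x_breadth_type"]), 1e-6)
  e1 <- res1$b[res1$term == "cue_eccentricity"]
  i1 <- res1$b[res1$term == "eccentricity_x_breadth_type"]
  e2 <- res2$b[res2$term == "cue_eccentricity"]
  expect_equal(e2, e1 + i1 / 2, tolerance = 1e-3)
})

test_that("per-participant effect sizes behave at the degenerate corners", {
  # exact linearity gives r = 1
  d <- cellmean_data(function(tr) 0.02 * ecc_code(tr$cued_ecc))
  r <- per_participant_effect(d$samples, d$trials, c(1000, 1100))
  expect_true(all(abs(r$r - 1) < 1e-12))
  expect_true(!any(r$degenerate))
  # constant pupil gives r = 0 with a degenerate flag
  d0 <- cellmean_data(function(tr) rep(0.3, nrow(tr)))
  r0 <- per_participant_effect(d0$samples, d0$trials, c(1000, 1100))
  expect_true(all(r0$r == 0))
  expect_true(all(r0$degenerate))
})

test_that("a cohort with a positive mean slope shows mostly positive r", {
  dat <- small_cohort()
  r <- per_participant_effect(dat$proc$samples, dat$proc$trials, c(2500, 2600))
  expect_equal(nrow(r), 10)
  expect_gt(mean(r$r > 0), 0.5)
  # signs track each participant's realized slope
  m <- merge(r, dat$effects, by = "participant_id")
  expect_gt(stats::cor(m$r, m$slope_mm), 0.7)
})
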