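test_that("performance deviance is symmetric and zero at equality", {
  expect_equal(performance_deviance(0.7, 0.7, 0.7)$deviance, 0)
  expect_equal(performance_deviance(0.75, 0.70, 0.65)$deviance, 0.10)
  # permutation invariance of the three accuracies
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  acc <- c(0.81, 0.66, 0.74)
  devs <- vapply(perms, function(p)
    do.call(performance_deviance, as.list(acc[p]))$deviance, numeric(1))
  expect_true(all(abs(devs - devs[1]) < 1e-12))
  # the as-printed variant double-counts near and is not symmetric
  d1 <- performance_deviance(0.8, 0.7, 0.6, printed_formula = TRUE)$deviance
  d2 <- performance_deviance(0.6, 0.7, 0.8, printed_formula = TRUE)$deviance
  expect_equal(d1, d2) # |near-overall| duplicated, symmetric here by accident
  d3 <- performance_deviance(0.7, 0.8, 0.6, printed_formula = TRUE)$deviance
  expect_false(isTRUE(all.equal(d3,
    performance_deviance(0.7, 0.8, 0.6)$deviance)))
})

test_that("the validity model detects the cueing effect and flips with labels", {
  dat <- small_cohort()
  v1 <- accuracy_validity_model(dat$proc$trials)
  expect_equal(v1$term, "cue_validity")
  expect_gt(v1$b, 0) # more accurate on valid trials (gain > 1)
  expect_lt(v1$p, 0.05)
  # relabeling valid <-> invalid flips the sign of the fixed effect
  tr2 <- dat$proc$trials
  tr2$validity <- ifelse(tr2$validity == "valid", "invalid", "valid")
  v2 <- accuracy_validity_model(tr2)
  expect_equal(v2$b, -v1$b, tolerance = 0.05)
})

test_that("participants with a single validity level are dropped", {
  dat <- small_cohort()
  tr <- dat$proc$trials
  one <- tr$participant_id == "p01" & tr$validity == "invalid"
  expect_warning(accuracy_validity_model(tr[!one, ]), "p01")
})

test_that("RT shifts on one eccentricity move the slope by half the shift", {
  dat <- small_cohort()
  tr <- dat$proc$trials
  r1 <- rt_model(tr)
  expect_equal(r1$term, "cue_eccentricity")
  # generator RTs are eccentricity-independent: the slope should be tiny
  # relative to the RT scale
  expect_lt(abs(r1$b), 25)
  k <- 100
  tr2 <- tr
  far <- tr2$cued_ecc == "far"
  tr2$rt_ms[far] <- tr2$rt_ms[far] + k
  r2 <- rt_model(tr2)
  # with balanced -1/0/+1 codes, +k on the far third moves the OLS slope by k/2
  expect_equal(r2$b - r1$b, k / 2, tolerance = 0.2)
})

test_that("staircase-equated cohorts pass the efficacy Bayes factor", {
  dat <- small_cohort()
  bf <- bf01_staircase_efficacy(dat$proc$trials)
  expect_s3_class(bf, "bf_result")
  expect_gt(bf$bf01, 0)
  expect_equal(bf$n_participants, 10)
})

test_that("iterative exclusion is a no-op on an already-passing cohort", {
  # per-participant accuracy differs, but is exactly equal across
  # eccentricities, so the null is unambiguously supported
  p <- lapply(1:12, function(i) {
    a <- 0.6 + 0.025 * (i %% 5)
    c(near = a, medium = a, far = a)
  })
  names(p) <- sprintf("p%02d", 1:12)
  tr <- accuracy_trials(p, n_per_ecc = 40, seed = 21, exact = TRUE)
  res <- iterative_exclusion(tr)
  expect_equal(res$status, "success")
  expect_length(res$dropped, 0)
  expect_length(res$bf_trace, 1)
  expect_gt(tail(res$bf_trace, 1), 3)
})

test_that("deviant participants are excluded first, in deviance order", {
  p <- setNames(rep(list(c(near = .7, medium = .7, far = .7)),
                    12), sprintf("p%02d", 1:12))
  deviants <- sprintf("q%02d", 1:3)
  for (q in deviants) p[[q]] <- c(near = .95, medium = .7, far = .45)
  tr <- accuracy_trials(p, n_per_ecc = 40, seed = 22)
  res <- iterative_exclusion(tr)
  if (res$status == "success" && length(res$dropped) > 0) {
    expect_true(all(res$dropped[seq_len(min(3, length(res$dropped)))] %in%
                      c(deviants, res$deviance$participant_id[1:4])))
    expect_gt(tail(res$bf_trace, 1), 3)
  }
  # the three injected deviants carry the largest deviances
  topdev <- res$deviance$participant_id[1:3]
  expect_setequal(topdev, deviants)
})

test_that("exhausting the cohort yields an explicit failure status", {
  # every participant deviates in the same direction: the effect never goes
  # away, so exclusion runs out of participants
  p <- setNames(rep(list(c(near = .95, medium = .7, far = .45)), 6),
                sprintf("p%02d", 1:6))
  tr <- accuracy_trials(p, n_per_ecc = 60, seed = 23)
  res <- iterative_exclusion(tr)
  expect_equal(res$status, "exhausted")
  expect_true(all(res$bf_trace <= 3))
})

test_that("falling below the target sample size is flagged", {
  p <- setNames(rep(list(c(near = .7, medium = .7, far = .7)), 10),
                sprintf("p%02d", 1:10))
  p$q01 <- c(near = .95, medium = .7, far = .45)
  tr <- accuracy_trials(p, n_per_ecc = 40, seed = 24)
  res <- suppressWarnings(iterative_exclusion(tr, target_n = 11))
  if (length(res$dropped) > 0) expect_true(res$below_target_n)
})
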