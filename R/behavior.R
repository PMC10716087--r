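analysis_trials <- function(trials) {
  tr <- as.data.frame(trials)
  keep <- tr$phase == "experimental" & !is.na(tr$accuracy)
  if ("excluded" %in% names(tr)) keep <- keep & !tr$excluded
  tr[keep, ]
}

#' Mixed logistic model of the cue-validity effect
#'
#' Accuracy (0/1) is regressed on cue validity (invalid trials as the
#' reference level) in a binomial mixed model with by-participant random
#' intercepts and validity slopes. A positive fixed effect means participants
#' were more accurate on valid than invalid trials (the behavioral cueing
#' effect). If the random-slopes model fails to converge it is downgraded to
#' intercepts only.
#'
#' @param trials trial table (experimental, non-excluded trials are used).
#' @return One-row data.frame (`term = "cue_validity"`, log-odds `b`, `se`,
#'   Wald `stat`, `p`, `converged`, `random_structure`).
#' @export
accuracy_validity_model <- function(trials) {
  tr <- analysis_trials(trials)
  if (length(unique(tr$validity)) < 2)
    stop("trials must contain both valid and invalid trials")
  both <- tapply(tr$validity, tr$participant_id,
                 function(v) length(unique(v)) == 2)
  bad <- names(both)[!both]
  if (length(bad) > 0) {
    warning("dropping participant(s) with a single validity level: ",
            paste(bad, collapse = ", "))
    tr <- tr[!tr$participant_id %in% bad, ]
  }
  tr$validity <- factor(tr$validity, levels = c("invalid", "valid"))
  structure_used <- "intercepts_and_slopes"
  fit <- retry_if_unconverged(suppressMessages(suppressWarnings(
    lme4::glmer(accuracy ~ validity + (1 + validity | participant_id),
                data = tr, family = stats::binomial()))))
  if (!lme_converged(fit)) {
    structure_used <- "intercepts_only"
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(accuracy ~ validity + (1 | participant_id),
                  data = tr, family = stats::binomial())))
  }
  b <- lme4::fixef(fit)[["validityvalid"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["validityvalid"]]
  out <- wald_row("cue_validity", b, se)
  out$converged <- lme_converged(fit)
  out$random_structure <- structure_used
  attr(out, "model") <- fit
  out
}

#' Mixed model of reaction times on cue eccentricity
#'
#' Reaction time (ms) is regressed on the ordinal cue-eccentricity code with
#' by-participant random intercepts and eccentricity slopes (downgraded to
#' intercepts only on non-convergence). In a well-calibrated staircase design
#' the fixed effect is expected to be null: task difficulty, and hence
#' response speed, should not differ across eccentricities.
#'
#' @param trials trial table with `rt_ms`.
#' @return One-row data.frame (`term = "cue_eccentricity"`, `b` in
#'   ms per ordinal unit, `se`, `stat`, `p`, `converged`,
#'   `random_structure`).
#' @export
rt_model <- function(trials) {
  tr <- analysis_trials(trials)
  tr <- tr[!is.na(tr$rt_ms), ]
  tr$ecc <- ecc_code(tr$cued_ecc)
  structure_used <- "intercepts_and_slopes"
  fit <- retry_if_unconverged(suppressMessages(suppressWarnings(
    lme4::lmer(rt_ms ~ ecc + (1 + ecc | participant_id), data = tr,
               REML = TRUE))))
  if (!lme_converged(fit)) {
    structure_used <- "intercepts_only"
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(rt_ms ~ ecc + (1 | participant_id), data = tr, REML = TRUE)))
  }
  b <- lme4::fixef(fit)[["ecc"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["ecc"]]
  out <- wald_row("cue_eccentricity", b, se)
  out$converged <- lme_converged(fit)
  out$random_structure <- structure_used
  attr(out, "model") <- fit
  out
}

# per-participant mean accuracy per cued eccentricity, valid trials only
valid_accuracy_cells <- function(trials) {
  tr <- analysis_trials(trials)
  tr <- tr[tr$validity == "valid", ]
  agg <- stats::aggregate(accuracy ~ participant_id + cued_ecc, data = tr,
                          FUN = mean)
  tab <- table(agg$participant_id)
  incomplete <- names(tab)[tab < length(ECC_LABELS)]
  if (length(incomplete) > 0) {
    warning("dropping participant(s) with missing eccentricity cells: ",
            paste(incomplete, collapse = ", "))
    agg <- agg[!agg$participant_id %in% incomplete, ]
  }
  agg
}

#' Bayes-factor check of staircase efficacy
#'
#' Did the per-eccentricity staircases equate accuracy across eccentricities?
#' Per-participant mean accuracy on validly cued trials is computed per cued
#' eccentricity and entered into a one-factor repeated-measures JZS Bayes
#' factor ([bf01_rm_anova()]); `bf01 > 3` is the conventional threshold for
#' substantial evidence that accuracy did not differ across eccentricities.
#' Falls back to the BIC approximation ([bf01_bic()]) if the quadrature is
#' not applicable; the method actually used is recorded in `method`.
#'
#' @param trials trial table.
#' @return A `bf_result` (`bf01`, `bf10`, `method`, `n_participants`).
#' @export
bf01_staircase_efficacy <- function(trials) {
  agg <- valid_accuracy_cells(trials)
  if (length(unique(agg$participant_id)) < 2)
    stop("need at least 2 participants with valid trials at all eccentricities")
  tryCatch(
    bf01_rm_anova(agg$accuracy, agg$participant_id, agg$cued_ecc),
    error = function(e) bf01_bic(agg$accuracy, agg$participant_id,
                                 agg$cued_ecc))
}

#' Absolute performance deviance across eccentricities
#'
#' How much a participant's accuracy differs across the three cued
#' eccentricities: the sum of absolute deviations of the per-eccentricity
#' accuracies from their overall (unweighted) mean,
#' `|near - overall| + |medium - overall| + |far - overall|`. The deviance is
#' permutation-invariant in its three arguments and zero exactly when all
#' three accuracies are equal. `printed_formula = TRUE` reproduces a variant
#' that counts the near deviation twice and omits the far term.
#'
#' @param acc_near,acc_medium,acc_far accuracies in \[0, 1\] (vectorized).
#' @param printed_formula use the duplicated-near variant instead of the
#'   symmetric formula.
#' @return data.frame with the three accuracies, `acc_overall` and
#'   `deviance`.
#' @export
performance_deviance <- function(acc_near, acc_medium, acc_far,
                                 printed_formula = FALSE) {
  stopifnot(all(acc_near >= 0 & acc_near <= 1),
            all(acc_medium >= 0 & acc_medium <= 1),
            all(acc_far >= 0 & acc_far <= 1))
  overall <- (acc_near + acc_medium + acc_far) / 3
  dev <- if (printed_formula)
    abs(acc_near - overall) + abs(acc_medium - overall) + abs(acc_near - overall)
  else
    abs(acc_near - overall) + abs(acc_medium - overall) + abs(acc_far - overall)
  data.frame(acc_near = acc_near, acc_medium = acc_medium, acc_far = acc_far,
             acc_overall = overall, deviance = dev)
}

participant_deviances <- function(trials) {
  agg <- valid_accuracy_cells(trials)
  wide <- stats::reshape(agg, idvar = "participant_id", timevar = "cued_ecc",
                         direction = "wide")
  names(wide) <- sub("accuracy\\.", "", names(wide))
  dv <- performance_deviance(wide$near, wide$medium, wide$far)
  data.frame(participant_id = wide$participant_id, deviance = dv$deviance,
             stringsAsFactors = FALSE)
}

#' Deviance-guided iterative participant exclusion
#'
#' If the staircase-efficacy Bayes factor does not reach the substantial-null
#' threshold (`bf01 > 3`), participants are excluded one at a time in
#' decreasing order of absolute performance deviance (ties broken by
#' participant id order), recomputing the Bayes factor after each exclusion,
#' until the threshold is met or the cohort is exhausted.
#'
#' @param trials trial table.
#' @param target_n the design's target sample size; falling below it is
#'   logged in the returned bookkeeping (and with a warning) but does not
#'   stop the loop.
#' @param bf_threshold the BF01 criterion (3 by convention).
#' @return list with `kept` and `dropped` participant ids (in exclusion
#'   order), `bf_trace` (BF01 after each step; non-empty, ending > threshold
#'   on success), `status` (`"success"` or `"exhausted"`),
#'   `below_target_n`, and the per-participant `deviance` table.
#' @export
iterative_exclusion <- function(trials, target_n = NULL, bf_threshold = 3) {
  tr <- as.data.frame(trials)
  devs <- participant_deviances(tr)
  devs <- devs[order(-devs$deviance, devs$participant_id), ]
  kept <- sort(unique(devs$participant_id))
  dropped <- character(0)
  bf_trace <- numeric(0)
  status <- "exhausted"
  repeat {
    bf <- suppressWarnings(
      bf01_staircase_efficacy(tr[tr$participant_id %in% kept, ]))
    bf_trace <- c(bf_trace, bf$bf01)
    if (bf$bf01 > bf_threshold) { status <- "success"; break }
    if (length(kept) <= 3) break # next drop would leave too few for the BF
    worst <- devs$participant_id[devs$participant_id %in% kept][1]
    dropped <- c(dropped, worst)
    kept <- setdiff(kept, worst)
  }
  below <- !is.null(target_n) && length(kept) < target_n
  if (below)
    warning("cohort dropped below the target sample size (", length(kept),
            " < ", target_n, "); recruit replacements")
  list(kept = kept, dropped = dropped, bf_trace = bf_trace, status = status,
       below_target_n = below, deviance = devs)
}
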