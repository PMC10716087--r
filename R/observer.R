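#' Parameters of the synthetic psychophysical observer
#'
#' The observer performs the two-alternative luminance increment/decrement
#' judgement. Accuracy follows a logistic psychometric function of target
#' opacity with a guessing floor of 0.5 (two-choice task) and an upper
#' asymptote of `1 - lapse_rate`. A zero-opacity target carries no signal, so
#' performance is exactly at chance there. On validly cued trials the
#' effective signal is multiplied by `validity_sensitivity_gain` (>= 1),
#' which produces the behavioral cueing effect (higher accuracy on valid than
#' invalid trials at matched opacity). Reaction times are log-normal and do
#' not depend on eccentricity.
#'
#' @param threshold_opacity_pct opacity (percent) at which the effective
#'   signal reaches the psychometric midpoint on invalid trials; one value
#'   recycled over eccentricities.
#' @param psychometric_slope slope of the logistic in 1/percent.
#' @param lapse_rate asymptotic error rate in \[0, 0.05\].
#' @param validity_sensitivity_gain multiplicative signal gain on valid
#'   trials (>= 1).
#' @param rt_location_ms median reaction time in ms.
#' @param rt_scale log-normal scale (sdlog) of reaction times.
#' @return An `observer_params` list.
#' @export
observer_params <- function(threshold_opacity_pct = 30,
                            psychometric_slope = 0.15,
                            lapse_rate = 0.02,
                            validity_sensitivity_gain = 1.3,
                            rt_location_ms = 600,
                            rt_scale = 0.25) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 0.05,
            validity_sensitivity_gain >= 1,
            rt_location_ms > 0, rt_scale > 0)
  structure(list(threshold_opacity_pct = threshold_opacity_pct,
                 psychometric_slope = psychometric_slope,
                 lapse_rate = lapse_rate,
                 validity_sensitivity_gain = validity_sensitivity_gain,
                 rt_location_ms = rt_location_ms,
                 rt_scale = rt_scale),
            class = "observer_params")
}

#' Probability correct for a given target opacity
#'
#' `p = 0.5 + (0.5 - lapse) * F(slope * (gain * opacity - threshold))`, with
#' `F` the logistic CDF and `gain` the validity sensitivity gain on valid
#' trials (1 on invalid trials). A zero-opacity target is invisible, so the
#' probability is clamped to exactly 0.5 at `opacity <= 0`.
#'
#' @param opacity_pct target opacity in percent (vectorized).
#' @param observer an `observer_params` object.
#' @param valid logical; validly cued trial?
#' @return numeric vector of probabilities in \[0.5, 1 - lapse\].
#' @export
psychometric_prob <- function(opacity_pct, observer = observer_params(),
                              valid = TRUE) {
  gain <- ifelse(valid, observer$validity_sensitivity_gain, 1)
  x <- observer$psychometric_slope *
    (gain * opacity_pct - observer$threshold_opacity_pct)
  p <- 0.5 + (0.5 - observer$lapse_rate) * stats::plogis(x)
  ifelse(opacity_pct <= 0, 0.5, p)
}

#' Simulate one behavioral response
#'
#' Draws accuracy from a Bernoulli with the psychometric probability at the
#' trial's opacity and validity, and a log-normal reaction time that is
#' independent of eccentricity.
#'
#' @param trial one-row data.frame with at least `validity` and
#'   `target_opacity_pct`.
#' @param observer an `observer_params` object.
#' @return list with `accuracy` (0/1) and `rt_ms`.
#' @export
simulate_response <- function(trial, observer = observer_params()) {
  stopifnot(!is.null(trial$target_opacity_pct))
  p <- psychometric_prob(trial$target_opacity_pct, observer,
                         valid = trial$validity == "valid")
  acc <- stats::rbinom(length(p), 1, p)
  rt <- stats::rlnorm(length(p), meanlog = log(observer$rt_location_ms),
                      sdlog = observer$rt_scale)
  list(accuracy = acc, rt_ms = rt)
}
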