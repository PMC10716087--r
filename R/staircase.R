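#' Initialize an n-up-1-down opacity staircase
#'
#' The staircases keep discrimination accuracy on validly cued trials near a
#' fixed level by adapting target opacity in 1% steps: after `n_up`
#' consecutive correct responses opacity decreases by one step (harder), after
#' any single error it increases by one step (easier). The asymptotic
#' percent-correct of an n-up-1-down rule is `0.5^(1/n)` (about 70.7% for
#' n = 2, 79.4% for n = 3). One independent staircase is run per eccentricity.
#'
#' @param n_up consecutive correct responses required before a step down
#'   (2 for the symbolic-cue experiment, 3 for the location-cue experiments).
#' @param opacity_pct starting opacity in percent.
#' @param step_pct step size in percent opacity.
#' @param opacity_min floor opacity in percent (> 0 so the target never
#'   vanishes entirely).
#' @param eccentricity optional eccentricity label this staircase serves.
#' @return A `staircase_state` list.
#' @export
staircase_init <- function(n_up = 2L, opacity_pct = 50, step_pct = 1,
                           opacity_min = 1, eccentricity = NA_character_) {
  stopifnot(n_up >= 1, step_pct > 0, opacity_min > 0,
            opacity_min <= opacity_pct, opacity_pct <= 100)
  structure(list(n_up = as.integer(n_up), step_pct = step_pct,
                 opacity_pct = opacity_pct, opacity_min = opacity_min,
                 consecutive_correct = 0L, eccentricity = eccentricity),
            class = "staircase_state")
}

#' Update a staircase after one response
#'
#' @param state a `staircase_state` from [staircase_init()].
#' @param correct logical; was the response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1, !is.na(correct))
  if (correct) {
    cc <- state$consecutive_correct + 1L
    if (cc >= state$n_up) {
      state$opacity_pct <- max(state$opacity_min,
                               state$opacity_pct - state$step_pct)
      state$consecutive_correct <- 0L
    } else {
      state$consecutive_correct <- cc
    }
  } else {
    state$opacity_pct <- min(100, state$opacity_pct + state$step_pct)
    state$consecutive_correct <- 0L
  }
  state
}

#' Run a staircase against a simulated observer
#'
#' Couples an n-up-1-down staircase to a psychometric observer (see
#' [observer_params()]) and reports the post-burn-in proportion correct and
#' the opacity trajectory. For a monotone observer spanning the equilibrium
#' accuracy, the post-burn-in accuracy converges to `0.5^(1/n_up)` up to
#' Monte-Carlo and step-quantization error.
#'
#' @param n_up staircase rule parameter (2 or 3 in the cueing experiments).
#' @param observer an `observer_params` object; its psychometric function
#'   must be strictly increasing in opacity.
#' @param n_trials total number of simulated trials (>= 200).
#' @param seed integer RNG seed.
#' @param burn_in trials discarded before computing accuracy (the staircase
#'   must first descend from its start value to the equilibrium band).
#' @param start_opacity starting opacity in percent.
#' @return list with `accuracy` (post-burn-in proportion correct),
#'   `opacity_trace` (per-trial opacity), `responses` (0/1 vector).
#' @export
simulate_staircase <- function(n_up = 2L, observer = observer_params(),
                               n_trials = 5000L, seed = 1L, burn_in = 500L,
                               start_opacity = 50) {
  stopifnot(n_trials >= 200, burn_in < n_trials)
  if (observer$psychometric_slope <= 0)
    stop("observer psychometric function must be strictly increasing in opacity ",
         "(psychometric_slope > 0)")
  set.seed(substream_seed(seed, "staircase"))
  st <- staircase_init(n_up = n_up, opacity_pct = start_opacity)
  opac <- numeric(n_trials)
  resp <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    opac[i] <- st$opacity_pct
    p <- psychometric_prob(st$opacity_pct, observer, valid = TRUE)
    resp[i] <- stats::rbinom(1, 1, p)
    st <- staircase_update(st, resp[i] == 1L)
  }
  keep <- seq.int(burn_in + 1L, n_trials)
  list(accuracy = mean(resp[keep]), opacity_trace = opac,
       responses = resp)
}
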