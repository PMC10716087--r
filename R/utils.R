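#' @importFrom stats rnorm runif rbinom rpois rlnorm pnorm qnorm sd approx
#'   coef lm complete.cases aggregate rgamma setNames cor
#' @importFrom utils write.csv read.csv modifyList
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named random substream seed
#'
#' Every stochastic stage of the pipeline (design shuffling, observer
#' responses, trace noise, fold assignment) seeds its own RNG stream derived
#' deterministically from a single master seed and a stage name, so stages are
#' independently reproducible.
#'
#' @param seed master integer seed (non-negative).
#' @param name character stage label, e.g. `"design"` or `"folds"`.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  # Lehmer-style mix; keep within the 32-bit signed range R requires
  as.integer((seed * 48271 + h * 16807 + 12345) %% 2147483647)
}

# largest-remainder apportionment of `total` over weights `w` (integer result)
apportion <- function(total, w) {
  raw <- total * w / sum(w)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

stop_unknown_keys <- function(supplied, known, where) {
  bad <- setdiff(names(supplied), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s key(s): %s (known keys: %s)",
                 where, paste(bad, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
}
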