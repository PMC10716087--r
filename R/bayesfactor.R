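#' One-way repeated-measures JZS Bayes factor
#'
#' Default-prior (JZS) Bayes factor for a one-factor within-participant
#' design, comparing the model with a condition effect plus participant
#' effects against the participant-only null. Both effect blocks receive
#' Zellner-Siow g-priors (Cauchy on standardized effects; scale 0.5 for the
#' condition effect, 1 for the participant block, the conventional defaults),
#' with the factor effects projected onto orthonormal sum-to-zero contrasts.
#' The two g parameters are integrated out numerically on a log-scale grid;
#' because the participant and condition design blocks are orthogonal in a
#' balanced design, each marginal-likelihood evaluation is closed-form up to
#' the two one-dimensional eigen-decompositions, so the quadrature is exact
#' to grid resolution.
#'
#' `bf01` > 1 favours the null; values above 3 are conventionally read as
#' substantial evidence for the null (here: that the staircases equated
#' accuracy across eccentricities).
#'
#' @param y numeric response (e.g. per-participant mean accuracy per cell).
#' @param subject factor/vector of participant ids (balanced over
#'   `condition`).
#' @param condition factor/vector of condition labels.
#' @param rscale_fixed prior scale for the condition effect.
#' @param rscale_random prior scale for the participant block.
#' @param grid_n quadrature grid points per g dimension.
#' @param grid_range range of `log(g)` covered by the grid.
#' @return A `bf_result` list: `bf01`, `bf10`, `method`, `n_participants`.
#' @export
bf01_rm_anova <- function(y, subject, condition,
                          rscale_fixed = 0.5, rscale_random = 1,
                          grid_n = 101L, grid_range = c(-15, 15)) {
  subject <- factor(subject)
  condition <- factor(condition)
  stopifnot(length(y) == length(subject), length(y) == length(condition))
  tab <- table(subject, condition)
  if (any(tab == 0)) stop("design is not complete: every subject needs every condition")
  if (any(tab != tab[1])) stop("design must be balanced for the JZS quadrature")
  if (nlevels(subject) < 2) stop("need at least 2 subjects")
  n <- length(y)
  yc <- y - mean(y)
  s0 <- sum(yc^2)
  Xs <- sumzero_design(subject)
  Xe <- sumzero_design(condition)
  # balanced crossing makes the two blocks orthogonal; verify
  if (max(abs(crossprod(Xs, Xe))) > 1e-8 * n)
    stop("participant and condition design blocks are not orthogonal")
  blk_s <- block_spectrum(Xs, yc)
  blk_e <- block_spectrum(Xe, yc)

  u <- seq(grid_range[1], grid_range[2], length.out = grid_n)
  h <- u[2] - u[1]
  lw <- rep(log(h), grid_n); lw[c(1, grid_n)] <- log(h / 2) # trapezoid
  g <- exp(u)
  lprior_s <- invgamma_logpdf(g, rscale_random) + u # + u: Jacobian of g = e^u
  lprior_e <- invgamma_logpdf(g, rscale_fixed) + u

  ld_s <- vapply(g, function(gg) sum(log1p(gg * blk_s$d)), numeric(1))
  ld_e <- vapply(g, function(gg) sum(log1p(gg * blk_e$d)), numeric(1))
  q_s <- vapply(g, function(gg) sum(blk_s$w / (1 / gg + blk_s$d)), numeric(1))
  q_e <- vapply(g, function(gg) sum(blk_e$w / (1 / gg + blk_e$d)), numeric(1))

  # null model: subject block only
  lm0 <- -0.5 * ld_s - ((n - 1) / 2) * log(s0 - q_s)
  log_den <- logsumexp(lm0 + lprior_s + lw)
  # full model: subject + condition blocks (separable in the two g's)
  lq <- log(pmax(s0 - outer(q_s, q_e, "+"), .Machine$double.xmin))
  lm1 <- -0.5 * outer(ld_s, ld_e, "+") - ((n - 1) / 2) * lq
  log_num <- logsumexp(lm1 + outer(lprior_s + lw, lprior_e + lw, "+"))
  bf10 <- exp(log_num - log_den)
  structure(list(bf01 = 1 / bf10, bf10 = bf10, method = "jzs_quadrature",
                 n_participants = nlevels(subject)),
            class = "bf_result")
}

# orthonormal sum-to-zero design block for a factor (n x (levels-1))
sumzero_design <- function(f) {
  a <- nlevels(f)
  Qf <- qr.Q(qr(matrix(1, a, 1)), complete = TRUE)[, -1, drop = FALSE]
  Z <- stats::model.matrix(~ f - 1)
  X <- Z %*% Qf
  sweep(X, 2, colMeans(X)) # exactly orthogonal to the intercept
}

# eigen-spectrum of X'X plus squared projections of y onto the eigenvectors;
# lets |I + gXX'| and y'(I + gXX')^{-1}y be evaluated in O(p) per g
block_spectrum <- function(X, yc) {
  W <- crossprod(X)
  e <- eigen(W, symmetric = TRUE)
  v <- crossprod(X, yc)
  w <- as.numeric(crossprod(e$vectors, v))^2
  list(d = e$values, w = w)
}

invgamma_logpdf <- function(g, rscale) {
  a <- 0.5; b <- rscale^2 / 2
  a * log(b) - lgamma(a) - (a + 1) * log(g) - b / g
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' BIC-approximation Bayes factor for the one-way RM design
#'
#' A coarse large-sample approximation used as a fallback when the JZS
#' quadrature is not applicable: `BF01 = exp((BIC_full - BIC_null) / 2)` from
#' fixed-effects fits with participant as a blocking factor.
#'
#' @inheritParams bf01_rm_anova
#' @return A `bf_result` list with `method = "bic"`.
#' @export
bf01_bic <- function(y, subject, condition) {
  d <- data.frame(y = y, subject = factor(subject),
                  condition = factor(condition))
  full <- stats::lm(y ~ subject + condition, data = d)
  null <- stats::lm(y ~ subject, data = d)
  bf01 <- exp((stats::BIC(full) - stats::BIC(null)) / 2)
  structure(list(bf01 = bf01, bf10 = 1 / bf01, method = "bic",
                 n_participants = nlevels(d$subject)),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF01 = %.3f (BF10 = %.3f), method = %s, n = %d participants\n",
              x$bf01, x$bf10, x$method, x$n_participants))
  invisible(x)
}
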