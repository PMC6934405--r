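#' Simulated psychophysical observer
#'
#' A parametric stand-in for a listener in a forced-choice task. The
#' probability of a correct response at stimulus level `x` (in task units on
#' a normalized axis, see [run_track]) is
#' `gamma + (1 - gamma - lambda) * pnorm(beta * (log10(x) - alpha))`:
#' a cumulative-Gaussian psychometric function in log10 level, floored at the
#' guess rate and ceilinged by the lapse rate.
#'
#' @param alpha Threshold location on the log10 task-unit axis (the midpoint
#'   of the underlying Gaussian).
#' @param beta Slope per log10 unit (> 0: larger levels are easier).
#' @param gamma Guess rate; 1/3 for a 3-alternative task (default).
#' @param lambda Lapse rate in `[0, 0.1]` (default 0.02).
#' @return An object of class `"observer_model"`.
#' @examples
#' obs <- observer_model(alpha = -1.1, beta = 8)
#' p_correct(obs, 10^-1.1)  # midpoint: 2/3 minus half the lapse
#' @export
observer_model <- function(alpha, beta, gamma = 1/3, lambda = 0.02) {
  if (beta <= 0) stop("slope beta must be positive")
  if (gamma < 0 || gamma >= 1) stop("guess rate must be in [0, 1)")
  if (lambda < 0 || lambda > 0.1) stop("lapse rate must be in [0, 0.1]")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    "simulated observer: alpha = %.3f (log10 units), beta = %.2f, gamma = %.3f, lambda = %.3f\n",
    x$alpha, x$beta, x$gamma, x$lambda))
  invisible(x)
}

#' Probability of a correct response
#'
#' @param obs An [observer_model].
#' @param level Stimulus level in (normalized) task units, `> 0`. Vectorised.
#' @return Probability in `[gamma, 1 - lambda]`.
#' @export
p_correct <- function(obs, level) {
  stopifnot(inherits(obs, "observer_model"))
  if (any(level <= 0)) stop("level must be positive")
  obs$gamma + (1 - obs$gamma - obs$lambda) *
    stats::pnorm(obs$beta * (log10(level) - obs$alpha))
}

#' Level at which the observer reaches a target proportion correct
#'
#' Inverts the observer's psychometric function; useful as ground truth when
#' checking threshold estimators against simulated data.
#'
#' @param obs An [observer_model].
#' @param p Target probability correct, strictly between `gamma` and
#'   `1 - lambda` (default 0.794, the three-down/one-up convergence point).
#' @return Level in normalized task units.
#' @export
true_threshold <- function(obs, p = 0.5^(1/3)) {
  stopifnot(inherits(obs, "observer_model"))
  f <- (p - obs$gamma) / (1 - obs$gamma - obs$lambda)
  if (f <= 0 || f >= 1) stop("target p outside the observer's range")
  10^(obs$alpha + stats::qnorm(f) / obs$beta)
}
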