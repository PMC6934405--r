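## Threshold estimation from adaptive tracks: maximum-likelihood fit of a
## guess-rate-floored cumulative-Gaussian psychometric function in log10
## level, with track-level quality control (negative slopes and thresholds
## outside the measured range are discarded) and a 2.5 x IQR outlier screen
## on the resulting threshold tables.

#' Fit a psychometric function to a staircase track
#'
#' Maximum-likelihood fit of
#' `p(x) = gamma + (1 - gamma - lambda) * pnorm(beta * (x - alpha))`
#' to the per-trial (log10 level, correct) pairs of a track, with the guess
#' rate fixed at 1/3 and the lapse rate fixed at `lambda`. The reported
#' threshold is the level at which the fitted function reaches `target_p`
#' (default `0.5^(1/3)`, about 79.4% correct, the convergence point of the
#' three-down/one-up rule). Slope is left unconstrained in sign so that
#' misbehaving tracks are detected rather than forced: fits with a negative
#' slope, or with a threshold outside the range of levels the track visited,
#' are flagged invalid.
#'
#' @param track A [run_track] result (practice trials are ignored).
#' @param lambda Fixed lapse rate; default 0.01. A sensitivity switch: try
#'   0, 0.01 and 0.05.
#' @param target_p Proportion correct defining the threshold (default
#'   `0.5^(1/3)`).
#' @return An object of class `"psychfit"`: `threshold` (log10 normalized
#'   task units), `slope` (per log10 unit), `gamma`, `lambda`, `valid`,
#'   `reject_reason` (`"none"`, `"negative_slope"`, `"out_of_range"` or
#'   `"no_convergence"`), plus the fitted data and `level_ref`.
#' @export
fit_track <- function(track, lambda = 0.01, target_p = 0.5^(1/3)) {
  stopifnot(inherits(track, "staircase_track"))
  tr <- track$trials[!track$trials$practice & track$trials$level > 0, ]
  if (nrow(tr) < 10L || length(unique(tr$level)) < 2L) {
    stop("need at least 10 adaptive trials spanning at least 2 levels")
  }
  ref <- track$config$level_ref
  x <- log10(tr$level / ref)
  y <- as.numeric(tr$correct)
  gamma <- 1 / 3

  nll <- function(par) {
    p <- gamma + (1 - gamma - lambda) * stats::pnorm(par[2] * (x - par[1]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  starts <- list(c(stats::median(x), 5), c(stats::median(x), 15),
                 c(stats::median(x), -5))
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, nll, method = "Nelder-Mead",
                          control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)

  out <- list(threshold = NA_real_, slope = NA_real_, gamma = gamma,
              lambda = lambda, target_p = target_p, valid = FALSE,
              reject_reason = "no_convergence", level_ref = ref,
              task = track$config$task, x = x, y = y)
  class(out) <- "psychfit"
  if (length(fits) == 0L) return(out)

  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  alpha <- best$par[1]; beta <- best$par[2]
  f <- (target_p - gamma) / (1 - gamma - lambda)
  thr <- alpha + stats::qnorm(f) / beta
  out$threshold <- thr
  out$slope <- beta
  out$alpha <- alpha
  if (beta <= 0) {
    out$reject_reason <- "negative_slope"
  } else if (thr < min(x) || thr > max(x)) {
    out$reject_reason <- "out_of_range"
  } else {
    out$valid <- TRUE
    out$reject_reason <- "none"
  }
  out
}

#' @export
print.psychfit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "psychometric fit (%s): threshold %.3f log10 units (%.1f%% point), slope %.2f\n",
      x$task, x$threshold, 100 * x$target_p, x$slope))
  } else {
    cat(sprintf("psychometric fit (%s): INVALID (%s)\n", x$task,
                x$reject_reason))
  }
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(threshold = object$threshold, slope = object$slope,
    gamma = object$gamma, lambda = object$lambda)
}

#' @export
predict.psychfit <- function(object, level = NULL, ...) {
  x <- if (is.null(level)) object$x else log10(level / object$level_ref)
  object$gamma + (1 - object$gamma - object$lambda) *
    stats::pnorm(object$slope * (x - object$alpha))
}

#' @export
plot.psychfit <- function(x, n_bins = 8, ...) {
  bins <- cut(x$x, n_bins)
  px <- tapply(x$x, bins, mean)
  py <- tapply(x$y, bins, mean)
  graphics::plot(px, py, ylim = c(0, 1), xlab = "log10 level",
                 ylab = "proportion correct", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, x$gamma + (1 - x$gamma - x$lambda) *
                    stats::pnorm(x$slope * (xs - x$alpha)))
  graphics::abline(h = x$gamma, lty = 3)
  if (x$valid) graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Partition psychometric fits into kept and discarded
#'
#' Discards exactly the invalid fits (negative slope, threshold outside the
#' measured range, or no convergence) and reports the discard fraction.
#'
#' @param fits List of [fit_track] results.
#' @return List: `kept`, `discarded` (both lists), `discard_fraction`,
#'   `reasons` (table).
#' @export
qc_tracks <- function(fits) {
  valid <- vapply(fits, `[[`, logical(1), "valid")
  list(kept = fits[valid], discarded = fits[!valid],
       discard_fraction = mean(!valid),
       reasons = table(vapply(fits[!valid], `[[`, character(1),
                              "reject_reason")))
}

#' Interquartile-range outlier mask
#'
#' Flags values beyond `k` times the interquartile range above the third or
#' below the first quartile. Quartiles use linear interpolation between order
#' statistics (R quantile type 7). Single-pass: the rule is not re-applied to
#' the kept set.
#'
#' @param values Numeric vector (at least 4 values; fewer produce no flags
#'   and a warning).
#' @param k Fence multiplier (default 2.5).
#' @return Logical mask, `TRUE` = outlier.
#' @export
iqr_outliers <- function(values, k = 2.5) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  (values > q[2] + k * iqr) | (values < q[1] - k * iqr)
}

#' Correlation between consecutive test blocks
#'
#' Pearson correlation between the block-1 and block-2 log10 thresholds of
#' each task (and session, when present), a consistency check on the
#' adaptive measurements.
#'
#' @param records Data frame with columns `subject`, `task`, `block`,
#'   `threshold_log10` and optionally `session`.
#' @return Data frame: one row per task (x session) with `r` and `n_pairs`.
#' @export
block_correlation <- function(records) {
  by_cols <- intersect(c("task", "session"), names(records))
  split_key <- interaction(records[by_cols], drop = TRUE)
  rows <- lapply(split(records, split_key), function(d) {
    wide <- merge(d[d$block == 1, c("subject", "threshold_log10")],
                  d[d$block == 2, c("subject", "threshold_log10")],
                  by = "subject", suffixes = c("_b1", "_b2"))
    wide <- wide[stats::complete.cases(wide), ]
    if (nrow(wide) < 3L) stop("fewer than 3 complete block pairs")
    out <- d[1, by_cols, drop = FALSE]
    out$r <- stats::cor(wide$threshold_log10_b1, wide$threshold_log10_b2)
    out$n_pairs <- nrow(wide)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold table from a simulated study
#'
#' Fits every staircase track of a study, applies track QC, flags subjects
#' left without any valid track in some task/session cell, screens the
#' surviving log10 thresholds with the IQR rule within group x task x
#' session, and returns one record per track alongside a per-session summary
#' (mean of the two block thresholds after QC).
#'
#' @param study A [generate_study] result in `"tracks"` mode.
#' @param lambda,k Passed to [fit_track] and [iqr_outliers].
#' @return List: `records` (per-track data frame with `threshold_log10`,
#'   `valid`, `reject_reason`, `outlier`), `per_session` (block-averaged),
#'   `discard_fraction`, `excluded_subjects`.
#' @export
threshold_table <- function(study, lambda = 0.01, k = 2.5) {
  stopifnot(inherits(study, "vocotrain_study"), !is.null(study$tracks))
  idx <- study$track_index
  fits <- lapply(study$tracks, fit_track, lambda = lambda)
  idx$threshold_log10 <- vapply(fits, `[[`, numeric(1), "threshold")
  idx$valid <- vapply(fits, `[[`, logical(1), "valid")
  idx$reject_reason <- vapply(fits, `[[`, character(1), "reject_reason")
  idx$threshold_log10[!idx$valid] <- NA_real_

  # subjects with an empty task x session cell after QC are flagged
  cell <- stats::aggregate(valid ~ subject + task + session, idx, sum)
  bad <- unique(cell$subject[cell$valid == 0])

  idx$outlier <- FALSE
  grp_key <- interaction(idx$group, idx$task, idx$session, drop = TRUE)
  for (g in levels(grp_key)) {
    sel <- which(grp_key == g & idx$valid)
    if (length(sel) >= 4L) {
      idx$outlier[sel] <- iqr_outliers(idx$threshold_log10[sel], k)
    }
  }

  keep <- idx$valid & !idx$outlier
  per_session <- stats::aggregate(
    threshold_log10 ~ subject + group + task + session, idx[keep, ], mean)
  list(records = idx, per_session = per_session,
       discard_fraction = mean(!idx$valid),
       outlier_fraction = mean(idx$outlier[idx$valid]),
       excluded_subjects = bad)
}
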