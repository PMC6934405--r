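## Transformed up-down adaptive staircases for 3I-3AFC oddball tasks.
##
## All three tasks share one two-phase rule: a one-down/one-up phase with a
## large multiplicative step until the first incorrect response, then a
## permanent switch to a three-down/one-up phase with a smaller step,
## converging on the 0.5^(1/3) ~ 79.4% point of the psychometric function.
## The tracked variable is multiplicative (modulation depth m for AMD, the
## modulation-rate increment in Hz for AMRD, the frequency increment in Hz
## for FD), so steps are level factors: divide on a "down" (harder) move,
## multiply on an "up" (easier) move, clamped to [level_floor, level_cap].

#' Staircase configuration
#'
#' Task defaults follow the study design: AMD starts at full modulation
#' (m = 1, the cap) with factors 1.58 (4 dB) then 1.26 (2 dB); AMRD tracks
#' the modulation-rate increment above an 8-Hz standard, starting at 50% of
#' the standard (4 Hz) with factors 1.4 then sqrt(1.4); FD tracks the
#' frequency increment above an 800-Hz standard, starting at 50% (400 Hz)
#' with factors 2 then sqrt(2). Observers see the level normalized by
#' `level_ref` (1 for AMD, the standard rate for AMRD, the base frequency
#' for FD), which makes the multiplicative track additive in log10 units.
#'
#' @param task `"AMD"`, `"AMRD"` or `"FD"`.
#' @param n_trials Adaptive trials per block (30 in test blocks, 60 in
#'   training blocks). Default 30.
#' @param standard AMRD standard modulation rate in Hz (default 8; sets the
#'   start level to half the standard).
#' @param base FD standard frequency in Hz (default 800).
#' @param start_level,phase1_step,phase2_step,level_cap,level_floor,level_ref
#'   Override the task defaults.
#' @param phase2_down Consecutive correct responses required for a downward
#'   move in phase 2 (default 3, targeting `0.5^(1/3)` = 79.4% correct;
#'   1 gives a plain one-down/one-up rule targeting 50%).
#' @return A list of class `"staircase_config"`.
#' @examples
#' staircase_config("AMRD")$start_level  # 4 Hz: 50% of the 8-Hz standard
#' @export
staircase_config <- function(task = c("AMD", "AMRD", "FD"), n_trials = 30,
                             standard = 8, base = 800, start_level = NULL,
                             phase1_step = NULL, phase2_step = NULL,
                             level_cap = NULL, level_floor = NULL,
                             level_ref = NULL, phase2_down = 3) {
  task <- match.arg(task)
  def <- switch(task,
    AMD = list(start = 1.0, s1 = 1.58, s2 = 1.26,
               cap = 1.0, floor = 1e-4, ref = 1),
    AMRD = list(start = 0.5 * standard, s1 = 1.4, s2 = sqrt(1.4),
                cap = 2 * standard, floor = 1e-3 * standard, ref = standard),
    FD = list(start = 0.5 * base, s1 = 2, s2 = sqrt(2),
              cap = base, floor = 1e-4 * base, ref = base)
  )
  cfg <- list(
    task = task,
    n_trials = as.integer(n_trials),
    n_intervals = 3L,
    standard = if (task == "AMRD") standard else NA_real_,
    base = if (task == "FD") base else NA_real_,
    start_level = start_level %||% def$start,
    phase1_rule = c(down = 1L, up = 1L),
    phase2_rule = c(down = as.integer(phase2_down), up = 1L),
    phase1_step = phase1_step %||% def$s1,
    phase2_step = phase2_step %||% def$s2,
    level_cap = level_cap %||% def$cap,
    level_floor = level_floor %||% def$floor,
    level_ref = level_ref %||% def$ref
  )
  if (cfg$phase1_step <= 1 || cfg$phase2_step <= 1) stop("step factors must exceed 1")
  if (cfg$level_floor <= 0 || cfg$level_floor >= cfg$level_cap) {
    stop("need 0 < level_floor < level_cap")
  }
  if (cfg$n_trials < 1) stop("n_trials must be at least 1")
  structure(cfg, class = "staircase_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) min(max(x, lo), hi)

## One staircase update. state: list(level, phase, cc). Returns new state plus
## the direction of the attempted move ("down", "up", "hold").
staircase_step <- function(state, correct, cfg) {
  dir <- "hold"
  level <- state$level
  if (state$phase == 1L) {
    if (correct) {
      level <- level / cfg$phase1_step
      dir <- "down"
    } else {
      level <- level * cfg$phase1_step
      dir <- "up"
      state$phase <- 2L
      state$cc <- 0L
    }
  } else {
    if (correct) {
      state$cc <- state$cc + 1L
      if (state$cc >= cfg$phase2_rule[["down"]]) {
        level <- level / cfg$phase2_step
        dir <- "down"
        state$cc <- 0L
      }
    } else {
      level <- level * cfg$phase2_step
      dir <- "up"
      state$cc <- 0L
    }
  }
  state$level <- clamp(level, cfg$level_floor, cfg$level_cap)
  state$dir <- dir
  state
}

#' Level for the next trial of a track
#'
#' Replays the recorded responses through the staircase rule and returns the
#' level the next trial would present.
#'
#' @param track A [run_track] result.
#' @param cfg The track's [staircase_config] (defaults to `track$config`).
#' @return Level in task units.
#' @export
next_level <- function(track, cfg = track$config) {
  tr <- track$trials[!track$trials$practice, , drop = FALSE]
  if (nrow(tr) == 0L) stop("track has no adaptive trials")
  state <- list(level = cfg$start_level, phase = 1L, cc = 0L)
  for (i in seq_len(nrow(tr))) state <- staircase_step(state, tr$correct[i], cfg)
  state$level
}

#' Simulate one 3I-3AFC trial
#'
#' The target interval is drawn uniformly from 1..3; the simulated observer
#' responds correctly with probability `p_correct(obs, level)`, otherwise the
#' response is uniform over the two non-target intervals.
#'
#' @param level Stimulus level on the observer's normalized axis (> 0).
#' @param obs An [observer_model].
#' @return A one-row data frame: `level`, `target`, `response`, `correct`.
#' @export
run_trial <- function(level, obs) {
  target <- sample.int(3L, 1L)
  p <- p_correct(obs, level)
  correct <- stats::runif(1) < p
  response <- if (correct) target else sample(setdiff(1:3, target), 1L)
  data.frame(level = level, target = target, response = response,
             correct = correct)
}

#' Run an adaptive staircase track against a simulated observer
#'
#' @param cfg A [staircase_config].
#' @param obs An [observer_model] whose level axis is the track level divided
#'   by `cfg$level_ref`, in log10 units.
#' @param seed Integer seed; the track is fully reproducible from it (target
#'   intervals and response noise share one generator in a fixed draw order).
#' @param n_trials Number of adaptive trials (default `cfg$n_trials`).
#' @param include_practice Prepend the five customary practice trials (three
#'   easy at the start level, two impossible at zero); they are flagged
#'   `practice`, presented at fixed levels, and do not advance the staircase.
#' @param start_phase Start in phase 1 (default) or directly in the
#'   three-down/one-up phase 2 (used when studying the asymptotic rule).
#' @return An object of class `"staircase_track"`: list with `config`,
#'   `trials` (data frame: trial, level, phase, target, response, correct,
#'   direction, reversal, practice), `n_reversals` and `seed`.
#' @export
run_track <- function(cfg, obs, seed = NULL, n_trials = cfg$n_trials,
                      include_practice = FALSE, start_phase = 1L) {
  stopifnot(inherits(cfg, "staircase_config"), inherits(obs, "observer_model"))
  if (!is.null(seed)) set.seed(seed)

  rows <- vector("list", n_trials + if (include_practice) 5L else 0L)
  i <- 0L
  if (include_practice) {
    practice_levels <- c(rep(cfg$start_level, 3L), 0, 0)
    for (lev in practice_levels) {
      i <- i + 1L
      target <- sample.int(3L, 1L)
      p <- if (lev > 0) p_correct(obs, lev / cfg$level_ref) else obs$gamma
      correct <- stats::runif(1) < p
      response <- if (correct) target else sample(setdiff(1:3, target), 1L)
      rows[[i]] <- data.frame(trial = i, level = lev, phase = NA_integer_,
                              target = target, response = response,
                              correct = correct, direction = "hold",
                              reversal = FALSE, practice = TRUE)
    }
  }

  # inlined trial loop (same draw order as run_trial) with preallocated
  # columns; per-trial data.frame construction is too slow for the
  # simulation studies built on this function
  level_v <- phase_v <- numeric(n_trials)
  target_v <- response_v <- integer(n_trials)
  correct_v <- logical(n_trials)
  dir_v <- character(n_trials)
  state <- list(level = cfg$start_level, phase = as.integer(start_phase),
                cc = 0L)
  for (k in seq_len(n_trials)) {
    level_v[k] <- state$level
    phase_v[k] <- state$phase
    target <- sample.int(3L, 1L)
    p <- obs$gamma + (1 - obs$gamma - obs$lambda) *
      stats::pnorm(obs$beta * (log10(state$level / cfg$level_ref) - obs$alpha))
    correct <- stats::runif(1) < p
    target_v[k] <- target
    response_v[k] <- if (correct) target else sample(setdiff(1:3, target), 1L)
    correct_v[k] <- correct
    state <- staircase_step(state, correct, cfg)
    dir_v[k] <- state$dir
  }
  adaptive <- data.frame(trial = i + seq_len(n_trials), level = level_v,
                         phase = as.integer(phase_v), target = target_v,
                         response = response_v, correct = correct_v,
                         direction = dir_v, reversal = FALSE,
                         practice = FALSE)
  trials <- if (i > 0L) rbind(do.call(rbind, rows[seq_len(i)]), adaptive)
            else adaptive
  trials$reversal <- mark_reversals(trials$direction, trials$practice)
  out <- structure(list(config = cfg, trials = trials,
                        n_reversals = sum(trials$reversal), seed = seed),
                   class = "staircase_track")
  out
}

## Reversal = sign change between successive non-hold moves (practice ignored).
mark_reversals <- function(direction, practice) {
  rev_flag <- rep(FALSE, length(direction))
  moves <- which(!practice & direction %in% c("down", "up"))
  if (length(moves) > 1L) {
    d <- direction[moves]
    rev_flag[moves[-1L][d[-1L] != d[-length(d)]]] <- TRUE
  }
  rev_flag
}

#' Count reversals in a track
#'
#' A reversal is a change of direction between successive level moves;
#' trials where the level holds (incomplete three-correct runs) are ignored.
#'
#' @param track A [run_track] result.
#' @return Integer count.
#' @export
count_reversals <- function(track) {
  sum(mark_reversals(track$trials$direction, track$trials$practice))
}

#' @export
print.staircase_track <- function(x, ...) {
  tr <- x$trials[!x$trials$practice, ]
  cat(sprintf("%s staircase track: %d trials, %d reversals, final level %.4g\n",
              x$config$task, nrow(tr), count_reversals(x),
              tr$level[nrow(tr)]))
  invisible(x)
}

#' @export
plot.staircase_track <- function(x, ...) {
  tr <- x$trials[!x$trials$practice, ]
  graphics::plot(tr$trial, tr$level, log = "y", type = "b",
                 pch = ifelse(tr$correct, 19, 1),
                 xlab = "trial", ylab = paste0("level (", x$config$task, ")"),
                 ...)
  rev_i <- which(tr$reversal)
  if (length(rev_i)) graphics::points(tr$trial[rev_i], tr$level[rev_i],
                                      pch = 4, cex = 1.6)
  invisible(x)
}

#' Block schedule for a study protocol
#'
#' @param protocol One of `"pretraining"` (two 60-trial vocoded-VCV blocks
#'   with feedback), `"pretest"` / `"posttest"` (one 60-trial VCV block plus
#'   two 30-trial blocks of each of AMD, AMRD and FD), or `"training_AMD"` /
#'   `"training_AMRD"` (21 blocks of 60 adaptive trials across two days, the
#'   standard modulation rate rotating over 4, 8 and 16 Hz in a Latin-square
#'   cycle).
#' @return A data frame of class `"study_schedule"`: one row per block with
#'   `day`, `task`, `block`, `fm_standard` and `trials_per_block`.
#' @examples
#' sum(build_schedule("training_AMD")$trials_per_block)  # 1260
#' @export
build_schedule <- function(protocol = c("pretraining", "pretest",
                                        "training_AMD", "training_AMRD",
                                        "posttest")) {
  protocol <- match.arg(protocol)
  sched <- switch(protocol,
    pretraining = data.frame(day = 1L, task = "VCV", block = 1:2,
                             fm_standard = NA_real_, trials_per_block = 60L),
    pretest = test_day_schedule(2L),
    posttest = test_day_schedule(4L),
    training_AMD = training_schedule("AMD"),
    training_AMRD = training_schedule("AMRD")
  )
  attr(sched, "protocol") <- protocol
  class(sched) <- c("study_schedule", "data.frame")
  sched
}

test_day_schedule <- function(day) {
  data.frame(
    day = day,
    task = c("VCV", rep(c("AMD", "AMRD", "FD"), each = 2L)),
    block = c(1L, rep(1:2, times = 3L)),
    fm_standard = c(NA, 8, 8, 8, 8, NA, NA),
    trials_per_block = c(60L, rep(30L, 6L))
  )
}

## 21 blocks = 7 cycles of a 3x3 Latin square over {4, 8, 16} Hz:
## cycle c uses row ((c-1) mod 3) + 1, so every cycle presents each standard
## exactly once. Nine blocks fall on day 2, twelve on day 3.
training_schedule <- function(task) {
  square <- rbind(c(4, 8, 16), c(8, 16, 4), c(16, 4, 8))
  fm <- unlist(lapply(seq_len(7L), function(c) square[(c - 1L) %% 3L + 1L, ]))
  data.frame(
    day = rep(c(2L, 3L), times = c(9L, 12L)),
    task = task,
    block = 1:21,
    fm_standard = fm,
    trials_per_block = 60L
  )
}

#' The 20-consonant by 3-vowel VCV stimulus crossing
#'
#' @return A 60-row data frame with columns `consonant` and `vowel`.
#' @export
vcv_tokens <- function() {
  fm <- feature_map()
  out <- expand.grid(consonant = fm$consonant, vowel = c("a", "i", "u"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(out$consonant, out$vowel), , drop = FALSE]
}

#' Asymptotic performance of an adaptive rule
#'
#' Estimates the proportion correct that a staircase converges on, by running
#' many tracks against an observer with a known smooth psychometric function
#' and averaging the observer's true `p_correct` at the late-trial levels.
#' For a three-down/one-up rule this should approach `0.5^(1/3)` (about
#' 79.4% correct).
#'
#' @param cfg A [staircase_config].
#' @param obs An [observer_model].
#' @param n_tracks Number of simulated tracks (default 500).
#' @param n_trials Trials per track (default 100).
#' @param tail Number of final trials whose levels are evaluated (default 20).
#' @param seed Integer seed.
#' @return A list of class `"converged_performance"`: `p_asymptote` (mean
#'   true probability correct at converged levels), `se` (standard error over
#'   tracks), `n_tracks`, `n_trials`, `tail`.
#' @export
converged_performance <- function(cfg, obs, n_tracks = 500, n_trials = 100,
                                  tail = 20, seed = 1) {
  if (n_trials < 2 * tail) {
    warning("few trials relative to the evaluation tail; estimate may not be asymptotic")
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_tracks)
  per_track <- vapply(seeds, function(s) {
    tr <- run_track(cfg, obs, seed = s, n_trials = n_trials)
    lev <- utils::tail(tr$trials$level[!tr$trials$practice], tail)
    mean(p_correct(obs, lev / cfg$level_ref))
  }, numeric(1))
  structure(list(p_asymptote = mean(per_track),
                 se = stats::sd(per_track) / sqrt(n_tracks),
                 n_tracks = n_tracks, n_trials = n_trials, tail = tail),
            class = "converged_performance")
}

#' @export
print.converged_performance <- function(x, ...) {
  cat(sprintf(
    "converged performance: %.1f%% correct (SE %.2f) over %d tracks x %d trials\n",
    100 * x$p_asymptote, 100 * x$se, x$n_tracks, x$n_trials))
  invisible(x)
}
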