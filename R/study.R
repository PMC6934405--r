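## Whole-study synthetic data generator: three groups (control, AMD-trained,
## AMRD-trained) of simulated listeners, pre- and post-test adaptive tracks on
## the three psychophysical tasks, and VCV identification responses. Group and
## session effects are injected on the observers' threshold parameters (log10
## units) and on the feature-transmission probabilities, so the analysis
## pipeline can be validated by parameter recovery.

#' Study design for the synthetic generator
#'
#' Defaults reproduce the study conditions: 18 listeners per group, two test
#' sessions, pre-to-post threshold improvements (in log10 units, positive =
#' better) largest for the trained task of each trained group, and a general
#' session gain on consonant identification.
#'
#' @param n_per_group Listeners per group (default 18).
#' @param baseline_alpha Named numeric: baseline observer threshold location
#'   (log10 normalized task units) per task.
#' @param beta Observer slope per log10 unit (default 8).
#' @param lambda Observer lapse rate (default 0.02).
#' @param improvement 3 x 3 numeric matrix of pre-to-post threshold
#'   improvements in log10 units, rows = groups (control, AMD-trained,
#'   AMRD-trained), columns = tasks (AMD, AMRD, FD).
#' @param subject_sd Between-subject SD of `alpha` in log10 units
#'   (default 0.25).
#' @param baseline_t Named numeric: baseline feature-transmission
#'   probabilities (voice, manner, place) at pre-test.
#' @param t_gain Pre-to-post gain per group on the logit of each transmission
#'   probability (named by group).
#' @param t_subject_sd Between-subject SD on the logit of the transmission
#'   probabilities (default 0.3).
#' @param n_vcv_per_token VCV presentations per consonant-vowel token and
#'   session (default 1 = one 60-trial block).
#' @return A list of class `"study_design"`.
#' @export
study_design <- function(
    n_per_group = 18,
    baseline_alpha = c(AMD = -1.1, AMRD = -0.7, FD = -1.8),
    beta = 8, lambda = 0.02,
    improvement = rbind(
      control        = c(AMD = 0.08, AMRD = 0.10, FD = 0.18),
      `AMD-trained`  = c(AMD = 0.21, AMRD = 0.09, FD = 0.08),
      `AMRD-trained` = c(AMD = 0.07, AMRD = 0.23, FD = 0.07)
    ),
    subject_sd = 0.25,
    baseline_t = c(voice = 0.97, manner = 0.97, place = 0.75),
    t_gain = c(control = 0.30, `AMD-trained` = 0.42, `AMRD-trained` = 0.38),
    t_subject_sd = 0.3,
    n_vcv_per_token = 1) {
  if (n_per_group < 1) stop("need at least one listener per group")
  if (subject_sd < 0 || t_subject_sd < 0) stop("SDs must be non-negative")
  stopifnot(all(c("AMD", "AMRD", "FD") %in% names(baseline_alpha)),
            all(dim(improvement) == c(3L, 3L)))
  structure(list(
    n_per_group = as.integer(n_per_group),
    groups = c("control", "AMD-trained", "AMRD-trained"),
    tasks = c("AMD", "AMRD", "FD"),
    sessions = c("pretest", "posttest"),
    baseline_alpha = baseline_alpha, beta = beta, lambda = lambda,
    improvement = improvement, subject_sd = subject_sd,
    baseline_t = baseline_t, t_gain = t_gain, t_subject_sd = t_subject_sd,
    n_vcv_per_token = n_vcv_per_token
  ), class = "study_design")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Generate a full synthetic study
#'
#' Draws per-subject observer parameters from group/session means plus
#' between-subject noise, runs the pre- and post-test staircase blocks of
#' every task (two 30-trial blocks each), and simulates one VCV
#' identification block per session, plus two pre-training VCV blocks used
#' for group balancing. Fully reproducible from `seed`.
#'
#' @param design A [study_design].
#' @param seed Integer seed.
#' @param emit `"tracks"` (default; full per-trial staircase records) or
#'   `"thresholds"` (skip the staircases and emit noiseless-fit threshold
#'   records directly with block-level measurement noise `block_sd`; useful
#'   for fast calibration studies of the downstream models).
#' @param block_sd Block-level measurement SD (log10 units) in
#'   `"thresholds"` mode. Default 0.12.
#' @return A list of class `"vocotrain_study"` with elements `design`,
#'   `subjects`, `tracks` (list of [run_track] objects, `"tracks"` mode),
#'   `track_index` (data frame keyed subject/task/session/block),
#'   `thresholds` (`"thresholds"` mode), `vcv_trials` and `pretraining`.
#' @export
generate_study <- function(design = study_design(), seed = 1,
                           emit = c("tracks", "thresholds"),
                           block_sd = 0.12) {
  stopifnot(inherits(design, "study_design"))
  emit <- match.arg(emit)
  set.seed(seed)

  n <- design$n_per_group * length(design$groups)
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = rep(design$groups, each = design$n_per_group),
    stringsAsFactors = FALSE
  )
  # per-subject deviations, shared across tasks (a generally good listener
  # is good everywhere), plus task-specific jitter
  common_dev <- stats::rnorm(n, 0, design$subject_sd * 0.7)
  task_dev <- matrix(stats::rnorm(n * 3, 0, design$subject_sd * 0.7),
                     nrow = n, dimnames = list(NULL, design$tasks))
  t_dev <- stats::rnorm(n, 0, design$t_subject_sd)

  fmap <- feature_map()
  track_rows <- list(); tracks <- list(); thr_rows <- list()
  vcv_rows <- list(); pre_rows <- list()
  ti <- 0L

  for (i in seq_len(n)) {
    grp <- subjects$group[i]
    # pre-training: two 60-trial VCV blocks at reduced transmission (naive
    # listeners), mild within-day learning between blocks
    for (blk in 1:2) {
      t_pre <- inv_logit(logit(design$baseline_t) - 0.5 + 0.25 * (blk - 1) +
                           t_dev[i])
      ft <- feature_transmission(t_pre[["voice"]], t_pre[["manner"]],
                                 t_pre[["place"]])
      tr <- simulate_vcv_trials(ft, fmap, design$n_vcv_per_token)
      tr <- cbind(subject = subjects$subject[i], group = grp,
                  phase = paste0("pretraining", blk), block = blk, tr,
                  stringsAsFactors = FALSE)
      pre_rows[[length(pre_rows) + 1L]] <- tr
    }

    for (session in design$sessions) {
      post <- session == "posttest"
      for (task in design$tasks) {
        alpha <- design$baseline_alpha[[task]] + common_dev[i] +
          task_dev[i, task] -
          if (post) design$improvement[grp, task] else 0
        obs <- observer_model(alpha, design$beta, 1/3, design$lambda)
        cfg <- staircase_config(task, n_trials = 30)
        for (blk in 1:2) {
          if (emit == "tracks") {
            ti <- ti + 1L
            s <- sample.int(.Machine$integer.max, 1L)
            tracks[[ti]] <- run_track(cfg, obs, seed = s)
            track_rows[[ti]] <- data.frame(
              subject = subjects$subject[i], group = grp, task = task,
              session = session, block = blk, track = ti, seed = s,
              stringsAsFactors = FALSE)
          } else {
            thr_rows[[length(thr_rows) + 1L]] <- data.frame(
              subject = subjects$subject[i], group = grp, task = task,
              session = session, block = blk,
              threshold_log10 = log10(true_threshold(obs)) +
                stats::rnorm(1, 0, block_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
      t_now <- inv_logit(logit(design$baseline_t) + t_dev[i] +
                           if (post) design$t_gain[[grp]] else 0)
      ft <- feature_transmission(t_now[["voice"]], t_now[["manner"]],
                                 t_now[["place"]])
      tr <- simulate_vcv_trials(ft, fmap, design$n_vcv_per_token)
      tr <- cbind(subject = subjects$subject[i], group = grp,
                  phase = session, block = 1L, tr, stringsAsFactors = FALSE)
      vcv_rows[[length(vcv_rows) + 1L]] <- tr
    }
  }

  structure(list(
    design = design, seed = seed, subjects = subjects,
    tracks = if (emit == "tracks") tracks else NULL,
    track_index = if (emit == "tracks") do.call(rbind, track_rows) else NULL,
    thresholds = if (emit == "thresholds") do.call(rbind, thr_rows) else NULL,
    vcv_trials = do.call(rbind, vcv_rows),
    pretraining = do.call(rbind, pre_rows)
  ), class = "vocotrain_study")
}

#' @export
print.vocotrain_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d subjects (%d per group), seed %s\n",
              nrow(x$subjects), x$design$n_per_group, format(x$seed)))
  if (!is.null(x$track_index)) {
    cat(sprintf("  %d staircase tracks, %d VCV trials, %d pre-training trials\n",
                nrow(x$track_index), nrow(x$vcv_trials), nrow(x$pretraining)))
  } else {
    cat(sprintf("  %d threshold records, %d VCV trials\n",
                nrow(x$thresholds), nrow(x$vcv_trials)))
  }
  invisible(x)
}

#' Write a study's CSV files
#'
#' Emits the analysis pipeline's input schemas: `vcv_trials.csv`,
#' `pretraining.csv`, and either per-trial `tracks.csv` or `thresholds.csv`.
#'
#' @param study A [generate_study] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "vocotrain_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$vcv_trials, file.path(dir, "vcv_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pretraining, file.path(dir, "pretraining.csv"),
                   row.names = FALSE)
  if (!is.null(study$tracks)) {
    all_tr <- do.call(rbind, lapply(seq_along(study$tracks), function(k) {
      idx <- study$track_index[k, ]
      tr <- study$tracks[[k]]$trials
      cbind(subject = idx$subject, task = idx$task, session = idx$session,
            block = idx$block, tr, stringsAsFactors = FALSE)
    }))
    utils::write.csv(all_tr, file.path(dir, "tracks.csv"), row.names = FALSE)
  } else {
    utils::write.csv(study$thresholds, file.path(dir, "thresholds.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
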