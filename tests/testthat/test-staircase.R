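test_that("task configurations carry the study's step factors and start levels", {
  amd <- staircase_config("AMD")
  expect_equal(amd$start_level, 1.0)
  expect_equal(amd$phase1_step, 1.58)
  expect_equal(amd$phase2_step, 1.26)
  expect_equal(amd$level_cap, 1.0)
  # the printed dB equivalents of the AMD factors
  expect_equal(round(20 * log10(amd$phase1_step)), 4)
  expect_equal(round(20 * log10(amd$phase2_step)), 2)

  amrd <- staircase_config("AMRD")
  expect_equal(amrd$start_level, 4)      # 50% of the 8-Hz standard
  expect_equal(amrd$phase1_step, 1.4)
  expect_equal(amrd$phase2_step, sqrt(1.4))

  fd <- staircase_config("FD")
  expect_equal(fd$start_level, 400)      # 50% of 800 Hz
  expect_equal(fd$phase1_step, 2)
  expect_equal(fd$phase2_step, sqrt(2))

  expect_error(staircase_config("AMD", phase1_step = 0.9), "exceed 1")
  expect_error(staircase_config("AMD", level_floor = 2), "level_floor")
})

test_that("the level rule switches phase at the first error and clamps at the cap", {
  cfg <- staircase_config("AMD")
  # phase 1, correct: divide by 1.58
  expect_equal(next_level(make_fake_track(cfg, 1, TRUE)), 1 / 1.58)
  # first trial incorrect at the cap: stays at 1.0, now in phase 2
  expect_equal(next_level(make_fake_track(cfg, 1, FALSE)), 1.0)
  # ... where a single correct holds (needs 3)
  expect_equal(next_level(make_fake_track(cfg, c(1, 1), c(FALSE, TRUE))), 1.0)
  # ... and three consecutive corrects divide by 1.26
  expect_equal(next_level(make_fake_track(cfg, rep(1, 4),
                                          c(FALSE, TRUE, TRUE, TRUE))),
               1 / 1.26)
  # two corrects then an error multiply by 1.26 (and reset the counter)
  cfg2 <- staircase_config("AMD", start_level = 0.5)
  expect_equal(next_level(make_fake_track(cfg2, rep(0.5, 4),
                                          c(FALSE, TRUE, TRUE, FALSE))),
               0.5 * 1.58 * 1.26)
  # the counter reset means three further corrects are needed
  expect_equal(next_level(make_fake_track(
    cfg2, rep(0.5, 7), c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))),
    0.5 * 1.58 * 1.26 / 1.26)
})

test_that("simulated trials follow the observer and are seed-reproducible", {
  # effectively perfect observer
  good <- observer_model(alpha = -6, beta = 10, lambda = 0)
  set.seed(1)
  res <- replicate(50, run_trial(1, good)$correct)
  expect_true(all(res))

  # a guessing observer is correct about 1/3 of the time
  guess <- observer_model(alpha = 6, beta = 10, lambda = 0)
  set.seed(2)
  pc <- mean(replicate(3000, run_trial(1e-3, guess)$correct))
  expect_equal(pc, 1/3, tolerance = 0.05)

  # target intervals are uniform over 1..3
  set.seed(3)
  targ <- replicate(3000, run_trial(1, good)$target)
  expect_gt(stats::chisq.test(table(targ))$p.value, 0.01)

  cfg <- staircase_config("AMD")
  obs <- observer_model(-1.1, 8)
  t1 <- run_track(cfg, obs, seed = 99, n_trials = 40)
  t2 <- run_track(cfg, obs, seed = 99, n_trials = 40)
  expect_identical(t1$trials, t2$trials)
})

test_that("tracks stay in bounds and respond to observer quality", {
  cfg <- staircase_config("AMD")
  perfect <- observer_model(alpha = -8, beta = 10, lambda = 0)
  tr <- run_track(cfg, perfect, seed = 5, n_trials = 30)
  lv <- tr$trials$level
  expect_true(all(diff(lv) <= 0))           # monotone descending
  expect_equal(count_reversals(tr), 0L)
  expect_true(all(lv >= cfg$level_floor & lv <= cfg$level_cap))

  # a guessing observer drifts up and pins near the cap
  guess <- observer_model(alpha = 6, beta = 10)
  trg <- run_track(cfg, guess, seed = 6, n_trials = 60)
  expect_gt(mean(utils::tail(trg$trials$level, 20)), 0.5 * cfg$level_cap)
  expect_true(all(trg$trials$level <= cfg$level_cap))

  # realistic observers typically produce >= 4 reversals in 60 trials
  obs <- observer_model(-1.1, 8)
  revs <- vapply(1:20, function(s) {
    count_reversals(run_track(cfg, obs, seed = s, n_trials = 60))
  }, integer(1))
  expect_gte(stats::median(revs), 4)

  # and around the printed ~5 per 30-trial block on average
  revs30 <- vapply(21:80, function(s) {
    count_reversals(run_track(cfg, obs, seed = s, n_trials = 30))
  }, integer(1))
  expect_gt(mean(revs30), 3)
  expect_lt(mean(revs30), 9)
})

test_that("phase switches exactly once, at the first error, irreversibly", {
  cfg <- staircase_config("AMD")
  obs <- observer_model(-1.1, 8)
  for (s in 1:10) {
    tr <- run_track(cfg, obs, seed = s, n_trials = 50)$trials
    first_err <- which(!tr$correct)[1]
    if (is.na(first_err)) {
      expect_true(all(tr$phase == 1L))
    } else {
      expect_true(all(tr$phase[seq_len(first_err)] == 1L))
      expect_true(all(tr$phase[-seq_len(first_err)] == 2L))
    }
  }
})

test_that("reversal counting matches hand-enumerated move sequences", {
  cfg <- staircase_config("AMD")
  # monotone: no reversals
  mono <- make_fake_track(cfg, rep(1, 5), rep(TRUE, 5),
                          directions = rep("down", 5))
  expect_equal(count_reversals(mono), 0L)
  # strict zig-zag of 6 moves: 5 reversals
  zig <- make_fake_track(cfg, rep(1, 6), rep(TRUE, 6),
                         directions = rep(c("down", "up"), 3))
  expect_equal(count_reversals(zig), 5L)
  # holds between moves do not create or mask reversals
  mixed <- make_fake_track(
    cfg, rep(1, 7), rep(TRUE, 7),
    directions = c("down", "hold", "down", "hold", "up", "hold", "down"))
  expect_equal(count_reversals(mixed), 2L)
})

test_that("practice trials are flagged, fixed-level, and outside the adaptive rule", {
  cfg <- staircase_config("AMD")
  obs <- observer_model(-1.1, 8)
  tr <- run_track(cfg, obs, seed = 7, n_trials = 30, include_practice = TRUE)
  pr <- tr$trials[tr$trials$practice, ]
  expect_equal(nrow(pr), 5L)
  expect_equal(pr$level, c(1, 1, 1, 0, 0))  # three easy, two impossible
  adaptive <- tr$trials[!tr$trials$practice, ]
  expect_equal(nrow(adaptive), 30L)
  expect_equal(adaptive$level[1], cfg$start_level)  # practice did not move it
  # reversal count ignores practice rows
  expect_equal(count_reversals(tr),
               sum(tr$trials$reversal[!tr$trials$practice]))
})

test_that("schedules reproduce the study's block structure", {
  train <- build_schedule("training_AMD")
  expect_equal(nrow(train), 21L)
  expect_equal(sum(train$trials_per_block), 1260L)
  expect_equal(unique(train$trials_per_block), 60L)
  expect_equal(sum(train$day == 2), 9L)
  expect_equal(sum(train$day == 3), 12L)
  # every aligned 3-block cycle presents each standard rate once
  for (k in seq(1, 19, by = 3)) {
    expect_setequal(train$fm_standard[k:(k + 2)], c(4, 8, 16))
  }
  expect_equal(unique(build_schedule("training_AMRD")$task), "AMRD")

  pre <- build_schedule("pretest")
  amd <- pre[pre$task == "AMD", ]
  expect_equal(nrow(amd), 2L)
  expect_equal(unique(amd$trials_per_block), 30L)
  expect_equal(sum(pre$trials_per_block[pre$task == "VCV"]), 60L)

  expect_equal(sum(build_schedule("pretraining")$trials_per_block), 120L)
  expect_error(build_schedule("weekend"))
})

test_that("staircase visit frequencies match the Markov-chain stationary distribution", {
  step <- 1.26
  K <- 31L
  cfg <- staircase_config("AMD", start_level = step^-15,
                          level_floor = step^-(K - 1), phase2_step = step)
  obs <- observer_model(alpha = -1.5, beta = 4, lambda = 0.02)
  grid <- step^-(0:(K - 1))
  p_vec <- p_correct(obs, grid)

  pi_lev <- stationary_updown_oracle(p_vec, ndown = 3L)

  n_tracks <- 1000L
  set.seed(2024)
  seeds <- sample.int(.Machine$integer.max, n_tracks)
  finals <- vapply(seeds, function(s) {
    tr <- run_track(cfg, obs, seed = s, n_trials = 100, start_phase = 2)
    tr$trials$level[100]
  }, numeric(1))
  idx <- round(-log(finals) / log(step)) + 1L
  counts <- tabulate(idx, nbins = K)

  # lump low-expectation bins into their heavier neighbours
  expected <- pi_lev * n_tracks
  keep <- expected >= 5
  obs_c <- c(counts[keep], sum(counts[!keep]))
  exp_p <- c(pi_lev[keep], sum(pi_lev[!keep]))
  chi2 <- sum((obs_c - n_tracks * exp_p)^2 / (n_tracks * exp_p))
  p_val <- stats::pchisq(chi2, df = length(obs_c) - 1L, lower.tail = FALSE)
  expect_gt(p_val, 0.01)

  # the converged-performance estimate approaches the stationary mean
  cp <- converged_performance(cfg, obs, n_tracks = 400, n_trials = 100,
                              seed = 77)
  stationary_p <- sum(pi_lev * p_vec)
  expect_equal(cp$p_asymptote, stationary_p, tolerance = 0.01)
})

test_that("one-down/one-up tracks converge near 50% correct", {
  cfg <- staircase_config("AMD", start_level = 0.1, phase2_down = 1)
  obs <- observer_model(alpha = -1.5, beta = 3, lambda = 0)
  cp <- converged_performance(cfg, obs, n_tracks = 200, n_trials = 100,
                              seed = 5)
  expect_equal(cp$p_asymptote, 0.50, tolerance = 0.03)
})
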