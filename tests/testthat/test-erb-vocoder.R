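test_that("ERB_N-number scale evaluates and inverts correctly", {
  expect_identical(erb_number(0), 0)
  expect_equal(erb_number(100), 21.4 * log10(0.00437 * 100 + 1))
  expect_equal(erb_number(100), 3.37, tolerance = 0.01)
  expect_equal(erb_number(7800), 33.07, tolerance = 0.01)
  expect_error(erb_number(-1), "non-negative")
  expect_error(inverse_erb_number(-0.5), "non-negative")

  f <- c(0.5, 10, 100, 1000, 7800, 15000)
  expect_equal(inverse_erb_number(erb_number(f)), f, tolerance = 1e-6)
  expect_identical(inverse_erb_number(0), 0)
  expect_equal(inverse_erb_number(8.319), 331, tolerance = 0.5)
  # strictly increasing
  expect_true(all(diff(erb_number(seq(0, 10000, by = 50))) > 0))
})

test_that("default filterbank reproduces the printed corner frequencies", {
  fb <- design_filterbank(vocoder_config())
  expect_equal(nrow(fb), 6L)
  # contiguity is exact
  expect_identical(fb$hi[-6], fb$lo[-1])
  # equal ERB_N width to 1e-9 relative
  w <- erb_number(fb$hi) - erb_number(fb$lo)
  expect_equal(max(w) / min(w), 1, tolerance = 1e-9)
  # interior corners: at least 4 of the 5 printed values within 1 Hz
  printed <- c(331, 725, 1396, 2538, 4485)
  hits <- abs(round(fb$lo[-1]) - printed) <= 1
  expect_gte(sum(hits), 4L)
  # centers are geometric means; band 3 lands near 1006 Hz
  expect_equal(fb$center, sqrt(fb$lo * fb$hi))
  expect_equal(fb$center[3], 1006, tolerance = 1)
})

test_that("filterbank handles degenerate configs and rejects bad ones", {
  fb1 <- design_filterbank(vocoder_config(n_channels = 1))
  expect_equal(c(fb1$lo, fb1$hi), c(100, 7800))
  expect_error(vocoder_config(f_min = 5000, f_max = 100), "f_min")
})

test_that("configs round-trip through YAML and JSON files", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_channels: 4", "f_min: 200", "f_max: 5000"), y)
  cfg <- vocoder_config_from_file(y)
  expect_equal(cfg$n_channels, 4L)
  expect_equal(cfg$f_min, 200)
  expect_equal(cfg$env_cutoff, 45)  # default preserved

  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_channels": 6, "env_cutoff": 30}', j)
  expect_equal(vocoder_config_from_file(j)$env_cutoff, 30)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("channels: 4", bad)
  expect_error(vocoder_config_from_file(bad), "unknown config")
})

test_that("bandpass magnitude response matches the band spec", {
  fb <- design_filterbank(vocoder_config())
  band <- fb[3, ]  # 725-1396 Hz
  rate <- 22050
  tone_at <- function(f) make_tone(f, duration = 1000, ramp = 0, level = 0,
                                   rate = rate)
  trim <- function(w) w$samples[2000:20000]
  # center tone passes with <= 1 dB loss (single pass)
  y <- bandpass(tone_at(band$center), band, zero_phase = FALSE)
  gain_db <- 20 * log10(rms(trim(y)) / rms(trim(tone_at(band$center))))
  expect_gt(gain_db, -1)
  # tone two octaves below lo: single-pass attenuation >= 40 dB
  y2 <- bandpass(tone_at(band$lo / 4), band, zero_phase = FALSE)
  att_db <- -20 * log10(rms(trim(y2)) / rms(trim(tone_at(band$lo / 4))))
  expect_gte(att_db, 40)
  # zero in, zero out
  z <- bandpass(waveform(rep(0, 1000)), band)
  expect_equal(z$samples, rep(0, 1000))
  # corner above Nyquist rejected
  expect_error(bandpass(waveform(rnorm(100), rate = 8000), fb[6, ]),
               "Nyquist")
})

test_that("envelope extraction recovers modulation below the cutoff", {
  rate <- 22050
  am <- make_am_tone(carrier = 1000, fm = 8, m = 1, duration = 1000,
                     ramp = 0, level = 0, start_phase = 0,
                     compensate = FALSE, rate = rate)
  env <- extract_envelope(am, cutoff = 45, rolloff = 24)
  # measure depth as 8-Hz component over DC, edges trimmed
  mid <- 3000:19000
  t <- (mid - 1) / rate
  depth_of <- function(e) {
    fit <- stats::lm(e ~ sin(2 * pi * 8 * t) + cos(2 * pi * 8 * t))
    unname(sqrt(sum(stats::coef(fit)[2:3]^2)) / stats::coef(fit)[1])
  }
  expect_equal(depth_of(env$samples[mid]), 1, tolerance = 0.05)
  expect_true(all(env$samples >= 0))

  # unmodulated tone: flat envelope (CV < 2% after edge trim)
  tone <- make_tone(1000, duration = 1000, ramp = 0, level = 0, rate = rate)
  env0 <- extract_envelope(tone)
  ss <- env0$samples[mid]
  expect_lt(stats::sd(ss) / mean(ss), 0.02)
})

test_that("modulation above the envelope cutoff is attenuated per the filter response", {
  rate <- 22050
  am60 <- make_am_tone(carrier = 1000, fm = 60, m = 0.8, duration = 2000,
                       ramp = 0, level = 0, start_phase = 0,
                       compensate = FALSE, rate = rate)
  env <- extract_envelope(am60, cutoff = 45, rolloff = 24,
                          method = "analytic")
  mid <- 5000:39000
  t <- (mid - 1) / rate
  fit <- stats::lm(env$samples[mid] ~ sin(2 * pi * 60 * t) +
                     cos(2 * pi * 60 * t))
  depth <- unname(sqrt(sum(stats::coef(fit)[2:3]^2)) / stats::coef(fit)[1])
  # 4th-order Butterworth at 60/45 of cutoff, applied twice (filtfilt)
  expected <- 0.8 * (1 + (60 / 45)^8)^-1
  expect_equal(depth, expected, tolerance = 0.2)
  expect_lt(depth, 0.8 * 0.35)  # strongly attenuated relative to input
})

test_that("vocoding concentrates energy at channel carriers and preserves RMS", {
  cfg <- vocoder_config()
  fb <- design_filterbank(cfg)
  rate <- 22050

  # silence in, silence out
  expect_equal(vocode(waveform(rep(0, 2000), rate), cfg)$samples,
               rep(0, 2000))

  # pure tone in band 3: output dominated by carrier 3
  x <- make_tone(fb$center[3], duration = 1000, ramp = 10, level = 0,
                 rate = rate)
  y <- vocode(x, cfg)
  spec <- Mod(stats::fft(y$samples))[1:11025]
  near <- function(f, half = 60) {
    max(spec[max(1, round(f - half)):round(f + half)])
  }
  peaks <- vapply(fb$center, near, numeric(1))
  expect_equal(which.max(peaks), 3L)
  others <- max(peaks[-3])
  expect_gte(20 * log10(peaks[3] / others), 20)

  # overall RMS matched within 5%
  expect_equal(rms(y) / rms(x), 1, tolerance = 0.05)

  # two tones in different bands: both carriers present
  x2 <- waveform(make_tone(fb$center[2], 1000, 10, 0, rate = rate)$samples +
                   make_tone(fb$center[5], 1000, 10, 0, rate = rate)$samples,
                 rate)
  y2 <- vocode(x2, cfg)
  spec2 <- Mod(stats::fft(y2$samples))[1:11025]
  p2 <- vapply(fb$center, function(f) {
    max(spec2[max(1, round(f - 60)):round(f + 60)])
  }, numeric(1))
  expect_gt(p2[2], 10 * max(p2[c(1, 3, 4, 6)]))
  expect_gt(p2[5], 10 * max(p2[c(1, 3, 4, 6)]))
})

test_that("vocoding is near-idempotent in the envelope domain", {
  cfg <- vocoder_config()
  fb <- design_filterbank(cfg)
  rate <- 22050
  # speech-like input: AM tones in two separated bands
  x <- waveform(
    make_am_tone(fb$center[2], fm = 4, m = 0.8, duration = 1000, ramp = 10,
                 level = 0, start_phase = 0, rate = rate)$samples +
      make_am_tone(fb$center[5], fm = 10, m = 0.6, duration = 1000,
                   ramp = 10, level = -5, start_phase = 1, rate = rate)$samples,
    rate)
  y1 <- vocode(x, cfg)
  y2 <- vocode(y1, cfg)
  mid <- 2000:20000
  for (k in c(2, 5)) {
    e1 <- extract_envelope(bandpass(y1, fb[k, ]))$samples[mid]
    e2 <- extract_envelope(bandpass(y2, fb[k, ]))$samples[mid]
    expect_lt(sqrt(mean((e2 - e1)^2)) / sqrt(mean(e1^2)), 0.10)
  }
})

test_that("WAV round-trips preserve samples, rate, and mono constraint", {
  d <- withr::local_tempdir()
  x <- make_tone(440, duration = 50, rate = 22050, level = -6)
  p <- file.path(d, "tone.wav")

  write_wav(p, x, bit_depth = 16)
  y <- read_wav(p)
  expect_equal(y$rate, 22050)
  expect_lte(max(abs(y$samples - x$samples)), 2^-15)

  # float round-trip is exact to single precision
  write_wav(p, x, bit_depth = 32)
  y32 <- read_wav(p)
  expect_lte(max(abs(y32$samples - x$samples)), 1e-7)

  # other rates preserved
  x44 <- make_tone(440, duration = 50, rate = 44100)
  write_wav(p, x44)
  expect_equal(read_wav(p)$rate, 44100)

  # a stereo file errors without the down-mix flag
  stereo <- file.path(d, "stereo.wav")
  n <- 100
  con <- file(stereo, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * 4), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  for (v in c(1, 2)) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeBin(as.integer(22050), con, size = 4, endian = "little")
  writeBin(as.integer(22050 * 4), con, size = 4, endian = "little")
  for (v in c(4, 16)) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * 4), con, size = 4, endian = "little")
  writeBin(as.integer(round(2000 * sin(1:(2 * n)))), con, size = 2,
           endian = "little")
  close(con)
  expect_error(read_wav(stereo), "multi-channel")
  expect_s3_class(read_wav(stereo, down_mix = TRUE), "waveform")
})
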