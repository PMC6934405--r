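## Tone vocoder: band filtering, envelope extraction, sine-carrier resynthesis.
## Filters are Butterworth; a roll-off of r dB/octave maps to order r/6 per
## skirt. By default filters run forward-backward (filtfilt) so channel
## envelopes stay time-aligned; zero-phase filtering doubles the effective
## magnitude slope, so single-pass behaviour is available via zero_phase = FALSE.

butter_order <- function(rolloff) {
  ord <- rolloff / 6
  if (abs(ord - round(ord)) > 1e-8) {
    stop("rolloff must be a multiple of 6 dB/octave (Butterworth order)")
  }
  as.integer(round(ord))
}

apply_filter <- function(flt, s, zero_phase) {
  if (zero_phase) signal::filtfilt(flt, s) else
    as.numeric(signal::filter(flt, s))
}

#' Bandpass-filter a waveform
#'
#' Butterworth bandpass with 3-dB corners at the band's `lo` and `hi` and an
#' asymptotic single-pass slope of `rolloff` dB/octave per skirt.
#'
#' @param x A [waveform].
#' @param band One row of an [design_filterbank] table (or any list with
#'   `lo`, `hi`, `rolloff`).
#' @param zero_phase Apply the filter forward-backward (zero phase lag,
#'   doubled magnitude slope). Default `TRUE`.
#' @return Filtered [waveform], same length and rate.
#' @export
bandpass <- function(x, band, zero_phase = TRUE) {
  stopifnot(inherits(x, "waveform"))
  nyq <- x$rate / 2
  if (band$hi >= nyq) stop("band upper corner at or above Nyquist")
  if (band$lo <= 0 || band$lo >= band$hi) stop("need 0 < lo < hi")
  flt <- signal::butter(butter_order(band$rolloff),
                        c(band$lo, band$hi) / nyq, type = "pass")
  waveform(apply_filter(flt, x$samples, zero_phase), x$rate)
}

#' Extract the temporal envelope of a waveform
#'
#' Half-wave rectification (or analytic-signal magnitude) followed by a
#' Butterworth lowpass at `cutoff` Hz with the stated roll-off, removing
#' pitch-synchronous fluctuations above the cutoff. Residual negative values
#' after filtering are clamped to zero.
#'
#' @param x A [waveform] (typically one analysis band).
#' @param cutoff Envelope lowpass cutoff in Hz (default 45).
#' @param rolloff Lowpass slope in dB/octave (default 24).
#' @param method `"rectify"` or `"analytic"`.
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return Non-negative envelope as a [waveform].
#' @export
extract_envelope <- function(x, cutoff = 45, rolloff = 24,
                             method = c("rectify", "analytic"),
                             zero_phase = TRUE) {
  stopifnot(inherits(x, "waveform"))
  nyq <- x$rate / 2
  if (cutoff >= nyq) stop("cutoff must be below Nyquist")
  method <- match.arg(method)
  demod <- switch(method,
    rectify = pmax(x$samples, 0),
    analytic = Mod(analytic_signal(x$samples))
  )
  flt <- signal::butter(butter_order(rolloff), cutoff / nyq, type = "low")
  env <- apply_filter(flt, demod, zero_phase)
  waveform(pmax(env, 0), x$rate)
}

## FFT analytic signal (one-sided spectrum doubling)
analytic_signal <- function(s) {
  n <- length(s)
  S <- stats::fft(s)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(S * h, inverse = TRUE) / n
}

#' Tone-vocode a waveform
#'
#' Splits the input into contiguous analysis bands equally spaced in
#' ERB_N-number, extracts each band's temporal envelope, re-imposes the
#' envelopes on sine carriers at the bands' logarithmic center frequencies,
#' and recombines. Temporal fine structure within each band is discarded;
#' only envelope cues survive, emulating the information delivered by a
#' cochlear-implant processor.
#'
#' @param x A [waveform].
#' @param config A [vocoder_config].
#' @return Vocoded [waveform], same length and rate as the input.
#' @examples
#' x <- make_am_tone(fm = 8, m = 1, duration = 200, rate = 22050, seed = 1)
#' y <- vocode(x, vocoder_config())
#' @export
vocode <- function(x, config = vocoder_config()) {
  stopifnot(inherits(x, "waveform"), inherits(config, "vocoder_config"))
  if (config$f_max >= x$rate / 2) {
    stop("sampling rate too low for f_max")
  }
  fb <- design_filterbank(config)
  n <- length(x$samples)
  t <- (seq_len(n) - 1) / x$rate
  out <- numeric(n)
  for (k in seq_len(nrow(fb))) {
    band <- fb[k, ]
    sub <- bandpass(x, band)
    env <- extract_envelope(sub, cutoff = config$env_cutoff,
                            rolloff = config$env_rolloff,
                            method = config$envelope_method)
    chan <- env$samples * sin(2 * pi * band$center * t)
    if (config$level_match == "per_channel") {
      r_in <- rms(sub); r_ch <- rms(chan)
      if (r_ch > 0) chan <- chan * r_in / r_ch
    }
    out <- out + chan
  }
  if (config$level_match == "total") {
    r_in <- rms(x); r_out <- rms(out)
    if (r_out > 0) out <- out * r_in / r_out
  }
  waveform(out, x$rate)
}
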