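## Psychophysical stimuli: ramped pure tones, sinusoidally amplitude-modulated
## tones with modulation-power compensation, and frequency-discrimination tone
## pairs. Durations and ramps are in milliseconds. Digital level is expressed
## in dB re full scale (dBFS peak of the unmodulated carrier); the nominal
## 70 dB SPL presentation level of the tasks is a playback calibration
## constant with no digital counterpart.

raised_cosine_gate <- function(n, ramp_samples) {
  g <- rep(1, n)
  if (ramp_samples > 0) {
    if (2 * ramp_samples > n) stop("ramps longer than the stimulus")
    r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = ramp_samples)))
    g[seq_len(ramp_samples)] <- r
    g[n + 1 - seq_len(ramp_samples)] <- rev(r)
  }
  g
}

#' Synthesize a ramped pure tone
#'
#' @param freq Tone frequency in Hz (below Nyquist).
#' @param duration Total duration in ms, including ramps (default 100).
#' @param ramp Raised-cosine on/off ramp duration in ms (default 10; 0 gives
#'   rectangular gating).
#' @param level Peak level in dBFS (default -20).
#' @param phase Starting phase of the tone in radians (default 0).
#' @param rate Sampling rate in Hz (default 22050).
#' @return A [waveform] of `round(duration/1000 * rate)` samples.
#' @examples
#' w <- make_tone(800, duration = 100, rate = 22050)
#' length(w$samples)  # 2205
#' @export
make_tone <- function(freq, duration = 100, ramp = 10, level = -20,
                      phase = 0, rate = 22050) {
  if (freq >= rate / 2) stop("frequency at or above Nyquist")
  if (2 * ramp > duration) stop("2*ramp must not exceed duration")
  n <- round(duration / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  amp <- 10^(level / 20)
  s <- amp * sin(2 * pi * freq * t + phase)
  s <- s * raised_cosine_gate(n, round(ramp / 1000 * rate))
  waveform(s, rate)
}

#' Modulation-power compensation factor
#'
#' Sinusoidal amplitude modulation at depth `m` raises signal power by a
#' factor `1 + m^2/2`; dividing the modulated tone's amplitude by
#' `sqrt(1 + m^2/2)` restores the unmodulated power so that listeners cannot
#' use overall intensity as a cue.
#'
#' @param m Modulation depth in `[0, 1]`.
#' @return `sqrt(1 + m^2 / 2)`.
#' @examples
#' compensation_factor(1)  # sqrt(1.5) ~ 1.2247
#' @export
compensation_factor <- function(m) {
  if (any(m < 0 | m > 1)) stop("modulation depth must be in [0, 1]")
  sqrt(1 + m^2 / 2)
}

#' Synthesize a sinusoidally amplitude-modulated tone
#'
#' Multiplies a pure-tone carrier by a DC-shifted sinusoid
#' `1 + m * sin(2*pi*fm*t + phi)`. With `compensate = TRUE` (default) the
#' result is divided by [compensation_factor] so that the steady-state RMS
#' equals that of the unmodulated carrier. The modulator starting phase is
#' drawn uniformly from `[0, 2*pi)` when not supplied, as in
#' interval-by-interval phase randomization.
#'
#' @param carrier Carrier frequency in Hz (default 1000).
#' @param fm Modulation rate in Hz (must be below `carrier`).
#' @param m Modulation depth in `[0, 1]`.
#' @param duration Duration in ms including ramps (default 500).
#' @param ramp Raised-cosine ramp in ms (default 10).
#' @param level Carrier peak level in dBFS (default -20).
#' @param start_phase Modulator starting phase in radians; `NULL` (default)
#'   draws one at random from the current RNG state.
#' @param compensate Apply modulation-power compensation (default `TRUE`).
#' @param rate Sampling rate in Hz (default 22050).
#' @param seed Optional integer seed for the phase draw.
#' @return A [waveform].
#' @export
make_am_tone <- function(carrier = 1000, fm = 8, m = 1, duration = 500,
                         ramp = 10, level = -20, start_phase = NULL,
                         compensate = TRUE, rate = 22050, seed = NULL) {
  if (fm >= carrier) stop("modulation rate must be below the carrier")
  if (carrier >= rate / 2) stop("carrier at or above Nyquist")
  if (any(m < 0 | m > 1)) stop("modulation depth must be in [0, 1]")
  if (2 * ramp > duration) stop("2*ramp must not exceed duration")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_phase)) start_phase <- stats::runif(1, 0, 2 * pi)
  n <- round(duration / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  amp <- 10^(level / 20)
  s <- amp * (1 + m * sin(2 * pi * fm * t + start_phase)) *
    sin(2 * pi * carrier * t)
  if (compensate) s <- s / compensation_factor(m)
  s <- s * raised_cosine_gate(n, round(ramp / 1000 * rate))
  waveform(s, rate)
}

#' Frequency-discrimination tone pair
#'
#' Returns the standard and target frequencies for a frequency-discrimination
#' trial: the target is `base * (1 + delta_pct/100)`. `delta_pct = 0` yields
#' an "impossible" trial with identical tones.
#'
#' @param base Standard frequency in Hz (default 800).
#' @param delta_pct Frequency increment as a percentage of `base` (>= 0).
#' @return A list with elements `standard` and `target` (Hz).
#' @examples
#' fd_pair(delta_pct = 50)  # 800 and 1200 Hz
#' @export
fd_pair <- function(base = 800, delta_pct) {
  if (delta_pct < 0) stop("delta_pct must be non-negative")
  list(standard = base, target = base * (1 + delta_pct / 100))
}
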