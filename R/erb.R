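#' ERB_N-number of a frequency
#'
#' Converts frequency in Hz to the ERB_N-number scale (Glasberg & Moore):
#' `E(f) = 21.4 * log10(0.00437 * f + 1)`. Equal steps on this scale
#' approximate equal distances along the normal cochlear partition, which is
#' why vocoder analysis bands are spaced on it.
#'
#' @param f Frequency in Hz (vectorised, `f >= 0`).
#' @return ERB_N-number (dimensionless), same length as `f`.
#' @examples
#' erb_number(c(100, 1000, 7800))
#' @export
erb_number <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  21.4 * log10(0.00437 * f + 1)
}

#' Frequency corresponding to an ERB_N-number
#'
#' Closed-form inverse of [erb_number].
#'
#' @param e ERB_N-number (vectorised, `e >= 0`).
#' @return Frequency in Hz.
#' @export
inverse_erb_number <- function(e) {
  if (any(e < 0)) stop("ERB_N-number must be non-negative")
  (10^(e / 21.4) - 1) / 0.00437
}

#' Vocoder configuration
#'
#' Parameters of the tone vocoder: number of analysis channels, overall
#' analysis range, envelope smoothing, and filter slopes. The defaults give
#' the 6-band, 100-7800 Hz, 45-Hz-envelope configuration used throughout the
#' package.
#'
#' @param n_channels Number of contiguous analysis bands (default 6).
#' @param f_min,f_max Overall analysis range in Hz (default 100-7800).
#' @param env_cutoff Envelope lowpass cutoff in Hz (default 45).
#' @param env_rolloff Envelope filter slope in dB/octave (default 24).
#' @param band_rolloff Analysis-filter skirt slope in dB/octave per side
#'   (default 24).
#' @param carrier Carrier type; only `"tone"` (sine carriers) is supported.
#' @param envelope_method `"rectify"` (half-wave rectification followed by
#'   the envelope lowpass, classic vocoder practice; default) or `"analytic"`
#'   (magnitude of the analytic signal, then the same lowpass).
#' @param level_match `"total"` (scale the recombined output so its RMS equals
#'   the input RMS; default) or `"per_channel"` (match each channel's RMS to
#'   its analysis band before summing).
#' @return A list of class `"vocoder_config"`.
#' @export
vocoder_config <- function(n_channels = 6, f_min = 100, f_max = 7800,
                           env_cutoff = 45, env_rolloff = 24,
                           band_rolloff = 24, carrier = "tone",
                           envelope_method = c("rectify", "analytic"),
                           level_match = c("total", "per_channel")) {
  if (f_min >= f_max) stop("f_min must be below f_max")
  if (n_channels < 1) stop("need at least one channel")
  if (env_cutoff <= 0 || env_rolloff <= 0 || band_rolloff <= 0) {
    stop("cutoff and roll-offs must be positive")
  }
  carrier <- match.arg(carrier, "tone")
  structure(list(
    n_channels = as.integer(n_channels), f_min = f_min, f_max = f_max,
    env_cutoff = env_cutoff, env_rolloff = env_rolloff,
    band_rolloff = band_rolloff, carrier = carrier,
    envelope_method = match.arg(envelope_method),
    level_match = match.arg(level_match)
  ), class = "vocoder_config")
}

#' Read a vocoder configuration from a YAML or JSON file
#'
#' The file holds a flat mapping mirroring the arguments of
#' [vocoder_config] (`n_channels`, `f_min`, `f_max`, `env_cutoff`, ...);
#' absent fields take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [vocoder_config].
#' @export
vocoder_config_from_file <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is needed to read JSON configs")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(vocoder_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  do.call(vocoder_config, fields)
}

#' Design an equal-ERB_N filterbank
#'
#' Splits `[f_min, f_max]` into `n_channels` contiguous bands of equal width
#' on the ERB_N-number scale. Adjacent bands share corner frequencies (3-dB
#' points); each carrier sits at the geometric (logarithmic) center of its
#' band.
#'
#' @param config A [vocoder_config].
#' @return A data frame of class `"erb_filterbank"` with one row per band and
#'   columns `band`, `lo`, `hi`, `center` (Hz) and `rolloff` (dB/octave).
#' @examples
#' fb <- design_filterbank(vocoder_config())
#' round(fb$lo)   # interior corners land at 331, 725, 1396, ... Hz
#' @export
design_filterbank <- function(config = vocoder_config()) {
  stopifnot(inherits(config, "vocoder_config"))
  edges_erb <- seq(erb_number(config$f_min), erb_number(config$f_max),
                   length.out = config$n_channels + 1L)
  edges <- inverse_erb_number(edges_erb)
  # pin the outer corners exactly (round-trip is exact to ~1e-12 anyway)
  edges[1] <- config$f_min
  edges[length(edges)] <- config$f_max
  fb <- data.frame(
    band = seq_len(config$n_channels),
    lo = edges[-length(edges)],
    hi = edges[-1],
    center = sqrt(edges[-length(edges)] * edges[-1]),
    rolloff = config$band_rolloff
  )
  class(fb) <- c("erb_filterbank", "data.frame")
  fb
}

#' @export
print.erb_filterbank <- function(x, digits = 1, ...) {
  cat(sprintf("equal-ERB_N filterbank: %d bands, %g-%g Hz\n",
              nrow(x), min(x$lo), max(x$hi)))
  print.data.frame(round(as.data.frame(x)[, c("band", "lo", "center", "hi")],
                         digits), row.names = FALSE)
  invisible(x)
}
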