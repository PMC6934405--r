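## Synthetic VCV-identification responses with controllable per-feature
## transmission. Ground truth for the information-transfer pipeline: each
## phonetic feature of the presented consonant survives intact with its own
## probability, otherwise it is resampled uniformly from the feature's other
## categories; a token with every feature intact is identified outright,
## otherwise the response is drawn uniformly from the consonants matching
## the resulting (voice, manner, place) triple. Feature independence is a
## modeling choice (real confusions correlate features); a correlation hook
## is exposed via `resample`, which receives the sampled categories and may
## modify them jointly.

#' Per-feature transmission probabilities
#'
#' @param t_voice,t_manner,t_place Probability in `[0, 1]` that the voice,
#'   manner and place feature of a presented consonant is transmitted intact
#'   on a trial.
#' @return A list of class `"feature_transmission"`.
#' @export
feature_transmission <- function(t_voice, t_manner, t_place) {
  t <- c(voice = t_voice, manner = t_manner, place = t_place)
  if (any(t < 0 | t > 1)) stop("transmission probabilities must be in [0, 1]")
  structure(as.list(t), class = "feature_transmission")
}

#' Simulate VCV identification trials
#'
#' Each of the 20 consonants is presented `n_per_token` times in each of the
#' three vowel contexts (the generator ignores vowel identity; it is carried
#' through for schema compatibility).
#'
#' @param ft A [feature_transmission].
#' @param fmap A [feature_map].
#' @param n_per_token Presentations per consonant-vowel token (default 1,
#'   i.e. one 60-trial block).
#' @param seed Optional integer seed.
#' @param resample Optional hook: `function(cats, stim_cats)` receiving the
#'   data frame of sampled feature categories, returning a modified one
#'   (for correlated feature noise).
#' @return Data frame: `trial`, `stimulus`, `vowel`, `response`, `correct`.
#' @export
simulate_vcv_trials <- function(ft, fmap = feature_map(), n_per_token = 1,
                                seed = NULL, resample = NULL) {
  stopifnot(inherits(ft, "feature_transmission"))
  validate_feature_map(fmap)
  if (!is.null(seed)) set.seed(seed)

  tokens <- vcv_tokens()
  idx <- rep(seq_len(nrow(tokens)), times = n_per_token)
  idx <- sample(idx)  # randomized presentation order
  stim <- tokens$consonant[idx]
  vowel <- tokens$vowel[idx]
  n <- length(stim)
  si <- match(stim, fmap$consonant)

  cats <- data.frame(voice = fmap$voice[si], manner = fmap$manner[si],
                     place = fmap$place[si], stringsAsFactors = FALSE)
  intact <- rep(TRUE, n)
  for (f in c("voice", "manner", "place")) {
    lev <- unique(fmap[[f]])
    keep <- stats::runif(n) < ft[[f]]
    intact <- intact & keep
    flip <- which(!keep)
    if (length(flip)) {
      cats[[f]][flip] <- vapply(cats[[f]][flip], function(cur) {
        sample(setdiff(lev, cur), 1L)
      }, character(1))
    }
  }
  if (!is.null(resample)) cats <- resample(cats, fmap[si, ])

  # a token whose every feature survives is identified outright; otherwise
  # the listener knows only the (corrupted) category triple and picks
  # uniformly among the consonants consistent with it (several consonants
  # can share a triple), falling back to a full-alphabet guess when no
  # consonant matches
  key <- paste(cats$voice, cats$manner, cats$place)
  fmap_key <- paste(fmap$voice, fmap$manner, fmap$place)
  response <- stim
  for (i in which(!intact)) {
    match_set <- fmap$consonant[fmap_key == key[i]]
    if (length(match_set) == 0L) match_set <- fmap$consonant
    response[i] <- if (length(match_set) == 1L) match_set else
      sample(match_set, 1L)
  }

  data.frame(trial = seq_len(n), stimulus = stim, vowel = vowel,
             response = response, correct = stim == response,
             stringsAsFactors = FALSE)
}
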