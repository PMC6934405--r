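#' Consonant-to-phonetic-feature map
#'
#' Loads the table assigning each of the 20 consonants to its categories on
#' three phonetic features: voice (voiced/voiceless), manner (nasal,
#' fricative, approximant, plosive-initial) and place of articulation
#' (front, middle, back). The packaged default uses the standard articulatory
#' assignment (front = labial/labiodental, middle = dental/alveolar,
#' back = postalveolar/palatal/velar) and contains 12 voiced and 8 voiceless
#' consonants; it ships as an editable TSV so alternative place groupings can
#' be supplied.
#'
#' @param path Path to a TSV with columns `consonant`, `voice`, `manner`,
#'   `place` (and optionally `ipa`). Default: the packaged table.
#' @return A data frame of class `"feature_map"` with one row per consonant.
#' @examples
#' fm <- feature_map()
#' table(fm$voice)  # 12 voiced, 8 voiceless
#' @export
feature_map <- function(path = system.file("extdata", "feature_map.tsv",
                                           package = "vocotrain")) {
  fm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_feature_map(fm)
  class(fm) <- c("feature_map", "data.frame")
  fm
}

validate_feature_map <- function(fm) {
  need <- c("consonant", "voice", "manner", "place")
  if (!all(need %in% names(fm))) {
    stop("feature map must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(fm) != 20L || anyDuplicated(fm$consonant)) {
    stop("feature map must cover exactly 20 distinct consonants")
  }
  if (!all(fm$voice %in% c("voiced", "voiceless"))) {
    stop("voice categories must be voiced/voiceless")
  }
  if (sum(fm$voice == "voiced") != 12L) {
    stop("feature map must contain 12 voiced and 8 voiceless consonants")
  }
  if (!all(fm$manner %in% c("nasal", "fricative", "approximant", "plosive"))) {
    stop("unknown manner category")
  }
  if (!all(fm$place %in% c("front", "middle", "back"))) {
    stop("unknown place category")
  }
  invisible(fm)
}

#' Chance level of identifying a feature category
#'
#' One over the number of categories: 1/2 for voice, 1/4 for manner, 1/3 for
#' place under the default map.
#'
#' @param fmap A [feature_map].
#' @param feature `"voice"`, `"manner"` or `"place"`.
#' @return Probability.
#' @export
feature_chance <- function(fmap, feature = c("voice", "manner", "place")) {
  feature <- match.arg(feature)
  1 / length(unique(fmap[[feature]]))
}
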