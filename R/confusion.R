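## Consonant-identification scoring, confusion matrices, and Miller-Nicely
## information transfer. All logarithms are base 2; relative IT is base-free.

#' Percentage of correct identifications
#'
#' @param trials Data frame with columns `stimulus` and `response` (or a
#'   logical/0-1 column `correct`).
#' @return Percent correct (0-100).
#' @export
percent_correct <- function(trials) {
  if (nrow(trials) == 0L) stop("no trials")
  hits <- if ("correct" %in% names(trials)) as.logical(trials$correct)
          else trials$stimulus == trials$response
  100 * mean(hits)
}

#' Construct a confusion matrix from counts
#'
#' @param counts Square matrix of non-negative integer counts; rows index
#'   presented stimuli, columns responses. Dimnames supply the labels (made
#'   up if absent).
#' @return An object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) colnames(counts) <- rownames(counts)
  structure(list(counts = counts, n_total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: %d x %d, n = %d\n",
              nrow(x$counts), ncol(x$counts), x$n_total))
  print(x$counts)
  invisible(x)
}

#' Build a stimulus-by-response confusion matrix from trials
#'
#' Vowel contexts are collapsed: only consonant identity enters the matrix.
#'
#' @param trials Data frame with columns `stimulus` and `response`.
#' @param alphabet Character vector of allowed labels (default: the 20
#'   consonants of [feature_map]). Trials with labels outside it are an error.
#' @return A [confusion_matrix].
#' @export
build_confusion <- function(trials, alphabet = feature_map()$consonant) {
  s <- as.character(trials$stimulus)
  r <- as.character(trials$response)
  bad <- unique(c(setdiff(s, alphabet), setdiff(r, alphabet)))
  if (length(bad)) stop("labels outside the alphabet: ", paste(bad, collapse = ", "))
  counts <- table(factor(s, levels = alphabet), factor(r, levels = alphabet))
  confusion_matrix(unclass(counts))
}

#' Collapse a confusion matrix to phonetic-feature categories
#'
#' Sums counts within the categories of one feature, e.g. a /p/ -> /t/
#' confusion counts as a correct voiceless -> voiceless transmission on the
#' voice feature but front -> middle on place.
#'
#' @param cm A [confusion_matrix] over consonants.
#' @param fmap A [feature_map] covering the matrix labels.
#' @param feature `"voice"`, `"manner"` or `"place"`.
#' @return A [confusion_matrix] over the feature's categories.
#' @export
collapse_to_feature <- function(cm, fmap, feature = c("voice", "manner", "place")) {
  feature <- match.arg(feature)
  labs <- rownames(cm$counts)
  if (!all(labs %in% fmap$consonant)) stop("feature map does not cover matrix labels")
  cat_of <- fmap[[feature]][match(labs, fmap$consonant)]
  cats <- sort(unique(fmap[[feature]]))
  f <- factor(cat_of, levels = cats)
  agg <- rowsum(t(rowsum(cm$counts, f)), f)  # collapse rows then columns
  confusion_matrix(t(agg)[cats, cats, drop = FALSE])
}

#' Input (stimulus) entropy of a confusion matrix
#'
#' `H = -sum p_i log2 p_i` over the stimulus marginals. With unequal category
#' sizes (e.g. 12 voiced vs 8 voiceless consonants presented equally often)
#' this is below `log2(n_categories)`.
#'
#' @param cm A [confusion_matrix].
#' @return Entropy in bits.
#' @export
input_entropy <- function(cm) {
  if (cm$n_total == 0L) stop("empty confusion matrix")
  p <- rowSums(cm$counts) / cm$n_total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Miller-Nicely information transfer
#'
#' The plug-in mutual information of the stimulus-response table:
#' `T = sum_ij (n_ij/n) * log2(n * n_ij / (n_i * n_j))`, with `0 log 0 = 0`.
#' No small-sample bias correction is applied by default; `miller_madow`
#' subtracts the Miller-Madow term `(K_occupied - K_row - K_col + 1)/(2n ln 2)`.
#'
#' @param cm A [confusion_matrix].
#' @param miller_madow Apply the Miller-Madow bias correction (default
#'   `FALSE`).
#' @return Information transfer in bits (floored at 0 when corrected).
#' @export
information_transfer <- function(cm, miller_madow = FALSE) {
  n <- cm$n_total
  if (n == 0L) stop("empty confusion matrix")
  nij <- cm$counts
  ni <- rowSums(nij)
  nj <- colSums(nij)
  pos <- nij > 0
  denom <- outer(ni, nj)
  t_bits <- sum((nij[pos] / n) * log2(n * nij[pos] / denom[pos]))
  if (miller_madow) {
    corr <- (sum(pos) - sum(ni > 0) - sum(nj > 0) + 1) / (2 * n * log(2))
    t_bits <- max(0, t_bits - corr)
  }
  t_bits
}

#' Relative information transfer
#'
#' Information transfer normalized by the input entropy, in percent. This
#' puts features with different numbers of categories and unequal category
#' priors on a common 0-100 scale.
#'
#' @param cm A [confusion_matrix].
#' @param ... Passed to [information_transfer].
#' @return Percentage in `[0, 100]`.
#' @export
relative_it <- function(cm, ...) {
  h <- input_entropy(cm)
  if (h <= 0) stop("input entropy is zero; relative IT undefined")
  # T <= H_in holds exactly; clamp residual floating-point excess
  min(100, max(0, 100 * information_transfer(cm, ...) / h))
}

#' Per-feature information-transfer table for a set of trials
#'
#' Convenience wrapper: builds the consonant confusion matrix, collapses it
#' to each phonetic feature, and reports IT, input entropy and relative IT.
#'
#' @param trials Data frame with `stimulus` and `response` columns.
#' @param fmap A [feature_map].
#' @return Data frame with one row per feature (plus `"consonant"` for the
#'   full matrix): `feature`, `it_bits`, `h_in`, `relative_it`.
#' @export
it_results <- function(trials, fmap = feature_map()) {
  cm <- build_confusion(trials, fmap$consonant)
  rows <- lapply(c("consonant", "voice", "manner", "place"), function(f) {
    m <- if (f == "consonant") cm else collapse_to_feature(cm, fmap, f)
    data.frame(feature = f, it_bits = information_transfer(m),
               h_in = input_entropy(m), relative_it = relative_it(m))
  })
  do.call(rbind, rows)
}
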