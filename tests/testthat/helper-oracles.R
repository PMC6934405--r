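## Independent oracles used to cross-check the package's implementations.
## Everything here is deliberately written from first principles (entropy
## decompositions, explicit Markov transition matrices, exhaustive
## enumeration of generative processes) rather than by calling the package
## functions under test.

## Mutual information of a count matrix via the entropy decomposition
## I = H(rows) + H(cols) - H(joint), in bits.
mi_oracle <- function(counts) {
  n <- sum(counts)
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  H(rowSums(counts) / n) + H(colSums(counts) / n) - H(counts / n)
}

## All k-part compositions (ordered, non-negative) with total <= n,
## excluding the all-zero row.
compositions_upto <- function(k, n) {
  rec <- function(k, n) {
    if (k == 1L) return(matrix(0:n, ncol = 1))
    do.call(rbind, lapply(0:n, function(i) cbind(i, rec(k - 1L, n - i))))
  }
  m <- rec(k, n)
  m[rowSums(m) > 0, , drop = FALSE]
}

## Stationary distribution of a transformed up-down staircase on a discrete
## level grid. Levels are indexed 1..K from easiest (cap) to hardest (floor);
## a "down" move (after `ndown` consecutive correct responses) increments the
## index, an "up" move (any incorrect) decrements it, both clamped. States
## are (level index, consecutive-correct counter); the marginal over levels
## is returned.
stationary_updown_oracle <- function(p_vec, ndown = 3L) {
  K <- length(p_vec)
  nc <- ndown
  id <- function(i, c) (i - 1L) * nc + c + 1L
  N <- K * nc
  P <- matrix(0, N, N)
  for (i in seq_len(K)) {
    for (c in 0:(nc - 1L)) {
      p <- p_vec[i]
      if (c == nc - 1L) {
        P[id(i, c), id(min(i + 1L, K), 0L)] <-
          P[id(i, c), id(min(i + 1L, K), 0L)] + p
      } else {
        P[id(i, c), id(i, c + 1L)] <- P[id(i, c), id(i, c + 1L)] + p
      }
      P[id(i, c), id(max(i - 1L, 1L), 0L)] <-
        P[id(i, c), id(max(i - 1L, 1L), 0L)] + (1 - p)
    }
  }
  v <- rep(1 / N, N)
  for (it in seq_len(5000)) v <- as.numeric(v %*% P)
  lev <- vapply(seq_len(K), function(i) sum(v[id(i, 0:(nc - 1L))]), numeric(1))
  lev / sum(lev)
}

## Exact response distribution of the VCV feature-transmission generator:
## 20 x 20 matrix of P(response | stimulus), by enumerating every corrupted
## category triple. A triple equal to the stimulus's own triple can only
## arise with all features kept (flips always change category), in which
## case the response is the stimulus itself; otherwise the response is
## uniform over the consonants matching the triple (all 20 if none match).
exact_vcv_confusion_oracle <- function(ft, fmap) {
  cons <- fmap$consonant
  K <- length(cons)
  lev <- list(voice = unique(fmap$voice), manner = unique(fmap$manner),
              place = unique(fmap$place))
  fkey <- paste(fmap$voice, fmap$manner, fmap$place)
  P <- matrix(0, K, K, dimnames = list(cons, cons))
  for (s in seq_len(K)) {
    orig <- c(fmap$voice[s], fmap$manner[s], fmap$place[s])
    feats <- c("voice", "manner", "place")
    outcomes <- lapply(seq_along(feats), function(j) {
      f <- feats[j]
      cats <- lev[[f]]
      pr <- ifelse(cats == orig[j], ft[[f]],
                   (1 - ft[[f]]) / (length(cats) - 1))
      data.frame(cat = cats, pr = pr, stringsAsFactors = FALSE)
    })
    for (a in seq_len(nrow(outcomes[[1]]))) {
      for (b in seq_len(nrow(outcomes[[2]]))) {
        for (d in seq_len(nrow(outcomes[[3]]))) {
          w <- outcomes[[1]]$pr[a] * outcomes[[2]]$pr[b] * outcomes[[3]]$pr[d]
          if (w == 0) next
          tri <- c(outcomes[[1]]$cat[a], outcomes[[2]]$cat[b],
                   outcomes[[3]]$cat[d])
          if (all(tri == orig)) {
            P[s, s] <- P[s, s] + w
          } else {
            match_set <- which(fkey == paste(tri, collapse = " "))
            if (length(match_set) == 0L) match_set <- seq_len(K)
            P[s, match_set] <- P[s, match_set] + w / length(match_set)
          }
        }
      }
    }
  }
  P
}

## Exact per-feature relative IT (percent) of the generator, from the exact
## confusion probabilities with a uniform stimulus prior.
exact_relative_it_oracle <- function(ft, fmap, feature) {
  P <- exact_vcv_confusion_oracle(ft, fmap)
  joint <- P / nrow(P)
  f <- factor(fmap[[feature]][match(rownames(P), fmap$consonant)])
  coll <- rowsum(t(rowsum(joint, f)), f)  # feature-level joint (transposed)
  joint_f <- t(coll)
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_in <- H(rowSums(joint_f))
  mi <- H(rowSums(joint_f)) + H(colSums(joint_f)) - H(joint_f)
  100 * mi / h_in
}

## A minimal staircase_track object with prescribed trial outcomes, for
## exercising the replay and fitting code without a simulated observer.
make_fake_track <- function(cfg, levels, corrects,
                            directions = NULL) {
  n <- length(levels)
  tr <- data.frame(trial = seq_len(n), level = levels, phase = NA_integer_,
                   target = 1L, response = ifelse(corrects, 1L, 2L),
                   correct = corrects,
                   direction = directions %||% rep("hold", n),
                   reversal = FALSE, practice = FALSE)
  structure(list(config = cfg, trials = tr, n_reversals = NA_integer_,
                 seed = NA_integer_),
            class = "staircase_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
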