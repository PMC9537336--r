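#' The Mexbet-22 phone inventory
#'
#' The 22 phones of the basic transcription level of the Mexbet alphabet
#' for Mexican Spanish, including the multi-character symbols `tS`, `n~`
#' and `r(`.
#'
#' @return character vector of the 22 phone symbols.
#' @export
mexbet_phones <- function() {
  c("a", "e", "i", "o", "u",
    "p", "t", "k", "b", "d", "g",
    "tS", "f", "s", "x", "Z",
    "m", "n", "n~", "l", "r(", "r")
}

#' Tokenize a phone string
#'
#' Greedy longest-match tokenization over the phone inventory: at each
#' position the longest symbol that matches is consumed, so `tS`, `n~` and
#' `r(` are recognized before their single-character prefixes. Input may
#' be the concatenated dialect (no separators) or space-separated; spaces
#' are skipped.
#'
#' @param s a character scalar.
#' @param inventory the phone inventory (default Mexbet-22).
#' @return character vector of phone tokens.
#' @export
phone_tokenize <- function(s, inventory = mexbet_phones()) {
  stopifnot(is.character(s), length(s) == 1L)
  inv <- inventory[order(nchar(inventory), decreasing = TRUE)]
  out <- character(0)
  i <- 1L
  nc <- nchar(s)
  while (i <= nc) {
    if (substr(s, i, i) == " ") { i <- i + 1L; next }
    hit <- NA_character_
    for (tok in inv) {
      w <- nchar(tok)
      if (i + w - 1L <= nc && substr(s, i, i + w - 1L) == tok) {
        hit <- tok; break
      }
    }
    if (is.na(hit))
      stop_weam("unmatchable character '", substr(s, i, i),
                "' at position ", i)
    out <- c(out, hit)
    i <- i + nchar(hit)
  }
  out
}

#' Token-level Levenshtein distance
#'
#' Unit-cost edit distance (insertion, deletion, substitution) between two
#' token sequences, by the standard two-row dynamic programme.
#'
#' @param a,b character vectors of tokens.
#' @return non-negative integer distance.
#' @export
phone_levenshtein <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    sub <- prev[1:m] + (a[i] != b)
    for (j in seq_len(m))
      cur[j + 1L] <- min(cur[j] + 1L, prev[j + 1L] + 1L, sub[j])
    prev <- cur
  }
  prev[m + 1L]
}

#' Phoneme error rate
#'
#' `FER = (I + D + S) / (I + D + S + L)` where `I + D + S` is the token
#' Levenshtein distance from the hypothesis to the reference and `L` the
#' reference length. This normalization (distance over distance-plus-length,
#' rather than the conventional distance over length) keeps the rate in
#' `[0, 1)`: 0 for identical strings, approaching 1 for very different ones.
#'
#' @param hyp,ref character vectors of phone tokens; `ref` non-empty.
#' @return the error rate in `[0, 1)`.
#' @export
fer <- function(hyp, ref) {
  if (!length(ref)) stop_weam("the reference string must be non-empty")
  d <- phone_levenshtein(hyp, ref)
  d / (d + length(ref))
}

#' Precision, recall and accuracy with all-rejected conventions
#'
#' Standard confusion-matrix metrics with two conventions for degenerate
#' denominators: when a register rejects everything there are no false
#' positives and precision is 1, while all true positives are missed and
#' recall is 0. An all-zero confusion matrix additionally sets `degenerate
#' = TRUE`. At the system level true negatives do not exist (`tn = 0`) and
#' accuracy coincides with recall.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return list with the counts, `precision`, `recall`, `accuracy` and the
#'   `degenerate` flag.
#' @export
register_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop_weam("counts must be non-negative")
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  total <- tp + fp + tn + fn
  accuracy <- if (total == 0) 0 else (tp + tn) / total
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = precision, recall = recall, accuracy = accuracy,
       degenerate = total == 0)
}

#' Fit a phone bigram model
#'
#' Maximum-likelihood unigram and first-order conditional frequencies from
#' a corpus of token sequences. No smoothing is applied beyond an epsilon
#' guard on denominators at evaluation time.
#'
#' @param corpus list of character vectors of phone tokens.
#' @param eps denominator guard used when the model is evaluated.
#' @return object of class `bigram_model` with `phones`, unigram vector
#'   `p_uni` and conditional matrix `p_cond` (`p_cond[a, b] = p(b | a)`).
#' @export
fit_bigram <- function(corpus, eps = 1e-12) {
  corpus <- Filter(length, corpus)
  if (!length(corpus)) stop_weam("the corpus must contain tokens")
  phones <- sort(unique(unlist(corpus)))
  uni <- table(factor(unlist(corpus), levels = phones))
  p_uni <- as.numeric(uni) / sum(uni)
  names(p_uni) <- phones
  big <- matrix(0, length(phones), length(phones),
                dimnames = list(phones, phones))
  for (s in corpus) {
    if (length(s) < 2L) next
    for (k in seq_len(length(s) - 1L))
      big[s[k], s[k + 1L]] <- big[s[k], s[k + 1L]] + 1
  }
  rs <- rowSums(big)
  p_cond <- big / pmax(rs, eps)
  structure(list(phones = phones, p_uni = p_uni, p_cond = p_cond, eps = eps),
            class = "bigram_model")
}

#' Simplify a phone string with bigram context
#'
#' Left-to-right filter over a raw phone sequence (e.g. one symbol per
#' analysis frame). With `a` the most recently accepted phone and `c` the
#' next phone in the raw sequence, a candidate `b` is kept iff
#' `p(b | a, c) > p(b)` where
#' `p(b|a,c) = w p(b|a) + (1 - w) p(c|b) p(b) / p(c)`.
#' Boundary handling: the first token is accepted unconditionally; the last
#' token, having no right context, is scored by `p(b|a)` alone.
#'
#' @param s character vector of phone tokens.
#' @param model a [fit_bigram()] model covering the symbols of `s`.
#' @param w mixing weight of the left-context term (default 0.5).
#' @return the simplified (never longer) token vector.
#' @export
simplify_phones <- function(s, model, w = 0.5) {
  if (!length(s)) return(character(0))
  unknown <- setdiff(unique(s), model$phones)
  if (length(unknown))
    stop_weam("symbols not covered by the model: ",
              paste(unknown, collapse = ", "))
  p <- model$p_uni
  pc <- model$p_cond
  eps <- model$eps
  out <- s[1L]
  a <- s[1L]
  K <- length(s)
  for (k in seq_len(K)[-1L]) {
    b <- s[k]
    score <- if (k < K) {
      cc <- s[k + 1L]
      w * pc[a, b] + (1 - w) * pc[b, cc] * p[b] / max(p[cc], eps)
    } else {
      pc[a, b]
    }
    if (score > p[b]) {
      out <- c(out, b)
      a <- b
    }
  }
  out
}
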