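#' An ensemble of labelled memory registers
#'
#' A memory system holds one weighted AMR per class (default: one per
#' Mexbet-22 phone), a shared quantizer mapping real-valued vectors to
#' cues, and one set of recognition parameters used by all registers.
#' Registration is supervised (the cue goes to its labelled register only);
#' recognition presents the cue to every register simultaneously and
#' resolves multiple responders with a Bayesian-flavoured rule: the
#' register chosen is the one minimizing `entropy * (1 / rho)`, i.e. low
#' indeterminacy (prior) and strong cue support (likelihood) win.
#'
#' @param labels character vector of unique class labels.
#' @param n_args number of arguments `n` shared by all registers.
#' @param n_levels number of levels `m` shared by all registers.
#' @param quantizer optional fitted [quantizer_fit()] object; required
#'   before real-valued vectors can be presented.
#' @param params a [recognition_params()] shared by all registers.
#' @return an object of class `memory_system`.
#' @export
memory_system <- function(labels, n_args, n_levels, quantizer = NULL,
                          params = recognition_params()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop_weam("register labels must be unique")
  if (!length(labels)) stop_weam("at least one register is required")
  regs <- lapply(labels, function(l) weighted_amr(n_args, n_levels, l))
  names(regs) <- labels
  structure(list(registers = regs, quantizer = quantizer, params = params,
                 n_args = as.integer(n_args), n_levels = as.integer(n_levels)),
            class = "memory_system")
}

# Accept either a raw vector (quantized through the system's quantizer) or
# a ready-made feature_function.
ms_cue <- function(sys, v) {
  if (inherits(v, "feature_function")) return(v)
  if (is.null(sys$quantizer))
    stop_weam("the system has no quantizer; present a feature_function ",
              "or fit one with quantizer_fit()")
  quantize(sys$quantizer, v)
}

#' Supervised registration of a unit
#'
#' Quantizes `v` and registers the resulting cue into exactly the register
#' named `label`; all other registers are untouched.
#'
#' @param sys a `memory_system`.
#' @param label class label of the unit.
#' @param v numeric vector (or a `feature_function`).
#' @return the updated system.
#' @export
ms_register <- function(sys, label, v) {
  if (!label %in% names(sys$registers))
    stop_weam("unknown register label '", label, "'")
  sys$registers[[label]] <- amr_register(sys$registers[[label]], ms_cue(sys, v))
  sys
}

#' Recognize a unit against every register
#'
#' The cue is tested against all registers with the shared parameters.
#' Among accepting registers the chosen one minimizes
#' `entropy * (1 / rho)`; a responder with `rho = 0` scores `+Inf`. Ties
#' break to the lexicographically smallest label. An empty responder set
#' yields the decision `"rejected"`.
#'
#' @param sys a `memory_system`.
#' @param v numeric vector or `feature_function`.
#' @return list with `responders` (labels), `chosen` (label or
#'   `"rejected"`), `scores` (named, responders only) and the per-register
#'   `recognitions`.
#' @export
ms_recognize <- function(sys, v) {
  cue <- ms_cue(sys, v)
  recs <- lapply(sys$registers, amr_recognize, cue = cue, params = sys$params)
  acc <- vapply(recs, `[[`, logical(1), "accepted")
  responders <- names(recs)[acc]
  if (!length(responders))
    return(list(responders = character(), chosen = "rejected",
                scores = numeric(), recognitions = recs))
  scores <- vapply(responders, function(l) {
    r <- recs[[l]]
    if (r$rho <= 0) Inf else r$entropy / r$rho
  }, numeric(1))
  ord <- order(scores, responders)
  list(responders = responders, chosen = responders[ord[1L]],
       scores = scores, recognitions = recs)
}

#' Retrieve a unit through the system
#'
#' Runs the recognition decision; if some register is chosen, performs
#' constructive retrieval on it and dequantizes the result back to a real
#' vector. Undefined output arguments (empty columns admitted by `xi`) are
#' completed photographically from the cue before dequantization.
#'
#' @param sys a `memory_system`.
#' @param v numeric vector or `feature_function`.
#' @param seed integer seed for the retrieval sampling.
#' @return list with `accepted`; when accepted also `label`, the retrieved
#'   `vector`, and the retrieved `feature_function` `f`.
#' @export
ms_retrieve <- function(sys, v, seed = 1L) {
  cue <- ms_cue(sys, v)
  dec <- ms_recognize(sys, cue)
  if (identical(dec$chosen, "rejected"))
    return(list(accepted = FALSE, decision = dec))
  ret <- amr_retrieve(sys$registers[[dec$chosen]], cue, sys$params, seed)
  f <- ret$f
  if (anyNA(f$levels)) {  # rare: xi-admitted empty columns
    lv <- f$levels
    lv[is.na(lv)] <- cue$levels[is.na(lv)]
    f <- feature_function(lv, f$n_levels)
  }
  vec <- if (!is.null(sys$quantizer)) dequantize(sys$quantizer, f) else NULL
  list(accepted = TRUE, label = dec$chosen, f = f, vector = vec,
       decision = dec)
}

#' Evaluate a memory system on labelled test units
#'
#' Computes, for every register, the confusion counts of its own
#' recognition test (positives = test units of its class) and the derived
#' precision/recall/accuracy with the all-rejected conventions of
#' [register_metrics()]; and, at the system level, the precision and recall
#' of the final decision. There are no true negatives at the system level,
#' so system accuracy coincides with recall.
#'
#' @param sys a `memory_system`.
#' @param x numeric matrix of test units (rows).
#' @param y character vector of true labels.
#' @return list with the per-register table `registers`, the means
#'   `reg_precision`/`reg_recall`/`reg_accuracy`, `sys_precision`,
#'   `sys_recall` and the mean register `entropy`.
#' @export
ms_evaluate <- function(sys, x, y) {
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  labels <- names(sys$registers)
  cues <- lapply(seq_len(nrow(x)), function(i) ms_cue(sys, x[i, ]))
  acc <- matrix(FALSE, nrow(x), length(labels),
                dimnames = list(NULL, labels))
  chosen <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    dec <- ms_recognize(sys, cues[[i]])
    acc[i, dec$responders] <- TRUE
    chosen[i] <- dec$chosen
  }
  per <- lapply(labels, function(l) {
    pos <- y == l
    m <- register_metrics(tp = sum(acc[pos, l]), fp = sum(acc[!pos, l]),
                          tn = sum(!acc[!pos, l]), fn = sum(!acc[pos, l]))
    data.frame(label = l, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               precision = m$precision, recall = m$recall,
               accuracy = m$accuracy)
  })
  per <- do.call(rbind, per)
  correct <- sum(chosen == y)
  responded <- sum(chosen != "rejected")
  list(registers = per,
       reg_precision = mean(per$precision),
       reg_recall = mean(per$recall),
       reg_accuracy = mean(per$accuracy),
       sys_precision = if (responded > 0) correct / responded else 1,
       sys_recall = correct / length(y),
       entropy = mean(vapply(sys$registers, amr_entropy, numeric(1))))
}

#' Size and fill-level sweep
#'
#' The capacity experiment harness: for each register size `m` and each
#' fill fraction, a fresh system is built (quantizer fitted on the full
#' remembered set), the chosen fraction of the remembered units is
#' registered, and the per-register and system metrics are evaluated on the
#' test units. Deterministic given `seed` (the fill subset is a seeded
#' sample).
#'
#' @param rem_x,rem_y remembered units (matrix rows) and labels.
#' @param test_x,test_y disjoint test units and labels.
#' @param sizes integer vector of row counts `m`, e.g. `2^(0:10)`.
#' @param fills numeric vector of fill fractions in (0, 1].
#' @param params a [recognition_params()].
#' @param seed integer seed.
#' @return a data.frame with one row per (m, fill) configuration.
#' @export
run_size_sweep <- function(rem_x, rem_y, test_x, test_y,
                           sizes = 2^(0:10), fills = 1,
                           params = recognition_params(), seed = 1L) {
  rem_x <- as.matrix(rem_x); test_x <- as.matrix(test_x)
  rem_y <- as.character(rem_y); test_y <- as.character(test_y)
  if (any(fills <= 0 | fills > 1))
    stop_weam("fill fractions must lie in (0, 1]")
  labels <- sort(unique(c(rem_y, test_y)))
  rows <- list()
  for (m in sizes) {
    q <- quantizer_fit(rem_x, m)
    for (fill in fills) {
      idx <- with_seed(seed, sample.int(nrow(rem_x)))
      idx <- idx[seq_len(ceiling(fill * nrow(rem_x)))]
      sys <- memory_system(labels, ncol(rem_x), m, q, params)
      for (i in idx) sys <- ms_register(sys, rem_y[i], rem_x[i, ])
      ev <- ms_evaluate(sys, test_x, test_y)
      rows[[length(rows) + 1L]] <- data.frame(
        m = m, fill = fill,
        reg_precision = ev$reg_precision, reg_recall = ev$reg_recall,
        reg_accuracy = ev$reg_accuracy,
        sys_precision = ev$sys_precision, sys_recall = ev$sys_recall,
        entropy = ev$entropy)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.memory_system <- function(x, ...) {
  tot <- vapply(x$registers, function(a) sum(a$weights), numeric(1))
  cat(sprintf("<memory_system: %d registers, %d x %d, %s quantizer>\n",
              length(x$registers), x$n_args, x$n_levels,
              if (is.null(x$quantizer)) "no" else "fitted"))
  cat(sprintf("  total weight %d; non-empty registers: %d\n",
              sum(tot), sum(tot > 0)))
  invisible(x)
}
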