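#' Window sampling of a frame stream
#'
#' Slides a `width`-frame analysis window over the stream at a hop of one
#' frame and aggregates each window to a single unit vector (the frame
#' mean), matching the system's feature dimension. Streams shorter than the
#' window yield exactly one window, centre-padded by edge replication. When
#' ground-truth frame labels are present, each window carries the majority
#' label (ties break to the centre frame's label).
#'
#' @param stream list with `frames` (matrix, one row per frame) and
#'   optionally `labels`.
#' @param width window width in frames (default 8).
#' @return list with matrix `x` (one row per window) and `y` (labels or
#'   `NULL`).
#' @export
sample_windows <- function(stream, width = 8L) {
  width <- as.integer(width)
  if (width < 1L) stop_weam("width must be >= 1")
  fr <- stream$frames
  lb <- stream$labels
  nf <- nrow(fr)
  if (is.null(nf) || nf == 0L)
    return(list(x = matrix(numeric(0), 0, ncol(fr) %||% 0L), y = NULL))
  if (nf < width) {
    pad <- width - nf
    pre <- pad %/% 2L
    idx <- c(rep(1L, pre), seq_len(nf), rep(nf, pad - pre))
    fr <- fr[idx, , drop = FALSE]
    if (!is.null(lb)) lb <- lb[idx]
    nf <- width
  }
  nw <- nf - width + 1L
  x <- matrix(0, nw, ncol(fr))
  y <- if (is.null(lb)) NULL else character(nw)
  centre <- ceiling(width / 2)
  for (i in seq_len(nw)) {
    sel <- i:(i + width - 1L)
    x[i, ] <- colMeans(fr[sel, , drop = FALSE])
    if (!is.null(lb)) {
      tab <- table(lb[sel])
      top <- names(tab)[tab == max(tab)]
      y[i] <- if (length(top) == 1L) top else lb[sel[centre]]
    }
  }
  list(x = x, y = y)
}

#' Nearest-centroid classifier
#'
#' The reference implementation of the pluggable classifier interface that
#' stands in for the neural classifier of the full pipeline: class
#' centroids on training units, prediction by smallest Euclidean distance.
#'
#' @param x training matrix (one row per unit).
#' @param y training labels.
#' @return object of class `nearest_centroid`.
#' @export
nearest_centroid <- function(x, y) {
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  labels <- sort(unique(y))
  cent <- t(vapply(labels,
                   function(l) colMeans(x[y == l, , drop = FALSE]),
                   numeric(ncol(x))))
  structure(list(centroids = cent, labels = labels),
            class = "nearest_centroid")
}

#' @rdname nearest_centroid
#' @param object a fitted `nearest_centroid`.
#' @param newdata matrix of units to classify (one row each).
#' @param ... unused.
#' @export
predict.nearest_centroid <- function(object, newdata, ...) {
  newdata <- matrix(newdata, ncol = ncol(object$centroids))
  cn2 <- rowSums(object$centroids^2)
  d <- sweep(newdata %*% t(object$centroids), 2L, cn2 / 2, "-")
  object$labels[max.col(d, ties.method = "first")]
}

#' Active phase: collect novel units through the memory
#'
#' Every analysis window of the novel streams is presented to the memory
#' system. Windows rejected by all registers are discarded; accepted
#' windows act as retrieval cues, and the (cue, retrieved) pair enters the
#' enriched pool under the system's decision label iff both members belong
#' to the same class — by default as judged by the surrogate classifier on
#' both members (`check = "classifier"`), alternatively by comparing the
#' classifier's label for the cue with the memory's decision label
#' (`check = "decision"`). Optional per-class quota targets stop collection
#' for a class once the running count would exceed its target.
#'
#' @param sys a [memory_system()].
#' @param streams list of frame streams (see [sample_windows()]).
#' @param clf a fitted classifier with a `predict` method.
#' @param seed integer seed.
#' @param quotas optional data.frame from [balance_quotas()].
#' @param counts optional named starting counts per class (the current
#'   pool), used together with `quotas`.
#' @param width analysis window width.
#' @param check same-class test variant.
#' @return list with collected matrix `x`, labels `y`, and per-window
#'   bookkeeping `n_windows`, `n_accepted`, `n_kept`.
#' @export
active_phase <- function(sys, streams, clf, seed = 1L,
                         quotas = NULL, counts = NULL, width = 8L,
                         check = c("classifier", "decision")) {
  check <- match.arg(check)
  target <- NULL
  if (!is.null(quotas)) {
    target <- quotas$target
    names(target) <- quotas$label
    counts <- if (is.null(counts))
      stats::setNames(numeric(length(target)), names(target))
    else stats::setNames(as.numeric(counts), names(counts))
  }
  xs <- list(); ys <- character(0)
  n_windows <- 0L; n_accepted <- 0L; n_kept <- 0L
  wseed <- 0L
  for (st in streams) {
    win <- sample_windows(st, width)
    for (i in seq_len(nrow(win$x))) {
      n_windows <- n_windows + 1L
      wseed <- wseed + 1L
      v <- win$x[i, ]
      ret <- ms_retrieve(sys, v, seed = as.integer(seed) + wseed)
      if (!ret$accepted) next
      n_accepted <- n_accepted + 1L
      rv <- ret$vector
      same <- switch(check,
        classifier = identical(predict(clf, v), predict(clf, rv)),
        decision = identical(predict(clf, v), ret$label))
      if (!same) next
      lab <- ret$label
      if (!is.null(target)) {
        cur <- if (lab %in% names(counts)) counts[[lab]] else 0
        tgt <- if (lab %in% names(target)) target[[lab]] else Inf
        if (cur + 2 > tgt) next
        counts[[lab]] <- cur + 2
      }
      xs[[length(xs) + 1L]] <- rbind(v, rv)
      ys <- c(ys, lab, lab)
      n_kept <- n_kept + 1L
    }
  }
  list(x = if (length(xs)) do.call(rbind, xs)
           else matrix(numeric(0), 0, sys$quantizer$n_dims %||% 0L),
       y = ys, n_windows = n_windows, n_accepted = n_accepted,
       n_kept = n_kept)
}

#' Corpus balancing quotas
#'
#' The balancing rule of the incremental protocol: classes with counts
#' above the median are cut off at the median (`cap`); the collection
#' target for classes at or below the median is 10% above the median; and
#' already-high classes may still grow, but by at most one tenth of the
#' count of the most represented class (`target = median + max/10`).
#'
#' @param counts named non-negative counts per class.
#' @return data.frame with `label`, `count`, `cap`, `target`.
#' @export
balance_quotas <- function(counts) {
  if (!length(counts)) stop_weam("at least one class is required")
  counts <- stats::setNames(as.numeric(counts),
                            names(counts) %||% as.character(seq_along(counts)))
  med <- stats::median(counts)
  mx <- max(counts)
  data.frame(label = names(counts), count = unname(counts),
             cap = unname(pmin(counts, med)),
             target = unname(ifelse(counts <= med, 1.1 * med, med + mx / 10)),
             row.names = NULL)
}

# one full passive phase: partition the pool, refit the processing
# surrogates on Train, fill registers from Rem, evaluate on Test
build_stage_state <- function(x, y, config, seed) {
  n <- nrow(x)
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(config$split[1] * n)
  n_rem <- round(config$split[2] * n)
  tr <- idx[seq_len(n_train)]
  rm_ <- idx[n_train + seq_len(n_rem)]
  te <- idx[(n_train + n_rem + 1L):n]
  q <- quantizer_fit(x[tr, , drop = FALSE], config$n_levels)
  clf <- nearest_centroid(x[tr, , drop = FALSE], y[tr])
  sys <- memory_system(sort(unique(y)), ncol(x), config$n_levels,
                       q, config$params)
  for (i in rm_) sys <- ms_register(sys, y[i], x[i, ])
  ev <- ms_evaluate(sys, x[te, , drop = FALSE], y[te])
  list(sys = sys, clf = clf, quantizer = q, eval = ev,
       n_train = length(tr), n_rem = length(rm_), n_test = length(te))
}

#' Run the incremental learning protocol
#'
#' Five-stage (by default) self-training loop over an initial labelled unit
#' pool and per-stage collections of novel frame streams. Stage 0 builds
#' the initial state: optional median cut of over-represented classes, a
#' 70/20/10 Train/Rem/Test partition, quantizer and surrogate classifier
#' fitted on Train, registers filled from Rem, metrics on Test. Each
#' subsequent stage runs an active phase (window sampling, recognition,
#' retrieval, same-class filtering under [balance_quotas()] targets) to
#' enrich the pool, then a passive phase that re-partitions the enriched
#' pool and refits everything (default) or extends the existing registers
#' (`rebuild = FALSE`).
#'
#' @param x,y initial unit matrix and labels.
#' @param stage_streams list (one entry per stage) of lists of frame
#'   streams; an empty entry makes that stage a no-op.
#' @param n_stages number of stages (default 5).
#' @param config list overriding any of: `params`
#'   ([scenario_params()] `"V"` by default), `n_levels` (8), `width` (8),
#'   `split` (`c(0.7, 0.2, 0.1)`), `initial_cut` (TRUE), `rebuild` (TRUE),
#'   `check` (`"classifier"`), `probe` (optional fixed evaluation set as a
#'   list with `x` and `y`: because Test_s is re-drawn from the enriched
#'   pool each stage, stagewise metrics on it are not directly comparable;
#'   a fixed probe gives comparable `probe_precision`/`probe_recall`
#'   columns).
#' @param seed integer seed.
#' @return list with the per-stage `report` data.frame (one row per stage
#'   including stage 0), the final `state`, and the final pool.
#' @export
run_stages <- function(x, y, stage_streams, n_stages = 5L,
                       config = list(), seed = 1L) {
  defaults <- list(params = scenario_params("V"), n_levels = 8L,
                   width = 8L, split = c(0.7, 0.2, 0.1),
                   initial_cut = TRUE, rebuild = TRUE, check = "classifier")
  config <- utils::modifyList(defaults, config)
  if (abs(sum(config$split) - 1) > 1e-9)
    stop_weam("split fractions must sum to 1")
  x <- as.matrix(x); y <- as.character(y)
  if (isTRUE(config$initial_cut)) {
    q <- balance_quotas(table(y))
    keep <- unlist(lapply(seq_len(nrow(q)), function(k) {
      ids <- which(y == q$label[k])
      if (length(ids) > q$cap[k])
        ids <- with_seed(seed + k, sample(ids, q$cap[k]))
      ids
    }))
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  state <- build_stage_state(x, y, config, seed)
  row <- function(s, st, px, py, act) {
    cnt <- table(py)
    out <- data.frame(stage = s, n_pool = length(py),
                      n_classes = length(cnt),
                      imbalance = max(cnt) / min(cnt),
                      n_collected = act,
                      sys_precision = st$eval$sys_precision,
                      sys_recall = st$eval$sys_recall,
                      reg_precision = st$eval$reg_precision,
                      reg_recall = st$eval$reg_recall,
                      entropy = st$eval$entropy)
    if (!is.null(config$probe)) {
      pe <- ms_evaluate(st$sys, config$probe$x, config$probe$y)
      out$probe_precision <- pe$sys_precision
      out$probe_recall <- pe$sys_recall
    }
    out
  }
  report <- row(0L, state, x, y, 0L)
  for (s in seq_len(n_stages)) {
    streams <- if (s <= length(stage_streams)) stage_streams[[s]] else list()
    if (!length(streams)) {
      report <- rbind(report, row(s, state, x, y, 0L))
      next
    }
    quotas <- balance_quotas(table(y))
    got <- active_phase(state$sys, streams, state$clf,
                        seed = seed + 7919L * s,
                        quotas = quotas, counts = table(y),
                        width = config$width, check = config$check)
    if (nrow(got$x)) {
      x <- rbind(x, got$x)
      y <- c(y, got$y)
    }
    if (isTRUE(config$rebuild)) {
      state <- build_stage_state(x, y, config, seed + s)
    } else if (nrow(got$x)) {
      # extend: keep quantizer/classifier, register the new units' Rem share
      n_new <- nrow(got$x)
      idx <- with_seed(seed + s, sample.int(n_new))
      rm_ <- idx[seq_len(max(1L, round(config$split[2] * n_new)))]
      for (i in rm_) state$sys <- ms_register(state$sys, got$y[i], got$x[i, ])
      te <- with_seed(seed + s + 1L,
                      sample.int(length(y), max(2L, round(0.1 * length(y)))))
      state$eval <- ms_evaluate(state$sys, x[te, , drop = FALSE], y[te])
    }
    report <- rbind(report, row(s, state, x, y, got$n_kept))
  }
  list(report = report, state = state, pool = list(x = x, y = y))
}
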