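#' Synthetic class-conditional data generator
#'
#' Emulates the intermediate (encoder-output) representation of a phonetic
#' pipeline so every component is testable without external corpora: one
#' Gaussian cluster per phone class in `n_dims`-dimensional space, frame
#' streams sampled at a 10 ms hop, 8-frame analysis windows, and phone
#' durations drawn from a normal with mean 69.9 ms and s.d. 28.9 ms
#' truncated at one frame. Class means are drawn once at configuration time
#' (`N(0, separation^2)` per dimension), so a config value fully determines
#' the population.
#'
#' @param n_classes number of classes (default 22, one per Mexbet phone).
#' @param n_dims feature dimension (default 32).
#' @param separation s.d. of the class-mean coordinates; larger values
#'   spread the clusters further apart.
#' @param spread within-class s.d. of unit vectors around their class mean.
#' @param outlier_frac fraction of units drawn as broad outliers (atypical
#'   realizations — noisy or coarticulated segments). Real encoder outputs
#'   are heavy-tailed, and the heavy tail is functionally important: the
#'   cue-strength test of recognition compares a cue's cell weights against
#'   the mean non-zero column weight, which only drops below the modal
#'   weights when columns also hold rarely-used cells. Memories built from
#'   outlier-free clusters reject every cue once `kappa >= 1`.
#' @param outlier_spread s.d. of the outlier component.
#' @param frame_jitter s.d. of individual frames around their unit vector;
#'   defaults to half the spread so 8-frame window means stay
#'   class-informative.
#' @param profile `"balanced"` or `"zipf"` (frequency of class `r`
#'   proportional to `1/r`) class frequencies.
#' @param dur_mean,dur_sd phone duration distribution in ms.
#' @param hop_ms frame hop in ms.
#' @param window analysis window width in frames.
#' @param seed seed fixing the class means.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_classes = 22L, n_dims = 32L,
                             separation = 1, spread = 0.1,
                             outlier_frac = 0.02, outlier_spread = 2,
                             frame_jitter = spread / 2,
                             profile = c("balanced", "zipf"),
                             dur_mean = 69.9, dur_sd = 28.9,
                             hop_ms = 10, window = 8L, seed = 1L) {
  profile <- match.arg(profile)
  n_classes <- as.integer(n_classes); n_dims <- as.integer(n_dims)
  if (spread < 0 || separation <= 0)
    stop_weam("separation must be positive and spread non-negative")
  labels <- if (n_classes <= 22L) mexbet_phones()[seq_len(n_classes)]
            else sprintf("c%02d", seq_len(n_classes))
  means <- with_seed(seed,
    matrix(stats::rnorm(n_classes * n_dims, 0, separation),
           n_classes, n_dims, dimnames = list(labels, NULL)))
  freqs <- switch(profile,
                  balanced = rep(1 / n_classes, n_classes),
                  zipf = (1 / seq_len(n_classes)) / sum(1 / seq_len(n_classes)))
  names(freqs) <- labels
  structure(list(n_classes = n_classes, n_dims = n_dims,
                 separation = separation, spread = spread,
                 outlier_frac = outlier_frac, outlier_spread = outlier_spread,
                 frame_jitter = frame_jitter, profile = profile,
                 freqs = freqs, labels = labels, means = means,
                 dur_mean = dur_mean, dur_sd = dur_sd,
                 hop_ms = hop_ms, window = as.integer(window), seed = seed),
            class = "generator_config")
}

# duration in ms from the normal truncated below at one frame (hop_ms),
# by inverse-CDF so a single runif drives each draw
rdur <- function(n, cfg) {
  plo <- stats::pnorm(cfg$hop_ms, cfg$dur_mean, cfg$dur_sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, cfg$dur_mean, cfg$dur_sd)
}

#' Generate unit vectors of one class
#'
#' @param cfg a [generator_config()].
#' @param label class label (or 1-based index).
#' @param count number of vectors.
#' @param seed integer seed.
#' @return a `count x n_dims` matrix.
#' @export
generate_units <- function(cfg, label, count, seed = 1L) {
  if (is.numeric(label)) label <- cfg$labels[label]
  if (!label %in% cfg$labels) stop_weam("unknown class '", label, "'")
  mu <- cfg$means[label, ]
  with_seed(seed, draw_units(cfg, mu, count))
}

# class-conditional draw: tight core plus a broad outlier component;
# caller owns the RNG state
draw_units <- function(cfg, mu, count) {
  sd_unit <- ifelse(stats::runif(count) < cfg$outlier_frac,
                    cfg$outlier_spread, cfg$spread)
  z <- matrix(stats::rnorm(count * cfg$n_dims), count, cfg$n_dims) * sd_unit
  sweep(z, 2L, mu, "+")
}

#' Generate a synthetic utterance
#'
#' For each phone of the requested sequence a duration is drawn from the
#' truncated normal and converted to frames at the 10 ms hop (at least one
#' frame); a unit vector is drawn from the phone's cluster and the frames
#' scatter around it with `frame_jitter`. Frame-aligned ground-truth labels
#' are attached.
#'
#' @param cfg a [generator_config()].
#' @param phones character vector of phone labels (the ground truth).
#' @param seed integer seed.
#' @param durations optional forced durations in ms (recycled), bypassing
#'   the duration model.
#' @return list with `frames` (matrix, one row per 10 ms frame), `labels`
#'   (per frame), `units` (one row per phone), and `phones`.
#' @export
generate_utterance <- function(cfg, phones, seed = 1L, durations = NULL) {
  if (!length(phones))
    return(list(frames = matrix(numeric(0), 0, cfg$n_dims),
                labels = character(0),
                units = matrix(numeric(0), 0, cfg$n_dims),
                phones = character(0)))
  bad <- setdiff(unique(phones), cfg$labels)
  if (length(bad))
    stop_weam("phones not in the inventory: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    durs <- if (is.null(durations)) rdur(length(phones), cfg)
            else rep_len(durations, length(phones))
    nfr <- pmax(1L, as.integer(round(durs / cfg$hop_ms)))
    units <- matrix(0, length(phones), cfg$n_dims)
    frames <- vector("list", length(phones))
    for (k in seq_along(phones)) {
      mu <- cfg$means[phones[k], ]
      u <- draw_units(cfg, mu, 1L)[1L, ]
      units[k, ] <- u
      jit <- matrix(stats::rnorm(nfr[k] * cfg$n_dims, 0, cfg$frame_jitter),
                    nfr[k], cfg$n_dims)
      frames[[k]] <- sweep(jit, 2L, u, "+")
    }
    list(frames = do.call(rbind, frames),
         labels = rep(phones, nfr),
         units = units, phones = phones)
  })
}

#' Generate a partitioned synthetic corpus
#'
#' Utterances are random phone sequences drawn from the configured class
#' frequency profile, then split disjointly into Train (70%), Rem (20%) and
#' Test (10%) partitions — training data for the processing surrogates,
#' fill data for the memory registers, and held-out evaluation data.
#'
#' @param cfg a [generator_config()].
#' @param n_utterances at least 10.
#' @param seed integer seed.
#' @param len_range inclusive range of phones per utterance.
#' @return list with `train`, `rem`, `test`, each a list of utterances as
#'   returned by [generate_utterance()].
#' @export
generate_corpus <- function(cfg, n_utterances, seed = 1L,
                            len_range = c(5L, 15L)) {
  if (n_utterances < 10L) stop_weam("n_utterances must be >= 10")
  utts <- with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n_utterances, replace = TRUE)
    seqs <- lapply(lens, function(L)
      sample(cfg$labels, L, replace = TRUE, prob = cfg$freqs))
    useeds <- sample.int(.Machine$integer.max %/% 2L, n_utterances)
    Map(function(s, sd) generate_utterance(cfg, s, seed = sd), seqs, useeds)
  })
  n_train <- round(0.7 * n_utterances)
  n_rem <- round(0.2 * n_utterances)
  list(train = utts[seq_len(n_train)],
       rem = utts[n_train + seq_len(n_rem)],
       test = utts[(n_train + n_rem + 1L):n_utterances])
}

#' Stack the unit vectors of a corpus partition
#'
#' @param utterances a list of utterances from [generate_utterance()].
#' @return list with matrix `x` (one row per phone unit) and labels `y`.
#' @export
corpus_units <- function(utterances) {
  list(x = do.call(rbind, lapply(utterances, `[[`, "units")),
       y = unlist(lapply(utterances, `[[`, "phones"), use.names = FALSE))
}
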