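#' Weighted associative memory registers
#'
#' A weighted associative memory register (AMR) is an `n x m` table of
#' non-negative integer weights: columns are arguments (features), rows are
#' discrete values. A cell weight `w_ij` counts how often registration has
#' used value `j` for argument `i`; the relation held by the register
#' contains the pair `(a_i, v_j)` exactly when `w_ij > 0`. Each column,
#' normalized by its total weight, is a probability distribution over the
#' values of its argument, so the register as a whole is a parallel array of
#' per-argument distributions from which objects can be reconstructed.
#'
#' Internally the table is stored as an `n_levels x n_args` integer matrix
#' (matrix columns = arguments), which makes column sums and per-argument
#' distributions natural `colSums`/`sweep` operations.
#'
#' @param n_args number of arguments (columns of the conceptual table), `n`.
#' @param n_levels number of discrete values per argument (rows), `m`.
#' @param label optional class label (e.g. a phone symbol).
#' @return an object of class `weighted_amr`.
#' @examples
#' a <- weighted_amr(4, 4, label = "a")
#' a <- amr_register(a, feature_function(c(0, 1, 2, 3), 4))
#' amr_entropy(a)
#' @export
weighted_amr <- function(n_args, n_levels, label = NA_character_) {
  n_args <- as.integer(n_args); n_levels <- as.integer(n_levels)
  if (n_args < 1L || n_levels < 1L)
    stop_weam("n_args and n_levels must be positive integers")
  structure(list(weights = matrix(0L, nrow = n_levels, ncol = n_args),
                 label = as.character(label)),
            class = "weighted_amr")
}

amr_n_args <- function(amr) ncol(amr$weights)
amr_n_levels <- function(amr) nrow(amr$weights)

check_dims <- function(amr, cue) {
  if (!inherits(cue, "feature_function"))
    stop_weam("cue must be a feature_function")
  if (ff_n_args(cue) != amr_n_args(amr) || cue$n_levels != amr_n_levels(amr))
    stop_weam(sprintf(
      "dimension mismatch: cue is %d args x %d levels, register is %d x %d",
      ff_n_args(cue), cue$n_levels, amr_n_args(amr), amr_n_levels(amr)))
  invisible(TRUE)
}

#' Register a cue into an AMR
#'
#' The register operation is additive: each cell addressed by a defined
#' argument of the cue is incremented by one. Undefined (partial-cue)
#' arguments leave their column untouched. Weights never decrease, so an
#' AMR's history is monotone.
#'
#' @param amr a `weighted_amr`.
#' @param cue a `feature_function` of matching dimensions.
#' @return the updated register.
#' @export
amr_register <- function(amr, cue) {
  check_dims(amr, cue)
  def <- which(!is.na(cue$levels))
  if (length(def)) {
    idx <- cbind(cue$levels[def] + 1L, def)
    amr$weights[idx] <- amr$weights[idx] + 1L
  }
  amr
}

#' Per-column statistics of an AMR
#'
#' For each argument column `i`: the accumulated weight `W_i`, the count `k`
#' of non-zero cells, the mean non-zero weight `omega_i` (0 for an empty
#' column), the probability vector `p_i` (all zero when `W_i = 0`) and the
#' Shannon entropy `e_i` in bits.
#'
#' @param amr a `weighted_amr`.
#' @return a list with vector fields `W`, `k`, `omega`, `e` and the
#'   `n_levels x n_args` probability matrix `p`.
#' @export
amr_column_stats <- function(amr) {
  w <- amr$weights
  W <- colSums(w)
  k <- colSums(w > 0L)
  omega <- ifelse(k > 0L, W / k, 0)
  p <- sweep(w, 2L, ifelse(W > 0, W, 1), "/")
  p[, W == 0] <- 0
  e <- -colSums(matrix(xlog2(as.numeric(p)), nrow = nrow(w)))
  list(W = W, k = k, omega = omega, p = p, e = pmax(e, 0))
}

#' Entropy of a weighted AMR
#'
#' The entropy of a column is the Shannon entropy of its weight
#' distribution (with the `0 log 0 = 0` convention); the entropy of the
#' register is the mean column entropy. Empty columns contribute 0. The
#' entropy measures the indeterminacy of the distributed representation:
#' a register holding a single function (at any multiplicity) has entropy 0.
#'
#' @param amr a `weighted_amr`.
#' @return mean column entropy in bits, in `[0, log2(n_levels)]`.
#' @seealso [amr_basic_entropy()] for the unweighted variant.
#' @export
amr_entropy <- function(amr) mean(amr_column_stats(amr)$e)

#' Unweighted (binary) entropy of an AMR
#'
#' Treats every cell as on/off: a column with `k > 0` marked cells
#' contributes `log2(k)` regardless of the weight magnitudes, and an empty
#' column contributes 0 (it is fully determined). This is the indeterminacy
#' measure of the original, unweighted memory model; the weighted entropy of
#' [amr_entropy()] is never larger.
#'
#' @param amr a `weighted_amr`.
#' @return mean of `log2(k_i)` over columns, empty columns counting 0.
#' @export
amr_basic_entropy <- function(amr) {
  k <- colSums(amr$weights > 0L)
  mean(log2(pmax(k, 1L)))
}

#' Count the functions held by an AMR
#'
#' The distributed representation generalizes: the register holds every
#' total function that can be formed by picking one marked cell per
#' non-empty column, not just the functions registered explicitly. `F_T` is
#' that combinatorial count (empty columns contribute a factor of 1), and
#' the productivity `F_P = F_T - registered` is the number of emergent
#' (latent) functions. When all marked cells within each column carry equal
#' weight, `F_T = 2^(e * n)` with `e` the register entropy.
#'
#' `F_T` is returned as a double — exact below 2^53 — together with
#' `log2_F_T` computed in log space, which stays accurate for registers
#' whose count overflows a double.
#'
#' @param amr a `weighted_amr`.
#' @param registered number of distinct functions registered explicitly
#'   (`|F_R|`); the register itself does not track this.
#' @return list with `F_T`, `F_P` and `log2_F_T`.
#' @export
amr_count_functions <- function(amr, registered = 0) {
  if (registered < 0) stop_weam("registered must be >= 0")
  k <- pmax(colSums(amr$weights > 0L), 1L)
  log2_FT <- sum(log2(k))
  FT <- prod(as.numeric(k))
  if (is.finite(FT) && registered > FT)
    stop_weam("registered exceeds the total function count F_T = ", FT)
  list(F_T = FT, F_P = FT - registered, log2_F_T = log2_FT)
}

#' Recognition parameters
#'
#' The tuple governing recognition and retrieval: `iota` scales the minimum
#' weight a hit cell must reach (relative to its column's mean non-zero
#' weight) for the argument to pass; `kappa` scales the minimum cue strength
#' `rho` relative to the register-wide mean weight `Omega`; `xi` is the
#' number of arguments allowed to fail the implication test; `sigma` is the
#' standard deviation of the retrieval distribution centred on the cue.
#'
#' @param iota cell-sensitivity threshold, real >= 0.
#' @param kappa cue-strength threshold, real >= 0.
#' @param xi implication relaxation, integer >= 0.
#' @param sigma retrieval noise s.d.; 0 gives photographic retrieval.
#' @param sigma_units `"rows"` (default) interprets `sigma` in row units;
#'   `"fraction"` multiplies it by the number of rows first.
#' @return an object of class `recognition_params`.
#' @export
recognition_params <- function(iota = 0, kappa = 0, xi = 0L, sigma = 0.5,
                               sigma_units = c("rows", "fraction")) {
  if (iota < 0 || kappa < 0 || xi < 0 || sigma < 0)
    stop_weam("recognition parameters must be non-negative")
  structure(list(iota = iota, kappa = kappa, xi = as.integer(xi),
                 sigma = sigma, sigma_units = match.arg(sigma_units)),
            class = "recognition_params")
}

#' The six studied parameter scenarios
#'
#' Named parameter settings I-VI spanning the permissive-to-selective range:
#' I (0, 0, 0, 0.5), II (0.3, 0, 0, 0.5), III (0, 1.5, 0, 0.5),
#' IV (0, 0, 0, 0.1), V (0.3, 1.5, 0, 0.1), VI (0.3, 1.5, 1, 0.1),
#' as (iota, kappa, xi, sigma).
#'
#' @param name one of `"I" .. "VI"`.
#' @return a `recognition_params` object.
#' @export
scenario_params <- function(name) {
  tab <- list(I   = c(0,   0,   0, 0.5),
              II  = c(0.3, 0,   0, 0.5),
              III = c(0,   1.5, 0, 0.5),
              IV  = c(0,   0,   0, 0.1),
              V   = c(0.3, 1.5, 0, 0.1),
              VI  = c(0.3, 1.5, 1, 0.1))
  p <- tab[[toupper(name)]]
  if (is.null(p)) stop_weam("unknown scenario '", name, "'")
  recognition_params(iota = p[1], kappa = p[2], xi = p[3], sigma = p[4])
}

#' Recognize a cue against an AMR
#'
#' Recognition is a relaxed material-implication test plus a cue-strength
#' test. Per defined argument `i` with cue value `j`, the argument passes
#' iff `w_ij > 0` and `w_ij >= iota * omega_i` (a zero cell always fails:
#' the pair is not in the relation). Undefined arguments pass vacuously.
#' The cue is accepted iff at most `xi` arguments fail and its mean weight
#' `rho = (1/n) sum_i w_{i,cue(i)}` reaches `kappa * Omega`, where `Omega`
#' is the mean of the column mean weights.
#'
#' @param amr a `weighted_amr`.
#' @param cue a `feature_function` of matching dimensions.
#' @param params a `recognition_params`.
#' @return list with `accepted`, `per_arg_pass`, `failed_args`, `rho`,
#'   `omega_bar` and `entropy` (register entropy at test time).
#' @export
amr_recognize <- function(amr, cue, params = recognition_params()) {
  check_dims(amr, cue)
  st <- amr_column_stats(amr)
  n <- amr_n_args(amr)
  def <- !is.na(cue$levels)
  hit <- numeric(n)
  hit[def] <- amr$weights[cbind(cue$levels[def] + 1L, which(def))]
  pass <- rep(TRUE, n)
  pass[def] <- hit[def] > 0 & hit[def] >= params$iota * st$omega[def]
  failed <- sum(!pass)
  rho <- sum(hit) / n
  Omega <- mean(st$omega)
  list(accepted = failed <= params$xi && rho >= params$kappa * Omega,
       per_arg_pass = pass, failed_args = failed,
       rho = rho, omega_bar = Omega, entropy = mean(st$e))
}

# Probability mass of a unit-sd-sigma normal centred at `center` (0-based
# row index), integrated over the unit bins [j-0.5, j+0.5), j = 0..m-1.
# sigma = 0 degenerates to a point mass at the cue's own row.
zeta_bins <- function(center, sigma, m) {
  if (sigma <= 0) {
    z <- numeric(m); z[center + 1L] <- 1
    return(z)
  }
  edges <- seq(-0.5, m - 0.5, by = 1)
  diff(stats::pnorm(edges, mean = center, sd = sigma))
}

#' Retrieve an object from an AMR
#'
#' Constructive retrieval: if the cue is rejected the result is undefined
#' everywhere; otherwise each argument's output level is drawn from
#' `Phi_i`, the renormalized product of the column distribution `Psi_i` and
#' a discretized normal `zeta_i` centred on the cue's level with s.d.
#' `sigma` (integrated over unit bins). With `sigma = 0` retrieval is a
#' photographic copy of the cue. Undefined cue arguments, and arguments
#' whose `Phi_i` has no mass (possible only when `xi` let a failing
#' argument through), are filled by sampling `Psi_i` alone; an empty column
#' stays undefined.
#'
#' @param amr a `weighted_amr`.
#' @param cue a `feature_function` of matching dimensions.
#' @param params a `recognition_params`.
#' @param seed integer seed; all sampling is local to this call.
#' @return list with `accepted`, the retrieved `feature_function` `f`
#'   (all-`NA` levels when rejected), and the `recognition` detail.
#' @export
amr_retrieve <- function(amr, cue, params = recognition_params(), seed = 1L) {
  rec <- amr_recognize(amr, cue, params)
  n <- amr_n_args(amr); m <- amr_n_levels(amr)
  out <- rep(NA_integer_, n)
  if (!rec$accepted)
    return(list(accepted = FALSE,
                f = feature_function(out, m), recognition = rec))
  sigma <- params$sigma
  if (identical(params$sigma_units, "fraction")) sigma <- sigma * m
  st <- amr_column_stats(amr)
  with_seed(seed, {
    for (i in seq_len(n)) {
      psi <- st$p[, i]
      if (sum(psi) <= 0) next  # empty column: stays undefined
      lv <- cue$levels[i]
      phi <- if (is.na(lv)) psi else psi * zeta_bins(lv, sigma, m)
      if (sum(phi) <= 0) phi <- psi  # xi-admitted miss: prior alone
      out[i] <- sample.int(m, 1L, prob = phi) - 1L
    }
  })
  list(accepted = TRUE, f = feature_function(out, m), recognition = rec)
}

#' @export
print.weighted_amr <- function(x, ...) {
  cat(sprintf("<weighted_amr '%s': %d args x %d levels, total weight %d, e = %.4f>\n",
              x$label, amr_n_args(x), amr_n_levels(x),
              sum(x$weights), amr_entropy(x)))
  invisible(x)
}
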