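#' Discrete feature functions
#'
#' A feature function assigns one of `m` discrete levels to each of `n`
#' arguments. It is the unit of exchange with an associative memory
#' register: cues presented for registration, recognition and retrieval are
#' feature functions, and retrieval produces one. Levels are 0-based
#' (`0 .. n_levels - 1`) to match the quantization arithmetic; an `NA` entry
#' marks an undefined argument, making the function *partial*.
#'
#' @param levels integer vector of level indices, `NA` for undefined
#'   arguments.
#' @param n_levels number of discrete levels (`m`), a positive integer.
#' @return an object of class `feature_function` with fields `levels` and
#'   `n_levels`.
#' @examples
#' f <- feature_function(c(0, 3, NA, 1), n_levels = 4)
#' ff_is_total(f)
#' @export
feature_function <- function(levels, n_levels) {
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 1L)
    stop_weam("n_levels must be a positive integer")
  lv <- suppressWarnings(as.integer(levels))
  if (length(lv) < 1L)
    stop_weam("a feature function needs at least one argument")
  bad <- !is.na(lv) & (lv < 0L | lv >= n_levels)
  if (any(bad))
    stop_weam("defined levels must lie in [0, n_levels - 1]; offending ",
              "argument(s): ", paste(which(bad), collapse = ", "))
  structure(list(levels = lv, n_levels = n_levels),
            class = "feature_function")
}

#' @rdname feature_function
#' @param f a `feature_function`.
#' @export
ff_is_total <- function(f) !anyNA(f$levels)

#' @rdname feature_function
#' @export
ff_n_args <- function(f) length(f$levels)

#' @export
print.feature_function <- function(x, ...) {
  lv <- ifelse(is.na(x$levels), "-", as.character(x$levels))
  cat(sprintf("<feature_function: %d args, %d levels%s>\n",
              ff_n_args(x), x$n_levels,
              if (ff_is_total(x)) "" else ", partial"))
  cat(" ", paste(lv, collapse = " "), "\n")
  invisible(x)
}
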