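# shared fixture builders; everything is constructed in code

ff <- function(levels, m) feature_function(levels, m)

# build an AMR by registering a list of total functions (level vectors)
amr_from <- function(fns, n, m, label = "x", times = 1L) {
  a <- weighted_amr(n, m, label)
  for (lv in fns) for (i in seq_len(times)) a <- amr_register(a, ff(lv, m))
  a
}

# a seeded random AMR: `reg` random total functions registered
random_amr <- function(n, m, reg, seed) {
  set.seed(seed)
  fns <- replicate(reg, sample.int(m, n, replace = TRUE) - 1L,
                   simplify = FALSE)
  amr_from(fns, n, m)
}

# labelled class-conditional units via the package generator
units_for <- function(cfg, per_class, seed0) {
  x <- do.call(rbind, lapply(seq_along(cfg$labels), function(i)
    generate_units(cfg, i, per_class, seed = seed0 + i)))
  list(x = x, y = rep(cfg$labels, each = per_class))
}

# exhaustive function-count oracle: enumerate all m^n total functions and
# keep those whose cells are all non-zero in the table
count_functions_oracle <- function(amr) {
  n <- ncol(amr$weights); m <- nrow(amr$weights)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m) - 1L), n)))
  sum(apply(grid, 1L, function(lv)
    all(amr$weights[cbind(lv + 1L, seq_len(n))] > 0L)))
}

# naive recursive edit-distance oracle (exponential; tiny inputs only)
lev_oracle <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(lev_oracle(a[-1], b) + 1L,
      lev_oracle(a, b[-1]) + 1L,
      lev_oracle(a[-1], b[-1]) + (a[1] != b[1]))
}
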