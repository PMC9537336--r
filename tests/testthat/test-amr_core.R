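test_that("feature functions validate their levels", {
  f <- ff(c(0, 3, NA, 1), 4)
  expect_false(ff_is_total(f))
  expect_equal(ff_n_args(f), 4L)
  expect_true(ff_is_total(ff(c(0, 1), 2)))
  expect_error(feature_function(c(0, 4), 4), "levels")
  expect_error(feature_function(c(-1, 0), 4), "levels")
  expect_error(feature_function(integer(0), 4), "argument")
})

test_that("registration increments exactly the hit cells", {
  a <- amr_from(list(c(0, 1, 2, 3)), 4, 4)
  expect_equal(a$weights[cbind(1:4, 1:4)], rep(1L, 4))
  expect_equal(sum(a$weights), 4L)

  a5 <- amr_from(list(c(0, 1, 2, 3)), 4, 4, times = 5L)
  expect_equal(a5$weights[cbind(1:4, 1:4)], rep(5L, 4))
  expect_equal(amr_entropy(a5), 0)

  # partial cue: undefined arguments leave their column untouched
  p <- amr_register(weighted_amr(3, 2), ff(c(1, NA, 0), 2))
  expect_equal(colSums(p$weights), c(1L, 0L, 1L))

  expect_error(amr_register(weighted_amr(3, 2), ff(c(0, 1), 2)), "mismatch")
})

test_that("registration is monotone and order-independent", {
  set.seed(11)
  fns <- replicate(20, sample.int(4, 3, replace = TRUE) - 1L,
                   simplify = FALSE)
  a <- weighted_amr(3, 4)
  prev <- a$weights
  for (lv in fns) {
    a <- amr_register(a, ff(lv, 4))
    expect_true(all(a$weights >= prev))
    prev <- a$weights
  }
  b <- amr_from(rev(fns), 3, 4)
  expect_identical(a$weights, b$weights)
})

test_that("weighted entropy follows the column distributions", {
  # uniform column
  a <- amr_from(list(c(0), c(1), c(2), c(3)), 1, 4)
  expect_equal(amr_entropy(a), 2)
  # 3:1 split column: -(3/4)log2(3/4) - (1/4)log2(1/4)
  b <- amr_from(list(c(0), c(0), c(0), c(1)), 1, 4)
  expect_equal(amr_entropy(b), -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  # single registered function at any multiplicity
  expect_equal(amr_entropy(amr_from(list(c(2, 0)), 2, 3, times = 7L)), 0)
  # empty AMR
  expect_equal(amr_entropy(weighted_amr(5, 8)), 0)
  # column stats invariants
  st <- amr_column_stats(amr_from(list(c(0, 0), c(1, 1), c(1, 0)), 2, 2))
  expect_equal(colSums(st$p), rep(1, 2))
  expect_true(all(st$e >= 0 & st$e <= log2(2)))
})

test_that("basic entropy ignores weight magnitudes", {
  expect_equal(amr_basic_entropy(weighted_amr(4, 4)), 0)
  a <- amr_from(list(c(0, 0), c(1, 1)), 2, 2)
  expect_equal(amr_basic_entropy(a), 1)
  # [3,1,0,0] column contributes log2(2) = 1 regardless of weights
  b <- amr_from(list(c(0), c(0), c(0), c(1)), 1, 4)
  expect_equal(amr_basic_entropy(b), 1)
  expect_equal(amr_entropy(b) < amr_basic_entropy(b), TRUE)
})

test_that("function counting matches combinatorics and the 2^(en) law", {
  a <- amr_from(list(c(0, 0), c(1, 1)), 2, 2)
  cf <- amr_count_functions(a, registered = 2)
  expect_equal(cf$F_T, 4)
  expect_equal(cf$F_P, 2)
  expect_equal(2^(amr_entropy(a) * 2), cf$F_T)

  one <- amr_from(list(c(1, 0, 2)), 3, 3)
  expect_equal(amr_count_functions(one, 1)$F_T, 1)
  expect_equal(amr_count_functions(one, 1)$F_P, 0)

  # fully uniform n x m table holds m^n functions
  u <- weighted_amr(3, 4)
  for (j in 0:3) u <- amr_register(u, ff(rep(j, 3), 4))
  expect_equal(amr_count_functions(u)$F_T, 4^3)
  expect_equal(2^(amr_entropy(u) * 3), 4^3)

  expect_error(amr_count_functions(one, registered = 5), "exceeds")
})

test_that("function counting equals exhaustive enumeration for n, m <= 4", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(1:4, 1); m <- sample(2:4, 1)
    a <- random_amr(n, m, reg = sample(1:6, 1), seed = 100 + rep)
    expect_equal(amr_count_functions(a)$F_T, count_functions_oracle(a),
                 info = sprintf("n=%d m=%d rep=%d", n, m, rep))
  }
})

test_that("2^(en) equals the count exactly iff non-zero weights are equal", {
  eq <- amr_from(list(c(0, 0), c(1, 1)), 2, 2)          # equal weights
  expect_equal(2^(amr_entropy(eq) * 2), amr_count_functions(eq)$F_T)
  uneq <- amr_from(list(c(0, 0), c(0, 0), c(1, 1)), 2, 2) # 2:1 weights
  expect_lt(2^(amr_entropy(uneq) * 2), amr_count_functions(uneq)$F_T)
})

test_that("recognition implements the relaxed implication and kappa test", {
  # AMR containing only the cue: accepted, rho = Omega = 1
  a <- amr_from(list(c(0, 2, 1)), 3, 3)
  r <- amr_recognize(a, ff(c(0, 2, 1), 3), recognition_params(iota = 0.3))
  expect_true(r$accepted)
  expect_equal(r$rho, 1)
  expect_equal(r$omega_bar, 1)

  # kappa rejects a weak cue even when every argument passes iota
  b <- amr_from(list(c(0, 0)), 2, 2, times = 3L)
  b <- amr_register(b, ff(c(1, 1), 2))
  rw <- amr_recognize(b, ff(c(1, 1), 2),
                      recognition_params(iota = 0.3, kappa = 1.5))
  expect_false(rw$accepted)
  expect_equal(rw$failed_args, 0L)      # implication passed everywhere
  expect_equal(rw$rho, 1)
  expect_equal(rw$omega_bar, 2)
  # the strong cue is accepted
  expect_true(amr_recognize(b, ff(c(0, 0), 2),
                            recognition_params(iota = 0.3, kappa = 1.5))$accepted)

  # empty AMR rejects any cue while xi < n
  e <- weighted_amr(3, 3)
  expect_false(amr_recognize(e, ff(c(0, 1, 2), 3),
                             recognition_params())$accepted)
  expect_true(amr_recognize(e, ff(c(0, 1, 2), 3),
                            recognition_params(xi = 3))$accepted)

  # zero-weight cells fail even at iota = 0
  z <- amr_from(list(c(0, 0)), 2, 2)
  expect_false(amr_recognize(z, ff(c(0, 1), 2),
                             recognition_params(iota = 0))$accepted)

  # undefined arguments pass vacuously and contribute 0 to rho
  rp <- amr_recognize(a, ff(c(0, NA, NA), 3), recognition_params())
  expect_true(rp$accepted)
  expect_equal(rp$rho, 1 / 3)
})

test_that("acceptance is monotone in iota, kappa and xi", {
  set.seed(31)
  amrs <- lapply(1:4, function(k) random_amr(6, 4, reg = 12, seed = 40 + k))
  cues <- replicate(40, ff(sample.int(4, 6, replace = TRUE) - 1L, 4),
                    simplify = FALSE)
  accepted_set <- function(p) {
    unlist(lapply(seq_along(amrs), function(ai)
      vapply(cues, function(cu) amr_recognize(amrs[[ai]], cu, p)$accepted,
             logical(1))))
  }
  iotas <- c(0, 0.3, 0.7, 1, 1.5)
  kappas <- c(0, 0.5, 1, 1.5, 2)
  xis <- 0:4
  for (i in seq_len(length(iotas) - 1L)) {
    lo <- accepted_set(recognition_params(iota = iotas[i]))
    hi <- accepted_set(recognition_params(iota = iotas[i + 1L]))
    expect_true(all(lo >= hi))  # larger iota accepts a subset
  }
  for (i in seq_len(length(kappas) - 1L)) {
    lo <- accepted_set(recognition_params(kappa = kappas[i]))
    hi <- accepted_set(recognition_params(kappa = kappas[i + 1L]))
    expect_true(all(lo >= hi))
  }
  for (i in seq_len(length(xis) - 1L)) {
    lo <- accepted_set(recognition_params(iota = 0.8, xi = xis[i]))
    hi <- accepted_set(recognition_params(iota = 0.8, xi = xis[i + 1L]))
    expect_true(all(hi >= lo))  # larger xi accepts a superset
  }
})

test_that("sigma = 0 retrieval is photographic on accepted cues", {
  set.seed(51)
  for (rep in 1:10) {
    a <- random_amr(5, 6, reg = 8, seed = 60 + rep)
    cue <- ff(sample.int(6, 5, replace = TRUE) - 1L, 6)
    p0 <- recognition_params(sigma = 0)
    r <- amr_retrieve(a, cue, p0, seed = rep)
    rec <- amr_recognize(a, cue, p0)
    if (rec$accepted) expect_identical(r$f$levels, cue$levels)
    else expect_true(all(is.na(r$f$levels)))
  }
  # single-function AMR returns the cue for any sigma
  one <- amr_from(list(c(2, 0, 1)), 3, 3, times = 4L)
  for (s in c(0, 0.5, 3)) {
    r <- amr_retrieve(one, ff(c(2, 0, 1), 3),
                      recognition_params(sigma = s), seed = 9L)
    expect_identical(r$f$levels, c(2L, 0L, 1L))
  }
})

test_that("retrieval with a fixed seed is reproducible and seed-local", {
  a <- random_amr(4, 5, reg = 20, seed = 71)
  cue <- ff(c(1, 2, 3, 0), 5)
  p <- recognition_params(sigma = 2)
  r1 <- amr_retrieve(a, cue, p, seed = 123)
  set.seed(42); x_before <- runif(1)
  r2 <- amr_retrieve(a, cue, p, seed = 123)
  expect_identical(r1$f$levels, r2$f$levels)
  # the global RNG stream is untouched by package calls
  set.seed(42); invisible(amr_retrieve(a, cue, p, seed = 7))
  expect_equal(runif(1), x_before)
})

test_that("partial cues are completed by sampling the column prior", {
  a <- amr_from(list(c(0, 0), c(0, 1)), 2, 2, times = 3L)
  draws <- vapply(1:200, function(s)
    amr_retrieve(a, ff(c(0, NA), 2), recognition_params(sigma = 0),
                 seed = s)$f$levels[2], integer(1))
  expect_true(all(draws %in% c(0L, 1L)))
  expect_gt(length(unique(draws)), 1L)  # both values of the 50/50 prior seen
})

test_that("retrieval sampling follows the cue-modulated distribution", {
  # column Psi = (0.75, 0.25), cue at level 0, huge sigma (zeta ~ flat):
  # empirical frequency of level 0 must match 0.75 within 3 s.e.
  a <- amr_from(list(c(0), c(0), c(0), c(1)), 1, 2)
  n <- 4000L
  hits <- vapply(seq_len(n), function(s)
    amr_retrieve(a, ff(0, 2), recognition_params(sigma = 1e6),
                 seed = s)$f$levels[1], integer(1))
  phat <- mean(hits == 0L)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(phat - 0.75), 3 * se)
})

test_that("serialization round-trips bit-exactly", {
  a <- random_amr(6, 8, reg = 25, seed = 81)
  a$label <- "n~"
  prefix <- file.path(withr::local_tempdir(), "reg")
  amr_save(a, prefix)
  b <- amr_load(prefix)
  expect_identical(b$weights, a$weights)
  expect_identical(b$label, a$label)
})
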