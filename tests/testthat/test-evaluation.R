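test_that("greedy tokenization prefers multi-character phones", {
  expect_equal(phone_tokenize("tr(abaxo"),
               c("t", "r(", "a", "b", "a", "x", "o"))
  expect_equal(phone_tokenize("tSan~ar"), c("tS", "a", "n~", "a", "r"))
  expect_equal(phone_tokenize(""), character(0))
  expect_equal(phone_tokenize("a e i"), c("a", "e", "i"))  # spaces skipped
  expect_error(phone_tokenize("aqe"), "position 2")
})

test_that("the worked-example strings tokenize to the printed lengths", {
  s <- table5_strings()
  expect_length(phone_tokenize(s$transcription), 27)
  expect_length(phone_tokenize(s$network), 225)
  expect_length(phone_tokenize(s$memory), 178)
  expect_length(phone_tokenize(s$simplified_network), 41)
  expect_length(phone_tokenize(s$simplified_memory), 37)
})

test_that("the DP edit distance agrees with the recursive oracle", {
  syms <- c("a", "b", "c")
  # exhaustive over all pairs of strings of length <= 3
  short <- unlist(lapply(0:3, function(L)
    if (L == 0) list(character(0))
    else apply(as.matrix(expand.grid(rep(list(syms), L))), 1L,
               as.character, simplify = FALSE)), recursive = FALSE)
  for (a in short) for (b in short)
    expect_equal(phone_levenshtein(a, b), lev_oracle(a, b))
  # seeded sample at lengths 4-5 (the naive oracle is exponential)
  set.seed(17)
  for (k in 1:60) {
    a <- sample(syms, sample(4:5, 1), replace = TRUE)
    b <- sample(syms, sample(4:5, 1), replace = TRUE)
    expect_equal(phone_levenshtein(a, b), lev_oracle(a, b))
  }
})

test_that("edit distance is a metric on token strings", {
  set.seed(23)
  strs <- replicate(12, sample(c("a", "b", "c"), sample(0:6, 1),
                               replace = TRUE), simplify = FALSE)
  for (a in strs) for (b in strs) {
    d <- phone_levenshtein(a, b)
    expect_equal(d, phone_levenshtein(b, a))
    expect_equal(d == 0, identical(as.character(a), as.character(b)))
  }
  for (k in 1:40) {
    i <- sample(12, 3, replace = TRUE)
    expect_lte(phone_levenshtein(strs[[i[1]]], strs[[i[3]]]),
               phone_levenshtein(strs[[i[1]]], strs[[i[2]]]) +
                 phone_levenshtein(strs[[i[2]]], strs[[i[3]]]))
  }
})

test_that("fer normalizes distance by distance plus reference length", {
  ref <- phone_tokenize("tr(abaxo")
  expect_equal(fer(ref, ref), 0)
  expect_equal(fer(c("p", "p"), ref), 7 / (7 + 7))  # no token in common
  expect_error(fer(ref, character(0)), "non-empty")
  # d = 199, L = 27 from the worked example
  expect_equal(199 / 226, 0.8805, tolerance = 1e-4)
  set.seed(3)
  for (k in 1:20) {
    hyp <- sample(mexbet_phones(), sample(0:10, 1), replace = TRUE)
    f <- fer(hyp, ref)
    expect_true(f >= 0 && f < 1)
    expect_equal(f == 0, phone_levenshtein(hyp, ref) == 0L)
  }
})

test_that("register metrics honour the all-rejected conventions", {
  m <- register_metrics(tp = 0, fp = 0, fn = 10, tn = 90)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0)
  m2 <- register_metrics(tp = 8, fp = 2, fn = 2, tn = 88)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 0.8)
  # system level: tn = 0 makes accuracy coincide with recall
  m3 <- register_metrics(tp = 6, fp = 3, fn = 4, tn = 0)
  expect_equal(m3$accuracy, 6 / 13)
  z <- register_metrics(0, 0, 0, 0)
  expect_true(z$degenerate)
  expect_equal(c(z$precision, z$recall), c(1, 0))
  expect_error(register_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("bigram fitting counts unigrams and conditionals", {
  m1 <- fit_bigram(list(c("a", "a")))
  expect_equal(unname(m1$p_uni["a"]), 1)
  expect_equal(unname(m1$p_cond["a", "a"]), 1)

  m2 <- fit_bigram(list(c("a", "b"), c("a", "b")))
  expect_equal(unname(m2$p_cond["a", "b"]), 1)
  expect_equal(unname(m2$p_uni), c(0.5, 0.5))

  set.seed(7)
  corpus <- replicate(20, sample(c("x", "y", "z"), 8, replace = TRUE),
                      simplify = FALSE)
  m3 <- fit_bigram(corpus)
  expect_equal(sum(m3$p_uni), 1)
  expect_true(all(abs(rowSums(m3$p_cond) - 1) < 1e-9))
  expect_error(fit_bigram(list()), "corpus")
})

test_that("bigram simplification keeps contextually supported phones", {
  # uniform independence: p(b|a,c) = p(b) everywhere, strict > never holds
  flat <- fit_bigram(list(c("a", "b"), c("b", "a"),
                          c("a", "a"), c("b", "b")))
  expect_equal(simplify_phones(c("a", "b", "a", "b"), flat), "a")

  # hand-built alternating model: input (x, x, y) -> (x, y)
  model <- structure(list(
    phones = c("x", "y"),
    p_uni = c(x = 0.5, y = 0.5),
    p_cond = matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2, byrow = TRUE,
                    dimnames = list(c("x", "y"), c("x", "y"))),
    eps = 1e-12), class = "bigram_model")
  expect_equal(simplify_phones(c("x", "x", "y"), model), c("x", "y"))

  # filter property: never longer than the input, first token kept
  set.seed(13)
  corpus <- replicate(30, sample(c("x", "y", "z"), 10, replace = TRUE),
                      simplify = FALSE)
  m <- fit_bigram(corpus)
  for (k in 1:15) {
    s <- sample(c("x", "y", "z"), sample(1:12, 1), replace = TRUE)
    out <- simplify_phones(s, m)
    expect_lte(length(out), length(s))
    expect_equal(out[1], s[1])
  }
  expect_error(simplify_phones(c("x", "q"), m), "not covered")
})
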