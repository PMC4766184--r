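test_that("predictable sequences hit the designed balance and repeat count", {
  for (k in c(0L, 1L, 3L, 10L, 58L)) {
    s <- make_predictable(60, k, seed = 100 + k)
    expect_s3_class(s, "env_seq")
    expect_length(s, 60)
    expect_equal(sum(s == "N"), 30)
    expect_equal(sum(s == "A"), 30)
    expect_equal(count_equal_pairs(as.character(s)), k)
    # designed repeat count recovered exactly from the lag-1 diagnostic
    expect_equal(repeat_probability(s, 1) * 59, k)
  }
  # the experimental design: repeat probability 3/59, printed as 0.05
  expect_equal(repeat_probability(make_predictable(60, 3, seed = 1), 1),
               3 / 59)
  # zero repeats force strict alternation
  s0 <- make_predictable(60, 0, seed = 7)
  expect_true(all(s0[-1] != s0[-60]))
})

test_that("predictable construction is seeded and rejects infeasible designs", {
  expect_identical(as.character(make_predictable(60, 3, seed = 42)),
                   as.character(make_predictable(60, 3, seed = 42)))
  expect_error(make_predictable(59, 3), "even")
  expect_error(make_predictable(60, 59), "infeasible")
  expect_error(make_predictable(60, -1), "infeasible")
})

test_that("length-6 predictable sequences agree with exhaustive enumeration", {
  balanced <- enumerate_balanced(6)
  expect_equal(nrow(balanced), 20)
  with_one_pair <- balanced[apply(balanced, 1, count_equal_pairs) == 1, ,
                            drop = FALSE]
  keys <- apply(with_one_pair, 1, paste, collapse = "")
  for (seed in 1:5) {
    s <- make_predictable(6, 1, seed = seed)
    expect_true(paste(as.character(s), collapse = "") %in% keys)
  }
})

test_that("unpredictable sequences hit lag-1 (and lag-2) repeat targets", {
  u <- make_unpredictable(60, 27, seed = 3)
  expect_equal(sum(u == "N"), 30)
  expect_equal(repeat_probability(u, 1), 27 / 59)
  # with the distance-2 target of the archived sequences #11/#19
  u2 <- make_unpredictable(60, 27, 30, seed = 4)
  expect_equal(repeat_probability(u2, 1), 27 / 59)
  expect_equal(repeat_probability(u2, 2), 30 / 58)
  expect_identical(as.character(make_unpredictable(60, 27, 30, seed = 4)),
                   as.character(u2))
})

test_that("unpredictable search reports infeasible targets", {
  # a balanced length-4 sequence has at most 2 equal adjacent pairs
  expect_error(make_unpredictable(4, 3), "infeasible")
  # feasible lag-1 but impossible joint target (alternation forces all
  # distance-2 pairs equal): budget-exhaustion error reports best counts
  expect_error(make_unpredictable(6, 0, 0, seed = 1, budget = 2000),
               "best sequence")
})

test_that("constant sequences are one anoxia block then one normoxia block", {
  s <- make_constant(60)
  expect_equal(as.character(s), rep(c("A", "N"), each = 30))
  expect_equal(as.character(make_constant(2)), c("A", "N"))
  expect_equal(repeat_probability(s, 1), 58 / 59)  # single switch
})

test_that("markov sequences obey the switching probability", {
  expect_equal(as.character(make_markov(10, 1, init_env = "N")),
               rep(c("N", "A"), 5))
  expect_equal(as.character(make_markov(10, 0, init_env = "A")),
               rep("A", 10))
  n <- 1e5
  s <- make_markov(n, 0.95, seed = 5)
  frac <- mean(s[-1] != s[-n])
  se <- sqrt(0.95 * 0.05 / (n - 1))
  expect_lt(abs(frac - 0.95), 3 * se)
  expect_identical(as.character(make_markov(50, 0.5, seed = 9)),
                   as.character(make_markov(50, 0.5, seed = 9)))
})

test_that("markov lag-1 autocorrelation converges to 1 - 2 * p_switch", {
  for (sigma in c(0.3, 0.95)) {
    s <- make_markov(1e5, sigma, seed = 11)
    r1 <- env_autocorrelation(s, 1)[2]
    expect_lt(abs(r1 - (1 - 2 * sigma)), 0.01)
  }
})

test_that("repeat_probability counts shared environments at a lag", {
  alt <- make_predictable(60, 0, seed = 1)
  expect_equal(repeat_probability(alt, 1), 0)
  expect_equal(repeat_probability(alt, 2), 1)
  expect_error(repeat_probability(alt, 0), "lag")
  expect_error(repeat_probability(alt, 60), "lag")
})

test_that("transition frequencies count adjacent environment pairs", {
  alt <- env_seq(rep(c("N", "A"), 30))
  p <- transition_frequencies(alt)
  expect_equal(sum(p), 1)
  expect_equal(p["N", "A"], 30 / 59)
  expect_equal(p["A", "N"], 29 / 59)
  expect_equal(p["N", "N"] + p["A", "A"], 0)
  expect_equal(transition_frequencies(env_seq(c("A", "A")))["A", "A"], 1)
  pc <- transition_frequencies(make_constant(60))
  expect_equal(pc["A", "A"], 29 / 59)
  expect_equal(pc["A", "N"], 1 / 59)
  expect_equal(pc["N", "N"], 29 / 59)
})

test_that("row sums of transition frequencies match marginal label counts", {
  for (seed in 1:5) {
    s <- make_markov(40, 0.4, seed = seed)
    p <- transition_frequencies(s)
    x <- as.character(s)
    expect_equal(p["N", "A"] + p["N", "N"], mean(x[-40] == "N"))
  }
})

test_that("stationary transition frequencies close the markov environment", {
  expect_equal(unclass(stationary_transition_frequencies(0.5)),
               matrix(0.25, 2, 2), ignore_attr = TRUE)
  p <- stationary_transition_frequencies(0.95)
  expect_equal(p["N", "A"], 0.475)
  expect_equal(p["N", "N"], 0.025)
  p1 <- stationary_transition_frequencies(1)
  expect_equal(p1["A", "N"], 0.5)
  expect_equal(p1["A", "A"], 0)
})

test_that("autocorrelation matches the biased mean-centered estimator", {
  alt <- env_seq(rep(c("N", "A"), 30))
  r <- env_autocorrelation(alt, 2)
  expect_equal(r[1], 1)
  expect_equal(r[2], -59 / 60)  # balanced alternation closed form
  expect_error(env_autocorrelation(env_seq(rep("A", 10)), 2), "constant")
})

test_that("cumulative periodogram concentrates alternation power at Nyquist", {
  alt <- env_seq(rep(c("N", "A"), 30))
  cp <- cumulative_periodogram(alt)
  expect_equal(cp$frequency, (1:30) / 60)
  expect_equal(cp$cumulative[30], 1)
  expect_true(all(cp$cumulative[1:29] < 1e-10))
})

test_that("cumulative periodogram of white noise tracks the diagonal", {
  set.seed(21)
  x <- env_seq(sample(c("N", "A"), 512, replace = TRUE))
  cp <- cumulative_periodogram(x)
  m <- length(cp$frequency)
  # Kolmogorov-Smirnov 95% band around the uniform diagonal
  dev <- max(abs(cp$cumulative - seq_len(m) / m))
  expect_lt(dev, 1.36 / sqrt(m))
  expect_equal(cp$cumulative[m], 1)
})

test_that("sequence files round-trip through the one-label-per-line format", {
  s <- make_unpredictable(60, 27, seed = 8)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write_env_seq(s, f)
  s2 <- read_env_seq(f)
  expect_equal(as.character(s2), as.character(s))
  df <- as.data.frame(s)
  expect_equal(df$generation, 1:60)
  expect_equal(df$env, as.character(s))
})

test_that("env_seq validates labels and encoding is fixed", {
  expect_error(env_seq(c("N", "X")), "labels")
  expect_error(env_seq("N"), "at least 2")
  expect_equal(env_encode(c("N", "A", "A")), c(0L, 1L, 1L))
})
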