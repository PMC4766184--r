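# small hand-built assay tables

make_records <- function(regime, population, block, maternal_env,
                         offspring_env, value, replicate = 1,
                         trait = "growth_rate") {
  data.frame(regime = regime, population = population, block = block,
             replicate = replicate, maternal_env = maternal_env,
             offspring_env = offspring_env, trait = trait, value = value)
}

test_that("growth rate is the L1 count over the seeded larvae", {
  expect_equal(growth_rate_from_counts(5000), 1)
  expect_equal(growth_rate_from_counts(10000), 2)
  expect_equal(growth_rate_from_counts(0), 0)
  expect_equal(growth_rate_from_counts(300, seeded = 100), 3)
  expect_error(growth_rate_from_counts(-1), "nonnegative")
})

test_that("ancestral block means average within block and treatment", {
  rec <- rbind(
    make_records("ancestor", "anc", "b1", "N", "A", c(1, 3), replicate = 1:2),
    make_records("ancestor", "anc", "b2", "N", "A", 5))
  m <- ancestral_block_means(rec)
  expect_equal(m$anc_mean[m$block == "b1"], 2)
  expect_equal(m$anc_mean[m$block == "b2"], 5)
  expect_error(ancestral_block_means(make_records("predictable", "P1", "b1",
                                                  "N", "A", 1)),
               "no ancestor")
})

test_that("ln relative fitness is taken against the matching block cell", {
  anc <- ancestral_block_means(
    make_records("ancestor", "anc", "b1", "N", "A", 1.0))
  ev_equal <- make_records("predictable", "P1", "b1", "N", "A", 1.0)
  expect_equal(ln_relative(ev_equal, anc)$ln_rel, 0)
  ev_e <- make_records("predictable", "P1", "b1", "N", "A", exp(1))
  expect_equal(ln_relative(ev_e, anc)$ln_rel, 1)
  ev_2 <- make_records("predictable", "P1", "b1", "N", "A", 2)
  expect_equal(ln_relative(ev_2, anc)$ln_rel, log(2))
  # missing ancestor cell is named in the error
  ev_bad <- make_records("predictable", "P1", "b2", "N", "A", 2)
  expect_error(ln_relative(ev_bad, anc), "block 'b2'")
  ev_zero <- make_records("predictable", "P1", "b1", "N", "A", 0)
  expect_error(ln_relative(ev_zero, anc), "positive")
})

test_that("transition estimates summarize blocks with a seeded bootstrap", {
  rec <- rbind(
    make_records("predictable", "P1", "b1", "N", "A", c(0.1, 0.1),
                 replicate = 1:2),
    make_records("predictable", "P1", "b2", "N", "A", c(0.3, 0.3),
                 replicate = 1:2))
  rec$ln_rel <- rec$value
  est <- population_transition_estimates(rec, n_boot = 500, seed = 1)
  expect_equal(est$estimate, 0.2)
  expect_equal(est$n_blocks, 2)
  expect_equal(est$n, 4)
  # identical block means: zero bootstrap spread
  same <- rec; same$ln_rel <- 0.25
  est0 <- population_transition_estimates(same, n_boot = 200, seed = 1)
  expect_equal(est0$se, 0)
  # a single block cannot support a standard error
  one <- make_records("predictable", "P1", "b1", "N", "A", 0.5)
  one$ln_rel <- one$value
  est1 <- population_transition_estimates(one, n_boot = 200, seed = 1)
  expect_true(is.na(est1$se))
  # seeded: reproducible
  expect_identical(population_transition_estimates(rec, n_boot = 500, seed = 2),
                   population_transition_estimates(rec, n_boot = 500, seed = 2))
})

test_that("the fitted pipeline on ancestor-identical data finds no change", {
  blocks <- sprintf("b%d", 1:4)
  grid <- expand.grid(block = blocks, maternal_env = c("N", "A"),
                      offspring_env = c("N", "A"),
                      stringsAsFactors = FALSE)
  anc_val <- ifelse(grid$offspring_env == "A", 0.5, 1.5)
  rec <- rbind(
    make_records("ancestor", "anc", grid$block, grid$maternal_env,
                 grid$offspring_env, anc_val),
    make_records("predictable", "P1", grid$block, grid$maternal_env,
                 grid$offspring_env, anc_val))
  fit <- fit_relative_fitness(rec, n_boot = 200, seed = 3)
  expect_s3_class(fit, "relfit")
  expect_equal(fit$estimates$estimate, rep(0, 4))
  expect_equal(unname(coef(fit)), rep(0, 4))
  # ln G = 0, G = 1 over any weighting of the measured transitions
  w <- matrix(exp(fit$estimates$estimate), 2, 2)
  expect_equal(geometric_mean_fitness_assay(w, stationary_transition_frequencies(0.5)), 1)
  s <- summary(fit)
  expect_equal(s$by_regime$mean_estimate, rep(0, 4))
})

test_that("zero growth rates are excluded from the ln-ratio analysis", {
  rec <- rbind(
    make_records("ancestor", "anc", "b1", "N", "A", 1),
    make_records("predictable", "P1", "b1", "N", "A", c(2, 0), replicate = 1:2))
  expect_message(fit <- fit_relative_fitness(rec, n_boot = 0, seed = 1),
                 "1 zero-valued")
  expect_equal(fit$n_excluded_zero, 1)
  expect_equal(fit$estimates$estimate, log(2))
})

test_that("assay geometric mean fitness weights experienced transitions", {
  half <- stationary_transition_frequencies(1)  # 1/2 on each off-diagonal
  w_recip <- matrix(c(1, 0.5, 2, 1), 2, 2)      # w(N,A) = 2, w(A,N) = 0.5
  expect_equal(geometric_mean_fitness_assay(w_recip, half), 1)
  w_gain <- matrix(c(1, 1, 2.63, 1), 2, 2)
  expect_equal(geometric_mean_fitness_assay(w_gain, half), sqrt(2.63))
  expect_equal(geometric_mean_fitness_assay(matrix(1, 2, 2),
                                            stationary_transition_frequencies(0.3)), 1)
  expect_error(geometric_mean_fitness_assay(matrix(0, 2, 2), half), "> 0")
})

test_that("expected adaptation is the Lth root of the transition product", {
  alt12 <- env_seq(rep(c("N", "A"), 6))
  ones <- matrix(1, 2, 2)
  expect_equal(as.numeric(expected_adaptation(ones, alt12)), 1)
  w <- matrix(c(1, 1, 1.2, 1), 2, 2,
              dimnames = list(c("N", "A"), c("N", "A")))  # w(N,A) = 1.2
  a <- expected_adaptation(w, alt12)
  expect_equal(as.numeric(a), 1.2^(6 / 12))
  expect_equal(attr(a, "product"), 1.2^6)
  # a uniform sequence uses only its diagonal transition
  wd <- ones; wd[1, 1] <- 1.1  # w(N, N)
  expect_equal(as.numeric(expected_adaptation(wd, env_seq(rep("N", 12)))), 1.1)
  # prepend boundary duplicates the first environment
  seq_na <- env_seq(c("N", "A", "A", "N"))
  ap <- expected_adaptation(w, seq_na, boundary = "prepend")
  expect_equal(as.numeric(ap), (1 * 1.2 * 1 * 1)^(1 / 4))
})

test_that("cyclic expected adaptation is rotation invariant", {
  set.seed(91)
  w <- matrix(exp(rnorm(4, 0, 0.3)), 2, 2)
  for (i in 1:10) {
    x <- sample(c("N", "A"), 12, replace = TRUE)
    rot <- c(x[-1], x[1])
    expect_equal(as.numeric(expected_adaptation(w, env_seq(x))),
                 as.numeric(expected_adaptation(w, env_seq(rot))))
  }
})

test_that("raising a transition's relative fitness never lowers adaptation", {
  set.seed(92)
  w <- matrix(exp(rnorm(4, 0, 0.3)), 2, 2)
  w_up <- w; w_up[1, 2] <- w[1, 2] * 1.5  # raise w(N, A)
  tab <- enumerate_adaptation(w, length = 8)
  tab_up <- enumerate_adaptation(w_up, length = 8)
  expect_true(all(tab_up$a_s >= tab$a_s - 1e-12))
  uses_na <- grepl("NA", tab$sequence, fixed = TRUE) |
    (substr(tab$sequence, 8, 8) == "N" & substr(tab$sequence, 1, 1) == "A")
  expect_true(all(tab_up$a_s[uses_na] > tab$a_s[uses_na]))
})

test_that("adaptation enumeration covers every binary sequence", {
  w <- matrix(c(1.1, 0.9, 1.3, 0.8), 2, 2)
  tab <- enumerate_adaptation(w, length = 12)
  expect_equal(nrow(tab), 4096)
  expect_equal(anyDuplicated(tab$sequence), 0)
  expect_equal(sort(unique(tab$normoxia_freq)), (0:12) / 12)
  expect_equal(nrow(enumerate_adaptation(w, length = 1)), 2)
  expect_equal(enumerate_adaptation(matrix(1, 2, 2), length = 5)$a_s,
               rep(1, 32))
  # rows agree with the scalar evaluator
  i <- 1234
  s <- env_seq(strsplit(tab$sequence[i], "")[[1]])
  expect_equal(tab$a_s[i], as.numeric(expected_adaptation(w, s)))
  expect_error(enumerate_adaptation(w, length = 21), "\\[1, 20\\]")
})
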