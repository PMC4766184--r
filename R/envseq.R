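## Environmental sequences: ordered normoxia ("N") / anoxia ("A") labels over
## generations. Canonical integer encoding used throughout: NORMOXIA = 0,
## ANOXIA = 1.

#' Environment labels
#'
#' The two hatching environments are written `"N"` (normoxia) and `"A"`
#' (anoxia). The canonical integer encoding, used by all diagnostics, is
#' NORMOXIA = 0, ANOXIA = 1.
#'
#' @format A character vector of the two valid labels, `c("N", "A")`.
#' @export
env_levels <- c("N", "A")

#' Construct an environmental sequence
#'
#' An `env_seq` is an ordered vector of hatching-environment labels, one per
#' generation, describing the selective environment a population experiences.
#'
#' @param labels Character vector of `"N"`/`"A"` labels (length >= 2).
#' @param name Optional free-text name for the sequence.
#' @param seed Optional integer seed recorded as metadata (the seed the
#'   sequence was generated from, if any).
#' @return An object of class `env_seq`: a character vector of labels with
#'   `name` and `seed` attributes.
#' @examples
#' env_seq(c("N", "A", "N", "A"))
#' @export
env_seq <- function(labels, name = NULL, seed = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("an environmental sequence needs at least 2 generations")
  if (!all(labels %in% env_levels))
    stop("labels must be 'N' (normoxia) or 'A' (anoxia)")
  structure(labels, name = name, seed = seed, class = "env_seq")
}

#' @export
print.env_seq <- function(x, ...) {
  nm <- attr(x, "name")
  cat("Environmental sequence", if (!is.null(nm)) paste0("'", nm, "'"),
      "of", length(x), "generations\n")
  cat(" ", paste(unclass(x), collapse = ""), "\n")
  cat("  N:", sum(x == "N"), " A:", sum(x == "A"),
      " lag-1 repeat prob:", signif(repeat_probability(x, 1L), 3), "\n")
  invisible(x)
}

#' @export
`[.env_seq` <- function(x, i, ...) {
  out <- unclass(x)[i]
  if (length(out) >= 2L) env_seq(out, name = attr(x, "name")) else out
}

#' Encode environment labels as integers
#'
#' @param env Character vector of `"N"`/`"A"` labels (an [env_seq] or plain
#'   character vector).
#' @return Integer vector with NORMOXIA = 0, ANOXIA = 1.
#' @export
env_encode <- function(env) {
  env <- as.character(env)
  if (!all(env %in% env_levels)) stop("labels must be 'N' or 'A'")
  ifelse(env == "A", 1L, 0L)
}

## inverse of env_encode
env_decode <- function(code) env_levels[code + 1L]

## equal-label pair count at distance `lag`
.pair_count <- function(labels, lag) {
  n <- length(labels)
  sum(labels[seq_len(n - lag)] == labels[seq_len(n - lag) + lag])
}

#' Design a predictable (negatively correlated) sequence
#'
#' Builds a balanced sequence (`n_gen/2` generations of each environment)
#' with exactly `n_repeats` adjacent mother-offspring pairs sharing the same
#' environment. The experimental "predictable" regime used 60 generations
#' with 3 repeats, i.e. a lag-1 repeat probability of 3/59.
#'
#' The construction works on runs: a balanced sequence with `k` equal
#' adjacent pairs has exactly `n_gen - k` maximal runs; run lengths are
#' randomly apportioned given the seed.
#'
#' @param n_gen Even number of generations.
#' @param n_repeats Number of equal adjacent pairs, in `[0, n_gen - 2]`
#'   (a balanced sequence contains both labels, so at least two runs).
#' @param seed Optional integer seed; identical seeds give identical
#'   sequences.
#' @return An [env_seq].
#' @examples
#' s <- make_predictable(60, 3, seed = 1)
#' repeat_probability(s, 1) # 3/59
#' @export
make_predictable <- function(n_gen = 60L, n_repeats = 3L, seed = NULL) {
  n_gen <- as.integer(n_gen); n_repeats <- as.integer(n_repeats)
  if (n_gen < 2L || n_gen %% 2L != 0L)
    stop("n_gen must be even and >= 2 (balanced design)")
  if (n_repeats < 0L || n_repeats > n_gen - 2L)
    stop(sprintf(paste0("infeasible design: a balanced sequence of length %d",
                        " admits between 0 and %d equal adjacent pairs",
                        " (requested %d)"), n_gen, n_gen - 2L, n_repeats))
  half <- n_gen %/% 2L
  n_runs <- n_gen - n_repeats  # >= 2
  labels <- with_seed(seed, {
    start <- sample(env_levels, 1L)
    other <- setdiff(env_levels, start)
    k_start <- (n_runs + 1L) %/% 2L   # runs of the starting label
    k_other <- n_runs %/% 2L
    # random composition of `half` into k parts, each >= 1
    rand_lengths <- function(k, total) {
      extra <- total - k
      1L + tabulate(sample.int(k, extra, replace = TRUE), nbins = k)
    }
    len_s <- rand_lengths(k_start, half)
    len_o <- rand_lengths(k_other, half)
    runs_lab <- character(n_runs)
    runs_lab[seq(1L, n_runs, by = 2L)] <- start
    if (n_runs > 1L) runs_lab[seq(2L, n_runs, by = 2L)] <- other
    runs_len <- integer(n_runs)
    runs_len[seq(1L, n_runs, by = 2L)] <- len_s
    if (n_runs > 1L) runs_len[seq(2L, n_runs, by = 2L)] <- len_o
    rep(runs_lab, runs_len)
  })
  env_seq(labels, name = sprintf("predictable(%d,%d)", n_gen, n_repeats),
          seed = seed)
}

#' Design an unpredictable (uncorrelated) sequence
#'
#' Searches for a balanced sequence whose adjacent (mother-offspring,
#' distance 1) equal-pair count hits `lag1_repeats` exactly and, when given,
#' whose distance-2 (grandmother-offspring) equal-pair count hits
#' `lag2_repeats` exactly. The experimental "unpredictable" regimes used 60
#' generations with 27 adjacent repeats (repeat probability 27/59, printed
#' 0.46) and distance-2 repeat probabilities of 0.52, 0.34 or 0.62.
#'
#' Note on terminology: the experimental description counts mother-offspring
#' comparisons as "lag two" and grandmother-offspring comparisons as "lag
#' three" (one-based over the two or three generations involved); here lags
#' are zero-based distances, so those are `lag = 1` and `lag = 2`.
#'
#' The search is a seeded hill climb over label swaps that preserve balance,
#' with plateau moves, and a bounded proposal budget.
#'
#' @param n_gen Even number of generations.
#' @param lag1_repeats Target number of equal adjacent pairs (distance 1).
#' @param lag2_repeats Optional target number of equal distance-2 pairs.
#' @param seed Optional integer seed; identical seeds give identical
#'   sequences.
#' @param budget Maximum number of swap proposals before giving up.
#' @return An [env_seq].
#' @examples
#' s <- make_unpredictable(60, 27, seed = 1)
#' repeat_probability(s, 1) # 27/59
#' @export
make_unpredictable <- function(n_gen = 60L, lag1_repeats = 27L,
                               lag2_repeats = NULL, seed = NULL,
                               budget = 1e5) {
  n_gen <- as.integer(n_gen); lag1_repeats <- as.integer(lag1_repeats)
  if (n_gen < 2L || n_gen %% 2L != 0L)
    stop("n_gen must be even and >= 2 (balanced design)")
  if (lag1_repeats < 0L || lag1_repeats > n_gen - 2L)
    stop(sprintf(paste0("infeasible design: a balanced sequence of length %d",
                        " admits between 0 and %d equal adjacent pairs",
                        " (requested %d)"), n_gen, n_gen - 2L, lag1_repeats))
  half <- n_gen %/% 2L
  objective <- function(x) {
    d <- abs(.pair_count(x, 1L) - lag1_repeats)
    if (!is.null(lag2_repeats))
      d <- d + abs(.pair_count(x, 2L) - lag2_repeats)
    d
  }
  res <- with_seed(seed, {
    x <- sample(rep(env_levels, each = half))
    obj <- objective(x)
    best <- x; best_obj <- obj
    it <- 0L
    while (obj > 0L && it < budget) {
      it <- it + 1L
      i <- sample(which(x == "N"), 1L)
      j <- sample(which(x == "A"), 1L)
      cand <- x
      cand[c(i, j)] <- cand[c(j, i)]
      cand_obj <- objective(cand)
      if (cand_obj <= obj) {  # accept downhill and plateau moves
        x <- cand; obj <- cand_obj
        if (obj < best_obj) { best <- x; best_obj <- obj }
      }
    }
    list(x = x, obj = obj, best = best, best_obj = best_obj)
  })
  if (res$obj > 0L) {
    got1 <- .pair_count(res$best, 1L)
    msg <- sprintf(paste0("search budget (%g proposals) exhausted: best",
                          " sequence found has %d adjacent repeats",
                          " (target %d)"), budget, got1, lag1_repeats)
    if (!is.null(lag2_repeats))
      msg <- paste0(msg, sprintf(" and %d distance-2 repeats (target %d)",
                                 .pair_count(res$best, 2L), lag2_repeats))
    stop(msg)
  }
  env_seq(res$x,
          name = sprintf("unpredictable(%d,%d%s)", n_gen, lag1_repeats,
                         if (is.null(lag2_repeats)) "" else
                           paste0(",", lag2_repeats)),
          seed = seed)
}

#' Design a constant (positively correlated) sequence
#'
#' The experimental "constant" regime: the first half of the generations in
#' anoxia, the second half in normoxia.
#'
#' @param n_gen Even number of generations.
#' @return An [env_seq].
#' @examples
#' make_constant(60)
#' @export
make_constant <- function(n_gen = 60L) {
  n_gen <- as.integer(n_gen)
  if (n_gen < 2L || n_gen %% 2L != 0L) stop("n_gen must be even and >= 2")
  half <- n_gen %/% 2L
  env_seq(rep(c("A", "N"), each = half),
          name = sprintf("constant(%d)", n_gen))
}

#' Generate a two-state Markov environmental sequence
#'
#' Each generation the environment switches with probability `p_switch` and
#' stays the same with probability `1 - p_switch`. `p_switch = 0.95`
#' approximates the predictable experimental regime; `p_switch = 0.55`
#' approximates the unpredictable one.
#'
#' @param n_gen Number of generations (sequence length).
#' @param p_switch Probability of switching between consecutive generations.
#' @param init_env Initial environment: `"N"`, `"A"` or `"random"`
#'   (drawn uniformly).
#' @param seed Optional integer seed.
#' @return An [env_seq].
#' @export
make_markov <- function(n_gen, p_switch, init_env = "random", seed = NULL) {
  n_gen <- as.integer(n_gen)
  if (n_gen < 2L) stop("n_gen must be >= 2")
  if (p_switch < 0 || p_switch > 1) stop("p_switch must lie in [0, 1]")
  labels <- with_seed(seed, {
    e0 <- if (identical(init_env, "random")) sample(0:1, 1L)
          else env_encode(init_env)
    switches <- as.integer(stats::runif(n_gen - 1L) < p_switch)
    env_decode(cumsum(c(e0, switches)) %% 2L)
  })
  env_seq(labels, name = sprintf("markov(%d,%g)", n_gen, p_switch),
          seed = seed)
}

#' Probability of repeating the environment at a given lag
#'
#' The fraction of generation pairs at distance `lag` sharing the same
#' label; the denominator is `length(seq) - lag`. With `lag = 1` this is the
#' probability that mothers and offspring share the hatching environment.
#'
#' @param seq An [env_seq] (or character vector of labels).
#' @param lag Distance between compared generations, `1 <= lag < length`.
#' @return A probability.
#' @export
repeat_probability <- function(seq, lag = 1L) {
  lag <- as.integer(lag)
  n <- length(seq)
  if (lag < 1L || lag >= n) stop("lag must satisfy 1 <= lag < length(seq)")
  .pair_count(as.character(seq), lag) / (n - lag)
}

#' Transition-frequency matrix
#'
#' Construct or validate the 2 x 2 matrix `p(i, j)` of frequencies of a
#' maternal hatching environment `i` followed by offspring hatching
#' environment `j`. Rows index the maternal environment, columns the
#' offspring environment, both ordered `("N", "A")`; entries are
#' nonnegative and sum to 1.
#'
#' @param p A 2 x 2 numeric matrix (maternal rows, offspring columns).
#' @return An object of class `transition_freqs`.
#' @export
transition_freqs <- function(p) {
  p <- as.matrix(p)
  if (!all(dim(p) == c(2L, 2L))) stop("p must be a 2 x 2 matrix")
  if (any(p < 0)) stop("transition frequencies must be nonnegative")
  if (abs(sum(p) - 1) > 1e-12) stop("transition frequencies must sum to 1")
  dimnames(p) <- list(maternal = env_levels, offspring = env_levels)
  structure(p, class = c("transition_freqs", "matrix"))
}

#' @export
print.transition_freqs <- function(x, ...) {
  cat("Mother-offspring environmental transition frequencies p(i, j):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Empirical transition frequencies of a sequence
#'
#' Counts the `length(seq) - 1` adjacent (mother, offspring) environment
#' pairs and divides by their number.
#'
#' @param seq An [env_seq] (or character vector of labels), length >= 2.
#' @return A [transition_freqs] matrix.
#' @examples
#' transition_frequencies(make_constant(60)) # p(A,A) = p(N,N) = 29/59
#' @export
transition_frequencies <- function(seq) {
  x <- as.character(seq)
  n <- length(x)
  if (n < 2L) stop("sequence must have length >= 2")
  from <- factor(x[-n], levels = env_levels)
  to <- factor(x[-1L], levels = env_levels)
  transition_freqs(table(from, to) / (n - 1L))
}

#' Stationary transition frequencies of the symmetric Markov environment
#'
#' Under the two-state Markov environment with switching probability
#' `p_switch`, the stationary environment frequencies are 1/2 each, so the
#' long-run transition frequencies are `p_switch / 2` off the diagonal and
#' `(1 - p_switch) / 2` on it.
#'
#' @param p_switch Switching probability in `[0, 1]`.
#' @return A [transition_freqs] matrix.
#' @export
stationary_transition_frequencies <- function(p_switch) {
  if (p_switch < 0 || p_switch > 1) stop("p_switch must lie in [0, 1]")
  same <- (1 - p_switch) / 2
  diff <- p_switch / 2
  transition_freqs(matrix(c(same, diff, diff, same), 2L, 2L))
}

#' Autocorrelation function of an environmental sequence
#'
#' The mean-centered, lag-0-normalized (biased) autocorrelation estimator on
#' the 0/1 encoding,
#' `r_k = sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`,
#' as computed by [stats::acf()].
#'
#' @param seq An [env_seq].
#' @param max_lag Largest lag, `< length(seq)`.
#' @return Numeric vector of correlations at lags `0:max_lag` (`r_0 = 1`).
#' @export
env_autocorrelation <- function(seq, max_lag) {
  x <- env_encode(seq)
  max_lag <- as.integer(max_lag)
  if (max_lag >= length(x)) stop("max_lag must be < length(seq)")
  if (stats::var(x) == 0)
    stop("autocorrelation is undefined for a constant-label sequence")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE,
                  type = "correlation")
  as.numeric(a$acf)
}

#' Cumulative periodogram of an environmental sequence
#'
#' Raw periodogram of the mean-centered 0/1 encoding at the Fourier
#' frequencies `j/n`, `j = 1..floor(n/2)`, cumulatively summed and
#' normalized to end at 1. No taper and no detrending beyond mean removal:
#' the diagnostic compares the spectrum qualitatively against the white
#' (diagonal) spectrum.
#'
#' @param seq An [env_seq], length >= 4.
#' @return A list with components `frequency` and `cumulative` (both of
#'   length `floor(n/2)`; `cumulative` ends at 1).
#' @export
cumulative_periodogram <- function(seq) {
  x <- env_encode(seq)
  n <- length(x)
  if (n < 4L) stop("sequence must have length >= 4")
  if (stats::var(x) == 0)
    stop("periodogram is undefined for a constant-label sequence")
  x <- x - mean(x)
  m <- n %/% 2L
  pow <- Mod(stats::fft(x)[2L:(m + 1L)])^2
  list(frequency = (1L:m) / n, cumulative = cumsum(pow) / sum(pow))
}

#' Read / write environmental sequence files
#'
#' Sequences are stored one label (`"N"`/`"A"`) per line; lines beginning
#' with `#` are comments. [write_env_seq()] records the sequence name as a
#' header comment.
#'
#' @param file Path to a sequence file.
#' @return [read_env_seq()] returns an [env_seq]; [write_env_seq()] returns
#'   its input invisibly.
#' @export
read_env_seq <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  env_seq(lines, name = basename(file))
}

#' @param seq An [env_seq] to write.
#' @rdname read_env_seq
#' @export
write_env_seq <- function(seq, file) {
  nm <- attr(seq, "name")
  header <- if (!is.null(nm)) paste0("# ", nm) else "# environmental sequence"
  writeLines(c(header, as.character(seq)), file)
  invisible(seq)
}

#' @export
as.data.frame.env_seq <- function(x, ...) {
  data.frame(generation = seq_along(x), env = as.character(x))
}
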