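## Wright-Fisher invasion simulations of maternal-effect alleles.
##
## Conventions: the environmental sequence has length n_gen + 1; env[1] is
## the founding mothers' hatching environment (generation 0), so selection
## first acts at generation 1. The maternal environment is global: all
## mothers of one generation share a single hatching environment, matching
## the experimental design, so no per-individual maternal bookkeeping is
## needed.

## Row-wise multinomial sampler via conditional binomials: `prob` is an
## R x k matrix of row-stochastic probabilities, `size` the number of
## trials per row. Vectorized over rows (one rbinom call per genotype).
rmultinom_rows <- function(prob, size) {
  r <- nrow(prob); k <- ncol(prob)
  counts <- matrix(0L, r, k)
  remaining <- rep.int(as.integer(size), r)
  rem_p <- rep.int(1, r)
  for (j in seq_len(k - 1L)) {
    pj <- ifelse(rem_p > 0, prob[, j] / rem_p, 0)
    pj <- pmin(pmax(pj, 0), 1)
    counts[, j] <- stats::rbinom(r, remaining, pj)
    remaining <- remaining - counts[, j]
    rem_p <- rem_p - prob[, j]
  }
  counts[, k] <- remaining
  counts
}

#' One generation of Wright-Fisher multinomial resampling
#'
#' Given current genotype frequencies and this generation's per-genotype
#' reproductive outputs, the next generation's counts are drawn from a
#' multinomial of size `n` with sampling probabilities proportional to
#' `freqs * fitness`; returned as frequencies (`counts / n`).
#'
#' @param freqs Genotype frequencies: a vector summing to 1, or a matrix of
#'   replicate rows each summing to 1.
#' @param fitness Per-genotype reproductive outputs (>= 0): a vector
#'   (recycled across replicates) or a matrix matching `freqs`.
#' @param n Population size (number of multinomial trials).
#' @return Frequencies after resampling, same shape as `freqs`.
#' @export
wf_step <- function(freqs, fitness, n) {
  vec <- is.null(dim(freqs))
  f <- if (vec) matrix(freqs, nrow = 1L) else as.matrix(freqs)
  w <- if (is.null(dim(fitness)))
    matrix(fitness, nrow(f), ncol(f), byrow = TRUE) else as.matrix(fitness)
  if (any(w < 0)) stop("reproductive outputs must be nonnegative")
  if (any(abs(rowSums(f) - 1) > 1e-9)) stop("frequencies must sum to 1")
  out <- f * w
  tot <- rowSums(out)
  if (any(tot == 0))
    stop("total reproductive output is zero: population extinct")
  res <- rmultinom_rows(out / tot, n) / n
  if (vec) drop(res) else res
}

## Resolve an environment argument: either an env_seq of length n_gen + 1,
## or list(p_switch =, init_env =) drawn per replicate. Returns an
## R x (n_gen + 1) character matrix. Uses the current RNG stream.
resolve_env <- function(env, n_gen, n_reps) {
  if (inherits(env, "env_seq") || is.character(env)) {
    if (length(env) != n_gen + 1L)
      stop("the environmental sequence must have length n_gen + 1 ",
           "(entry 1 is the founding mothers' environment)")
    matrix(rep(as.character(env), each = n_reps), n_reps, n_gen + 1L)
  } else if (is.list(env) && !is.null(env$p_switch)) {
    init <- if (is.null(env$init_env)) "random" else env$init_env
    e0 <- if (identical(init, "random")) sample(0:1, n_reps, replace = TRUE)
          else rep.int(env_encode(init), n_reps)
    sw <- matrix(stats::runif(n_reps * n_gen) < env$p_switch, n_reps, n_gen)
    code <- (e0 + t(apply(cbind(0L, sw), 1L, cumsum))[, -1L, drop = FALSE])
    code <- cbind(e0, code) %% 2L
    matrix(env_decode(code), n_reps, n_gen + 1L)
  } else {
    stop("env must be an env_seq of length n_gen + 1 or ",
         "list(p_switch = , init_env = )")
  }
}

#' Simulate Wright-Fisher competition among maternal-effect genotypes
#'
#' Simulates one population of census size `n` in which genotypes carrying
#' different maternal-effect strategies compete. At each generation
#' `t >= 1` a genotype's reproductive output is
#' [transition_fitness()]`(strategy, env[t - 1], env[t], pf)` - the maternal
#' environment is the population's previous-generation hatching environment
#' - and genotype frequencies are resampled with [wf_step()].
#'
#' @param strategies A (preferably named) list of [strategy()] objects.
#' @param init_freqs Initial genotype frequencies (sum 1); each genotype
#'   must round to at least one founder copy.
#' @param env Either an [env_seq] of length `n_gen + 1` (the first entry is
#'   the founding mothers' environment) or `list(p_switch =, init_env =)`
#'   for a Markov environment drawn during the run.
#' @param pf A [phenotype_fitness].
#' @param n Census population size.
#' @param n_gen Number of generations; required (and only used) when `env`
#'   is a Markov specification.
#' @param seed Optional integer seed.
#' @return A `wf_trajectory`: list with `freq` (a `(n_gen + 1) x k` matrix
#'   of genotype frequencies, rows = generations 0..n_gen), `env` (labels
#'   per generation), `mean_fitness` (population mean reproductive output
#'   at generations 1..n_gen), `strategies`, `n`.
#' @examples
#' pf <- phenotype_fitness_from_w(2.63, 0.335)
#' tr <- wf_simulate(list(NONE = strategy_none(), DME = strategy_dme()),
#'                   c(0.99, 0.01), env = list(p_switch = 0.95),
#'                   pf = pf, n = 1000, n_gen = 60, seed = 1)
#' fixation_generation(tr, "DME")
#' @export
wf_simulate <- function(strategies, init_freqs, env, pf, n = 1000L,
                        n_gen = NULL, seed = NULL) {
  stopifnot(is.list(strategies),
            all(vapply(strategies, inherits, TRUE, "me_strategy")))
  k <- length(strategies)
  if (length(init_freqs) != k || abs(sum(init_freqs) - 1) > 1e-9)
    stop("init_freqs must match strategies and sum to 1")
  if (any(round(init_freqs * n) < 1))
    stop("every genotype must round to at least one founder copy")
  if (inherits(env, "env_seq") || is.character(env)) {
    n_gen <- length(env) - 1L
  } else if (is.null(n_gen)) {
    stop("n_gen is required with a Markov environment specification")
  }
  n_gen <- as.integer(n_gen)
  gnames <- names(strategies)
  if (is.null(gnames))
    gnames <- vapply(strategies, format, character(1L))
  with_seed(seed, {
    envs <- drop(resolve_env(env, n_gen, 1L))
    freq <- matrix(NA_real_, n_gen + 1L, k,
                   dimnames = list(generation = 0:n_gen, genotype = gnames))
    # start from integer counts so frequencies are exact multiples of 1/n
    founders <- round(init_freqs * n)
    freq[1L, ] <- founders / sum(founders)
    mean_w <- numeric(n_gen)
    for (t in seq_len(n_gen)) {
      w <- vapply(strategies, transition_fitness, numeric(1L),
                  maternal_env = envs[t], offspring_env = envs[t + 1L],
                  pf = pf)
      mean_w[t] <- sum(freq[t, ] * w)
      freq[t + 1L, ] <- wf_step(freq[t, ], w, n)
    }
    structure(list(freq = freq, env = envs, mean_fitness = mean_w,
                   strategies = strategies, n = n),
              class = "wf_trajectory")
  })
}

#' @export
print.wf_trajectory <- function(x, ...) {
  n_gen <- nrow(x$freq) - 1L
  cat(sprintf("Wright-Fisher trajectory: %d genotypes, N = %d, %d generations\n",
              ncol(x$freq), x$n, n_gen))
  cat("  final frequencies:",
      paste(sprintf("%s = %.3g", colnames(x$freq), x$freq[n_gen + 1L, ]),
            collapse = ", "), "\n")
  gm <- exp(mean(log(x$mean_fitness)))
  cat(sprintf("  realized geometric mean population fitness: %.4g\n", gm))
  invisible(x)
}

#' @export
as.data.frame.wf_trajectory <- function(x, ...) {
  n_gen <- nrow(x$freq) - 1L
  k <- ncol(x$freq)
  data.frame(generation = rep(0:n_gen, k),
             env = rep(x$env, k),
             genotype = rep(colnames(x$freq), each = n_gen + 1L),
             frequency = as.vector(x$freq))
}

#' @export
plot.wf_trajectory <- function(x, ...) {
  n_gen <- nrow(x$freq) - 1L
  graphics::matplot(0:n_gen, x$freq, type = "l", lty = 1L,
                    xlab = "generation", ylab = "genotype frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(x$freq), lty = 1L,
                   col = seq_len(ncol(x$freq)), bty = "n")
  invisible(x)
}

#' First generation at which a genotype is fixed
#'
#' @param traj A `wf_trajectory` from [wf_simulate()].
#' @param genotype Genotype name or column index.
#' @return The first generation with frequency exactly 1, or `NA` if the
#'   genotype never fixes.
#' @export
fixation_generation <- function(traj, genotype) {
  stopifnot(inherits(traj, "wf_trajectory"))
  f <- traj$freq[, genotype]
  hit <- which(f == 1)
  if (length(hit)) as.integer(names(f)[hit[1L]] %||% (hit[1L] - 1L))
  else NA_integer_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicated two-genotype invasion simulations
#'
#' Fast vectorized Wright-Fisher runs of a mutant maternal-effect genotype
#' invading a resident, with all replicates advanced in parallel (one
#' binomial draw per generation). Each replicate draws its own Markov
#' environment when `env` is a `list(p_switch = )` specification.
#'
#' @param mutant The invading genotype: an [strategy()] object, or a single
#'   number for a constant reproductive output (useful for calibration
#'   against diffusion theory).
#' @param resident The resident genotype (same forms); defaults to the
#'   ancestral no-maternal-effect strategy.
#' @param env Environment specification as in [wf_simulate()].
#' @param pf A [phenotype_fitness] (may be omitted when both genotypes have
#'   constant fitness).
#' @param p0 Initial mutant frequency.
#' @param n Census population size.
#' @param n_gen Number of generations per replicate.
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @return A data frame with one row per replicate: `final_freq` (mutant
#'   frequency at generation `n_gen`) and `fixation_gen` (first generation
#'   at which the mutant fixed, `NA` if it did not).
#' @export
wf_invasion <- function(mutant, resident = strategy_none(), env, pf = NULL,
                        p0 = 0.01, n = 1000L, n_gen = 60L, n_reps = 100L,
                        seed = NULL) {
  n <- as.integer(n); n_gen <- as.integer(n_gen)
  n_reps <- as.integer(n_reps)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (round(p0 * n) < 1) stop("p0 must round to at least one founder copy")
  fit_fun <- function(g) {
    if (inherits(g, "me_strategy")) {
      if (is.null(pf)) stop("pf is required for maternal-effect strategies")
      function(m_env, o_env) transition_fitness(g, m_env, o_env, pf)
    } else {
      w0 <- as.numeric(g)
      function(m_env, o_env) rep.int(w0, length(o_env))
    }
  }
  w_mut <- fit_fun(mutant); w_res <- fit_fun(resident)
  # a fixed sequence is shared by all replicates; only a Markov environment
  # needs per-replicate realizations
  env_fixed <- inherits(env, "env_seq") || is.character(env)
  if (env_fixed && length(env) != n_gen + 1L)
    stop("the environmental sequence must have length n_gen + 1")
  with_seed(seed, {
    envs <- if (env_fixed) NULL else resolve_env(env, n_gen, n_reps)
    env_vec <- if (env_fixed) as.character(env) else NULL
    p <- rep.int(round(p0 * n) / n, n_reps)
    fix_gen <- rep.int(NA_integer_, n_reps)
    for (t in seq_len(n_gen)) {
      active <- p > 0 & p < 1
      if (any(active)) {
        if (env_fixed) {
          m_env <- env_vec[t]; o_env <- env_vec[t + 1L]
        } else {
          m_env <- envs[active, t]; o_env <- envs[active, t + 1L]
        }
        wm <- w_mut(m_env, o_env); wr <- w_res(m_env, o_env)
        num <- p[active] * wm
        tot <- num + (1 - p[active]) * wr
        if (any(tot == 0))
          stop("total reproductive output is zero: population extinct")
        p[active] <- stats::rbinom(sum(active), n, num / tot) / n
      }
      newly <- is.na(fix_gen) & p == 1
      fix_gen[newly] <- t
    }
    data.frame(rep = seq_len(n_reps), final_freq = p, fixation_gen = fix_gen)
  })
}

#' Fixation-probability sweep over environmental switching rates
#'
#' For each of `n_draws` random phenotype-fitness draws (exponential log
#' effects with rate `gamma`, rejection-filtered so the ancestral phenotype
#' keeps the higher geometric mean fitness) and each environmental
#' switching probability in `switch_probs`, computes the geometric mean
#' fitness of the deterministic (DME) and optimal randomizing (RME)
#' maternal-effect strategies under the stationary transition frequencies,
#' the implied selection coefficients, and Kimura fixation probabilities.
#'
#' @param n_draws Number of random fitness draws.
#' @param gamma Exponential rate for [sample_fitness_effects()].
#' @param n_e Effective population size for the fixation formula.
#' @param p0 Initial allele frequency.
#' @param switch_probs Grid of environmental switching probabilities in
#'   (0, 1).
#' @param adjusted Also report establishment-adjusted probabilities, where
#'   a strategy prevails only if the competing strategy with higher
#'   geometric mean fitness fails to establish?
#' @param scaling Selection scaling constant for
#'   [kimura_fixation_probability()].
#' @param seed Optional integer seed.
#' @return A list of class `fixation_sweep`: `by_switch` (data frame with
#'   per-switching-rate means of `u_dme`, `u_rme` and their ratio, plus
#'   adjusted columns when requested), `overall_ratio`
#'   (`mean(U_RME) / mean(U_DME)` over all draws and switching rates) and
#'   the call parameters.
#' @export
fixation_sweep <- function(n_draws = 10000L, gamma = 2, n_e = 1000, p0 = 0.01,
                           switch_probs = seq(0.05, 0.95, by = 0.05),
                           adjusted = FALSE, scaling = 2, seed = NULL) {
  stopifnot(all(switch_probs > 0 & switch_probs < 1))
  draws <- with_seed(seed, {
    sample_fitness_effects(gamma, n = max(2L, as.integer(n_draws)),
                           enforce_ancestral_advantage = TRUE)
  })
  draws <- draws[seq_len(n_draws), , drop = FALSE]
  x_a <- draws$x_anoxia; x_n <- draws$x_normoxia
  w_aa <- exp(x_a); w_an <- exp(-x_n)
  # RME fitness depends on the offspring-environment marginal only, which
  # is 1/2 for every symmetric switching rate: q* and G_RME are shared.
  q_star <- optimal_q_ab(w_aa - 1, w_an - 1, 0.5)
  g_rme <- sqrt((1 + q_star * (w_aa - 1)) * (1 + q_star * (w_an - 1)))
  u_rme <- kimura_fixation_probability(g_rme - 1, n_e, p0, scaling)
  rows <- lapply(switch_probs, function(sigma) {
    g_dme <- exp(0.5 * sigma * x_a - 0.5 * (1 - sigma) * x_n)
    u_dme <- kimura_fixation_probability(g_dme - 1, n_e, p0, scaling)
    out <- data.frame(switch_prob = sigma,
                      mean_u_dme = mean(u_dme),
                      mean_u_rme = mean(u_rme),
                      ratio = mean(u_rme) / mean(u_dme))
    if (adjusted) {
      dme_wins <- g_dme >= g_rme
      u_dme_adj <- ifelse(dme_wins, u_dme, u_dme * (1 - u_rme))
      u_rme_adj <- ifelse(dme_wins, u_rme * (1 - u_dme), u_rme)
      out$mean_u_dme_adj <- mean(u_dme_adj)
      out$mean_u_rme_adj <- mean(u_rme_adj)
      out$ratio_adj <- mean(u_rme_adj) / mean(u_dme_adj)
    }
    out
  })
  by_switch <- do.call(rbind, rows)
  structure(list(by_switch = by_switch,
                 overall_ratio = mean(by_switch$mean_u_rme) /
                   mean(by_switch$mean_u_dme),
                 n_draws = n_draws, gamma = gamma, n_e = n_e, p0 = p0,
                 adjusted = adjusted, scaling = scaling),
            class = "fixation_sweep")
}

#' @export
print.fixation_sweep <- function(x, ...) {
  cat(sprintf(paste0("Fixation-probability sweep: %d fitness draws ",
                     "(gamma = %g), Ne = %g, p0 = %g\n"),
              x$n_draws, x$gamma, x$n_e, x$p0))
  print(x$by_switch, row.names = FALSE, digits = 3)
  cat(sprintf("Overall mean(U_RME) / mean(U_DME): %.3g\n", x$overall_ratio))
  invisible(x)
}
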