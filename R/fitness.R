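## Two-phenotype maternal-effect fitness model.
##
## Offspring carry one of two phenotypes: normoxia-adapted (the ancestral
## reference, fitness 1 in both environments) or anoxia-adapted, with
## fitness exp(x_anoxia) >= 1 in anoxia and exp(-x_normoxia) <= 1 in
## normoxia. A genotype's maternal-effect rule decides which fraction of a
## brood carries the anoxia phenotype given the mother's own hatching
## environment.

#' Phenotype-environment fitness parameterization
#'
#' `x_anoxia` is the log-fitness gain of the anoxia-adapted phenotype in
#' anoxia, `x_normoxia` its log-fitness loss in normoxia (both >= 0 and
#' dimensionless). The normoxia-adapted phenotype is the fitness-1 reference
#' in both environments. `phenotype_fitness_from_w()` parameterizes directly
#' from the two multiplicative fitness values, e.g. the illustrative
#' simulation values `w_anoxia_in_anoxia = 2.63`,
#' `w_anoxia_in_normoxia = 0.335`.
#'
#' @param x_anoxia Log-fitness gain in anoxia (>= 0).
#' @param x_normoxia Log-fitness loss in normoxia (>= 0).
#' @return An object of class `phenotype_fitness` with elements `x_anoxia`,
#'   `x_normoxia`, `w_aa` (= `exp(x_anoxia)`) and `w_an`
#'   (= `exp(-x_normoxia)`).
#' @examples
#' phenotype_fitness_from_w(2.63, 0.335)
#' @export
phenotype_fitness <- function(x_anoxia, x_normoxia) {
  stopifnot(is.numeric(x_anoxia), is.numeric(x_normoxia),
            length(x_anoxia) == 1L, length(x_normoxia) == 1L)
  if (x_anoxia < 0 || x_normoxia < 0)
    stop("x_anoxia and x_normoxia must be nonnegative")
  structure(list(x_anoxia = x_anoxia, x_normoxia = x_normoxia,
                 w_aa = exp(x_anoxia), w_an = exp(-x_normoxia)),
            class = "phenotype_fitness")
}

#' @param w_anoxia_in_anoxia Fitness of the anoxia phenotype in anoxia
#'   (>= 1).
#' @param w_anoxia_in_normoxia Fitness of the anoxia phenotype in normoxia
#'   (in (0, 1]).
#' @rdname phenotype_fitness
#' @export
phenotype_fitness_from_w <- function(w_anoxia_in_anoxia,
                                     w_anoxia_in_normoxia) {
  if (w_anoxia_in_anoxia < 1)
    stop("the anoxia phenotype's fitness in anoxia must be >= 1")
  if (w_anoxia_in_normoxia <= 0 || w_anoxia_in_normoxia > 1)
    stop("the anoxia phenotype's fitness in normoxia must lie in (0, 1]")
  phenotype_fitness(log(w_anoxia_in_anoxia), -log(w_anoxia_in_normoxia))
}

#' @export
print.phenotype_fitness <- function(x, ...) {
  cat("Two-phenotype fitness model (normoxia phenotype = reference, w = 1)\n")
  cat(sprintf("  anoxia phenotype: w = %.4g in anoxia (x_anoxia = %.4g),",
              x$w_aa, x$x_anoxia))
  cat(sprintf(" w = %.4g in normoxia (x_normoxia = %.4g)\n",
              x$w_an, x$x_normoxia))
  invisible(x)
}

## Fitness of the anoxia-adapted phenotype in environment `env` (vectorized
## over env).
w_anoxia_phenotype <- function(pf, env) {
  ifelse(as.character(env) == "A", pf$w_aa, pf$w_an)
}

#' Maternal-effect strategies
#'
#' A genotype's maternal-effect rule:
#' * `"NONE"` - no maternal effect; all offspring carry the normoxia
#'   phenotype (the ancestral state).
#' * `"DME"` - deterministic maternal effect (transgenerational
#'   plasticity): all offspring carry the phenotype suited to the
#'   environment the mother did *not* experience.
#' * `"RME"` - randomizing maternal effect (diversifying bet-hedging): a
#'   fixed fraction `q` of each brood carries the anoxia phenotype,
#'   regardless of the maternal environment.
#'
#' @param kind One of `"NONE"`, `"DME"`, `"RME"`.
#' @param q Anoxia-phenotype brood fraction in `[0, 1]`; required for (and
#'   only meaningful with) `kind = "RME"`.
#' @return An object of class `me_strategy`.
#' @examples
#' strategy_rme(0.445)
#' @export
strategy <- function(kind = c("NONE", "DME", "RME"), q = NULL) {
  kind <- match.arg(kind)
  if (kind == "RME") {
    if (is.null(q) || !is.numeric(q) || length(q) != 1L || q < 0 || q > 1)
      stop("an RME strategy needs a brood fraction q in [0, 1]")
  } else if (!is.null(q)) {
    stop("q is only meaningful for RME strategies")
  }
  structure(list(kind = kind, q = q), class = "me_strategy")
}

#' @rdname strategy
#' @export
strategy_none <- function() strategy("NONE")

#' @rdname strategy
#' @export
strategy_dme <- function() strategy("DME")

#' @rdname strategy
#' @export
strategy_rme <- function(q) strategy("RME", q = q)

#' @export
print.me_strategy <- function(x, ...) {
  cat(switch(x$kind,
             NONE = "No maternal effect (ancestral state)",
             DME = "Deterministic maternal effect",
             RME = sprintf("Randomizing maternal effect (q = %.4g)", x$q)),
      "\n")
  invisible(x)
}

#' @export
format.me_strategy <- function(x, ...) {
  if (x$kind == "RME") sprintf("RME(q=%.3g)", x$q) else x$kind
}

#' Sample random phenotype fitness effects
#'
#' Draws the log fitness effects `x_anoxia` and `x_normoxia` independently
#' from an exponential distribution with rate `gamma`. With `gamma = 2` the
#' mean multiplicative advantage of the anoxia phenotype in anoxia is
#' `gamma / (gamma - 1) = 2`, i.e. about 2-fold. When
#' `enforce_ancestral_advantage` is `TRUE` (the default) draws are rejected
#' until `x_anoxia < x_normoxia` (strict), so the anoxia phenotype's 50/50
#' geometric mean fitness is below 1 and the ancestral normoxia phenotype
#' keeps the higher geometric mean fitness. Note the rejection conditions
#' the distribution, so the 2-fold calibration applies to the raw
#' (pre-rejection) draws.
#'
#' @param gamma Rate of the exponential distribution (> 0). The mean
#'   multiplicative effect `gamma / (gamma - 1)` is finite only for
#'   `gamma > 1`; a warning is issued otherwise.
#' @param n Number of draws.
#' @param enforce_ancestral_advantage Reject draws with
#'   `x_anoxia >= x_normoxia`?
#' @return For `n = 1` a [phenotype_fitness]; for `n > 1` a data frame with
#'   columns `x_anoxia` and `x_normoxia`.
#' @examples
#' sample_fitness_effects(2, n = 1, enforce_ancestral_advantage = TRUE)
#' @export
sample_fitness_effects <- function(gamma, n = 1L,
                                   enforce_ancestral_advantage = TRUE) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (gamma <= 1)
    warning("gamma <= 1: the mean multiplicative fitness effect is infinite")
  n <- as.integer(n)
  x_a <- stats::rexp(n, rate = gamma)
  x_n <- stats::rexp(n, rate = gamma)
  if (enforce_ancestral_advantage) {
    bad <- which(x_a >= x_n)
    while (length(bad)) {
      x_a[bad] <- stats::rexp(length(bad), rate = gamma)
      x_n[bad] <- stats::rexp(length(bad), rate = gamma)
      bad <- bad[x_a[bad] >= x_n[bad]]
    }
  }
  if (n == 1L) phenotype_fitness(x_a, x_n)
  else data.frame(x_anoxia = x_a, x_normoxia = x_n)
}

#' Brood fraction of anoxia-adapted offspring
#'
#' The fraction of a brood carrying the anoxia phenotype, given the
#' genotype's strategy and the mother's own hatching environment: 0 for no
#' maternal effect, `q` for RME, and for DME 1 when the mother hatched in
#' normoxia and 0 when she hatched in anoxia (offspring get the phenotype
#' suited to the environment the mother did not experience).
#'
#' @param strat An [strategy()] object.
#' @param maternal_env Maternal hatching environment label(s), `"N"`/`"A"`
#'   (vectorized).
#' @return Probability (vector), the anoxia-phenotype brood fraction.
#' @export
offspring_anoxia_fraction <- function(strat, maternal_env) {
  stopifnot(inherits(strat, "me_strategy"))
  m <- as.character(maternal_env)
  if (!all(m %in% env_levels)) stop("maternal_env must be 'N' or 'A'")
  switch(strat$kind,
         NONE = rep(0, length(m)),
         DME = as.numeric(m == "N"),
         RME = rep(strat$q, length(m)))
}

#' Reproductive output across one environmental transition
#'
#' The reproductive output `w_k(i, j)` of a genotype `k` individual
#' developing in environment `j` whose mother experienced hatching
#' environment `i`: the brood's arithmetic mean fitness,
#' `f * w_anoxia(j) + (1 - f) * 1`, where `f` is the genotype's
#' anoxia-phenotype brood fraction given maternal environment `i`. All
#' offspring of one generation compete together, so within-brood fitness
#' averages arithmetically; geometric averaging applies only across
#' generations.
#'
#' @param strat An [strategy()] object.
#' @param maternal_env,offspring_env Environment labels (vectorized in
#'   parallel).
#' @param pf A [phenotype_fitness].
#' @return Numeric vector of reproductive outputs.
#' @examples
#' pf <- phenotype_fitness_from_w(2.63, 0.335)
#' transition_fitness(strategy_dme(), "N", "A", pf) # 2.63
#' @export
transition_fitness <- function(strat, maternal_env, offspring_env, pf) {
  stopifnot(inherits(pf, "phenotype_fitness"))
  f <- offspring_anoxia_fraction(strat, maternal_env)
  o <- as.character(offspring_env)
  if (!all(o %in% env_levels)) stop("offspring_env must be 'N' or 'A'")
  if (length(f) != length(o))
    stopifnot(length(f) == 1L || length(o) == 1L)
  f * w_anoxia_phenotype(pf, o) + (1 - f)
}

## 2 x 2 matrix of w_k(i, j) for a strategy (maternal rows, offspring cols).
transition_fitness_matrix <- function(strat, pf) {
  g <- expand.grid(maternal = env_levels, offspring = env_levels,
                   stringsAsFactors = FALSE)
  w <- transition_fitness(strat, g$maternal, g$offspring, pf)
  matrix(w, 2L, 2L, dimnames = list(maternal = env_levels,
                                    offspring = env_levels))
}

#' Geometric mean fitness of a genotype
#'
#' `G_k = exp(sum_{i,j} p(i, j) log(w_k(i, j)))`: the exponential of the
#' transition-frequency-weighted mean log reproductive output, the quantity
#' maximized by selection in temporally fluctuating environments. If any
#' transition with positive weight has zero reproductive output, `G = 0` is
#' returned with a warning.
#'
#' @param strat An [strategy()] object.
#' @param p A [transition_freqs] matrix (or plain 2 x 2 matrix of weights
#'   summing to 1).
#' @param pf A [phenotype_fitness].
#' @return The geometric mean fitness (scalar).
#' @examples
#' pf <- phenotype_fitness_from_w(2.63, 0.335)
#' p <- stationary_transition_frequencies(1) # strict alternation
#' geometric_mean_fitness(strategy_dme(), p, pf) # sqrt(2.63)
#' @export
geometric_mean_fitness <- function(strat, p, pf) {
  p <- transition_freqs(p)
  w <- transition_fitness_matrix(strat, pf)
  if (any(w == 0 & p > 0)) {
    warning("a transition with positive weight has zero reproductive ",
            "output; geometric mean fitness is 0")
    return(0)
  }
  lw <- ifelse(p > 0, log(w), 0)
  exp(sum(p * lw))
}

## Vectorized optimal bet-hedging fraction on the (a, b) = (w_aa - 1,
## w_an - 1) scale with offspring-anoxia marginal frequency m_a.
## d/dq log G = m_a a / (1 + q a) + (1 - m_a) b / (1 + q b); log G is
## concave, so boundary derivative checks plus the interior root
## q = -(m_a a + (1 - m_a) b) / (a b) give the argmax in closed form.
optimal_q_ab <- function(a, b, m_a) {
  d0 <- m_a * a + (1 - m_a) * b
  d1 <- m_a * a / (1 + a) + (1 - m_a) * b / (1 + b)
  q <- -d0 / (a * b)
  q[d1 >= 0] <- 1           # derivative at q = 1 nonnegative -> boundary 1
  q[d0 <= 0] <- 0           # derivative at q = 0 nonpositive -> boundary 0
  # (by concavity d1 <= d0; ordering makes the degenerate w = 1 case, where
  # both derivatives vanish, tie-break toward the ancestral phenotype q = 0)
  pmin(pmax(q, 0), 1)
}

#' Optimal bet-hedging fraction
#'
#' The anoxia-phenotype brood fraction `q*` maximizing the RME genotype's
#' geometric mean fitness under transition frequencies `p`. Because RME
#' fitness depends only on the offspring environment, the optimum depends on
#' `p` only through the marginal offspring-environment frequencies; the
#' concave first-order condition has the closed-form interior root
#' `q* = -(m_A a + m_N b) / (a b)` with `a = w_aa - 1`, `b = w_an - 1`, used
#' after derivative sign checks at the boundaries. Degenerate fitness
#' (`w_aa = w_an = 1`) ties break toward the ancestral phenotype, `q* = 0`.
#'
#' @param p A [transition_freqs] matrix.
#' @param pf A [phenotype_fitness].
#' @return The optimal fraction `q*` in `[0, 1]`.
#' @examples
#' pf <- phenotype_fitness_from_w(2.63, 0.335)
#' optimal_q(stationary_transition_frequencies(0.5), pf) # ~0.4451
#' @export
optimal_q <- function(p, pf) {
  p <- transition_freqs(p)
  stopifnot(inherits(pf, "phenotype_fitness"))
  m_a <- p["N", "A"] + p["A", "A"]
  optimal_q_ab(pf$w_aa - 1, pf$w_an - 1, m_a)
}
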