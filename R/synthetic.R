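## Synthetic assay tables with the statistical structure the analysis
## pipeline assumes: multiplicative (log-normal) block, replicate-population
## and residual effects around per-transition ancestral means, plus Poisson
## L1 counts as the raw observable behind growth rates.

#' True parameters for synthetic assay data
#'
#' Defines the data-generating truth for [generate_assay_table()]:
#' per-transition ancestral mean trait values and per-regime true ln
#' relative fitness effects, with log-scale standard deviations for
#' thawing-block effects (shared by all samples thawed together, ancestor
#' included), replicate-population effects (one per evolved population, the
#' signature of independent evolutionary history) and residual measurement
#' noise.
#'
#' The default ancestral means emulate the experimental system: growth
#' rates (offspring L1 per maternal L1 seeded) near 1.5 when embryos hatch
#' in normoxia and severely reduced, near 0.5, when they hatch in anoxia,
#' with a small further reduction when the mothers themselves hatched in
#' normoxia.
#'
#' @param ancestor_mean 2 x 2 matrix of true ancestral mean trait values
#'   (maternal rows, offspring columns, order `N`, `A`), all > 0.
#' @param effect Named list of 2 x 2 matrices of true ln relative fitness
#'   per evolved regime.
#' @param sigma_block,sigma_pop,sigma_res Log-scale standard deviations of
#'   block, replicate-population and residual effects (>= 0).
#' @param trait Trait label carried by generated records.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(ancestor_mean = default_ancestor_mean(),
                         effect = list(predictable = default_dme_effect()),
                         sigma_block = 0.1, sigma_pop = 0.1,
                         sigma_res = 0.2, trait = "growth_rate") {
  ancestor_mean <- as.matrix(ancestor_mean)
  if (!all(dim(ancestor_mean) == c(2L, 2L)) || any(ancestor_mean <= 0))
    stop("ancestor_mean must be a positive 2 x 2 matrix")
  dimnames(ancestor_mean) <- list(maternal = env_levels,
                                  offspring = env_levels)
  stopifnot(is.list(effect), length(names(effect)) == length(effect))
  effect <- lapply(effect, function(e) {
    e <- as.matrix(e)
    if (!all(dim(e) == c(2L, 2L))) stop("each effect must be a 2 x 2 matrix")
    dimnames(e) <- list(maternal = env_levels, offspring = env_levels)
    e
  })
  if (sigma_block < 0 || sigma_pop < 0 || sigma_res < 0)
    stop("effect standard deviations must be nonnegative")
  structure(list(ancestor_mean = ancestor_mean, effect = effect,
                 sigma_block = sigma_block, sigma_pop = sigma_pop,
                 sigma_res = sigma_res, trait = trait),
            class = "truth_params")
}

#' @rdname truth_params
#' @export
default_ancestor_mean <- function() {
  matrix(c(1.5, 1.6, 0.4, 0.6), 2L, 2L,
         dimnames = list(maternal = env_levels, offspring = env_levels))
}

#' @rdname truth_params
#' @export
default_dme_effect <- function() {
  # an evolved deterministic maternal effect: gains when mothers hatched in
  # normoxia and offspring face anoxia (and under repeated normoxia), a
  # cost under repeated anoxia
  matrix(c(0.3, 0.0, 0.5, -0.3), 2L, 2L,
         dimnames = list(maternal = env_levels, offspring = env_levels))
}

#' Assay design configuration
#'
#' The experimental design being emulated: measurements organized in
#' thawing blocks, several independently evolved replicate populations per
#' regime, and repeated measurements per population x hatching treatment.
#' The defaults follow the growth-rate assay design: 18 blocks, 4 replicate
#' populations, 3 measurements per population and treatment.
#'
#' @param n_blocks Number of thawing blocks.
#' @param n_populations Replicate populations per regime.
#' @param n_replicates Measurements per population x treatment x block.
#' @param seed Optional integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_blocks = 18L, n_populations = 4L,
                         n_replicates = 3L, seed = NULL) {
  n_blocks <- as.integer(n_blocks)
  n_populations <- as.integer(n_populations)
  n_replicates <- as.integer(n_replicates)
  if (min(n_blocks, n_populations, n_replicates) < 1L)
    stop("all design counts must be >= 1")
  structure(list(n_blocks = n_blocks, n_populations = n_populations,
                 n_replicates = n_replicates, seed = seed),
            class = "synth_config")
}

## design grid shared by the generators: ancestor rows (regime "ancestor",
## one population) plus n_populations per evolved regime, every block x
## transition x replicate
synth_design <- function(truth, cfg) {
  regimes <- names(truth$effect)
  pops <- lapply(regimes, function(r)
    paste0(toupper(substr(r, 1L, 1L)), seq_len(cfg$n_populations)))
  design <- expand.grid(
    replicate = seq_len(cfg$n_replicates),
    block = sprintf("b%02d", seq_len(cfg$n_blocks)),
    maternal_env = env_levels, offspring_env = env_levels,
    population = c("ancestor", unlist(pops)),
    stringsAsFactors = FALSE)
  pop2regime <- c(stats::setNames(rep(regimes, each = cfg$n_populations),
                                  unlist(pops)),
                  ancestor = "ancestor")
  design$regime <- pop2regime[design$population]
  design
}

## expected value on the natural scale for each design row, including the
## realized block and population effects; returns list(mu, truth_effects)
synth_expected <- function(truth, cfg, design) {
  blocks <- sprintf("b%02d", seq_len(cfg$n_blocks))
  block_eff <- stats::setNames(stats::rnorm(cfg$n_blocks, 0, truth$sigma_block),
                               blocks)
  pops <- setdiff(unique(design$population), "ancestor")
  pop_eff <- stats::setNames(stats::rnorm(length(pops), 0, truth$sigma_pop),
                             pops)
  idx <- cbind(design$maternal_env, design$offspring_env)
  eff <- numeric(nrow(design))
  for (r in names(truth$effect)) {
    sel <- design$regime == r
    eff[sel] <- truth$effect[[r]][idx[sel, , drop = FALSE]]
  }
  u <- ifelse(design$population == "ancestor", 0,
              pop_eff[design$population])
  mu <- truth$ancestor_mean[idx] *
    exp(eff + block_eff[design$block] + u)
  list(mu = mu,
       truth_effects = list(block = block_eff, population = pop_eff))
}

#' Generate a synthetic assay table
#'
#' Draws a full factorial two-generation assay table under the log-normal
#' effect model: each record's value is
#' `ancestor_mean(i, j) * exp(effect + block + population + residual)`,
#' with `effect = 0` for ancestor rows and all random effects Normal on the
#' log scale. Ancestor rows are present in every block. Identical seeds
#' give identical tables.
#'
#' @param truth A [truth_params()].
#' @param cfg A [synth_config()].
#' @return An assay table (data frame with the standard columns). The
#'   realized block and population effects are attached as attribute
#'   `"truth_effects"` so parameter-recovery checks can score estimates
#'   against each population's own true relative fitness
#'   (`effect + population effect`).
#' @export
generate_assay_table <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_params"), inherits(cfg, "synth_config"))
  design <- synth_design(truth, cfg)
  with_seed(cfg$seed, {
    ex <- synth_expected(truth, cfg, design)
    design$trait <- truth$trait
    design$value <- ex$mu * exp(stats::rnorm(nrow(design), 0, truth$sigma_res))
    out <- design[, assay_columns]
    attr(out, "truth_effects") <- ex$truth_effects
    out
  })
}

#' Generate synthetic L1 count tables
#'
#' The raw observable behind growth rates: offspring L1 counts drawn as
#' `Poisson(seeded * true growth rate)` around the same multiplicative
#' effect structure as [generate_assay_table()].
#' [growth_rate_from_counts()] inverts the counts to noisy growth rates.
#'
#' @param truth A [truth_params()] (trait interpreted as growth rate).
#' @param cfg A [synth_config()].
#' @param seeded Number of maternal L1 larvae seeded per measurement.
#' @return A data frame with the design columns plus `l1_count`, `seeded`
#'   and `value` (the implied growth rate `l1_count / seeded`).
#' @export
generate_l1_counts <- function(truth, cfg, seeded = 5000L) {
  stopifnot(inherits(truth, "truth_params"), inherits(cfg, "synth_config"))
  design <- synth_design(truth, cfg)
  with_seed(cfg$seed, {
    ex <- synth_expected(truth, cfg, design)
    design$trait <- truth$trait
    design$l1_count <- stats::rpois(nrow(design), seeded * ex$mu)
    design$seeded <- seeded
    design$value <- growth_rate_from_counts(design$l1_count, seeded)
    out <- design[, c(assay_columns, "l1_count", "seeded")]
    attr(out, "truth_effects") <- ex$truth_effects
    out
  })
}

#' Expected growth-rate series along an environmental sequence
#'
#' The deterministic expected per-generation reproductive output of a
#' population fixed for one maternal-effect strategy along an environmental
#' sequence: generation `t` (for `t >= 2`) has output
#' `baseline * `[transition_fitness()]`(strategy, env[t-1], env[t], pf)`.
#' Useful as a smoke-test fixture for evolution-trace plots; it makes no
#' claim about real (polymorphic, drifting) trajectories.
#'
#' @param seq An [env_seq].
#' @param pf A [phenotype_fitness].
#' @param strat An [strategy()] object.
#' @param baseline Baseline reproductive output multiplier.
#' @return Data frame with columns `generation` (2..length), `maternal_env`,
#'   `offspring_env`, `expected_output`.
#' @export
generate_evolution_trace <- function(seq, pf, strat, baseline = 1) {
  x <- as.character(seq)
  n <- length(x)
  m <- x[-n]; o <- x[-1L]
  data.frame(generation = 2:n, maternal_env = m, offspring_env = o,
             expected_output = baseline * transition_fitness(strat, m, o, pf))
}
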