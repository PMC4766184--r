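## Analysis pipeline for two-generation factorial fitness assays.
##
## Assay tables are data frames with columns
##   regime, population, block, replicate, maternal_env, offspring_env,
##   trait, value
## where regime is one of "predictable", "unpredictable", "constant",
## "ancestor"; maternal_env/offspring_env are "N"/"A"; trait is
## "growth_rate", "fecundity" or "hatchability"; value >= 0.

assay_columns <- c("regime", "population", "block", "replicate",
                   "maternal_env", "offspring_env", "trait", "value")

check_assay_table <- function(records) {
  miss <- setdiff(assay_columns, names(records))
  if (length(miss))
    stop("assay table is missing columns: ", paste(miss, collapse = ", "))
  if (any(records$value < 0)) stop("assay values must be nonnegative")
  invisible(records)
}

#' Growth rate from L1 counts
#'
#' The maternal-L1-to-offspring-L1 growth rate over one full life cycle:
#' the number of surviving offspring L1 larvae divided by the number of
#' maternal L1 larvae seeded (5,000 in the experimental design). Over a
#' full life cycle its natural logarithm estimates absolute fitness.
#'
#' @param l1_count Offspring L1 count(s) (>= 0); vectorized.
#' @param seeded Number of maternal L1 larvae seeded (> 0).
#' @return Growth rate(s).
#' @export
growth_rate_from_counts <- function(l1_count, seeded = 5000) {
  if (any(l1_count < 0)) stop("counts must be nonnegative")
  if (any(seeded <= 0)) stop("seeded count must be > 0")
  l1_count / seeded
}

#' Per-block ancestral means
#'
#' Arithmetic mean ancestral value per block x maternal environment x
#' offspring environment x trait, the denominator of the relative-fitness
#' ln ratios. Evolved and ancestral samples were assayed concurrently in
#' thawing blocks, so dividing by the per-block ancestral mean removes the
#' block effect.
#'
#' @param records Assay table (only rows with `regime == "ancestor"` are
#'   used).
#' @return Data frame with columns `block`, `maternal_env`, `offspring_env`,
#'   `trait`, `anc_mean`.
#' @export
ancestral_block_means <- function(records) {
  check_assay_table(records)
  anc <- records[records$regime == "ancestor", , drop = FALSE]
  if (!nrow(anc)) stop("no ancestor records in the assay table")
  out <- stats::aggregate(
    value ~ block + maternal_env + offspring_env + trait, data = anc,
    FUN = mean)
  names(out)[names(out) == "value"] <- "anc_mean"
  out
}

#' ln relative fitness against per-block ancestral means
#'
#' For each evolved record, `ln(value / ancestral block mean)` in the
#' matching block x maternal environment x offspring environment x trait
#' cell. Positive values imply adaptation; under a single invading
#' codominant allele (or haploid complement) the ln ratio estimates the
#' strength of selection.
#'
#' @param evolved Assay table of evolved (non-ancestor) records with
#'   strictly positive values.
#' @param anc_means Output of [ancestral_block_means()].
#' @return The evolved records with an added `ln_rel` column.
#' @export
ln_relative <- function(evolved, anc_means) {
  check_assay_table(evolved)
  merged <- merge(evolved, anc_means,
                  by = c("block", "maternal_env", "offspring_env", "trait"),
                  all.x = TRUE, sort = FALSE)
  if (anyNA(merged$anc_mean)) {
    bad <- merged[is.na(merged$anc_mean), , drop = FALSE][1L, ]
    stop(sprintf(paste0("no ancestor records for block '%s', transition ",
                        "%s->%s, trait '%s'"),
                 bad$block, bad$maternal_env, bad$offspring_env, bad$trait))
  }
  if (any(merged$value <= 0))
    stop("ln relative fitness requires strictly positive values; ",
         "exclude zero growth rates upstream")
  if (any(merged$anc_mean <= 0))
    stop("ancestral block means must be strictly positive")
  merged$ln_rel <- log(merged$value / merged$anc_mean)
  merged
}

## Bootstrap of a mean of per-block means: returns c(se, lower, upper).
## Resampling unit is the block (the thawing batch, the experimental unit);
## this propagates the shared ancestral-mean noise within a block. With few
## blocks the percentile interval is anticonservative, so the default
## interval is mean +/- t_{1-alpha/2, B-1} * bootstrap se.
boot_block_mean <- function(block_means, n_boot, conf,
                            ci_type = c("t", "percentile")) {
  ci_type <- match.arg(ci_type)
  b <- length(block_means)
  if (b < 2L) return(c(NA_real_, NA_real_, NA_real_))
  idx <- matrix(sample.int(b, b * n_boot, replace = TRUE), n_boot, b)
  t_star <- rowMeans(matrix(block_means[idx], n_boot, b))
  se <- stats::sd(t_star)
  alpha <- (1 - conf) / 2
  if (ci_type == "t") {
    m <- mean(block_means)
    half <- stats::qt(1 - alpha, df = b - 1L) * se
    c(se, m - half, m + half)
  } else {
    c(se, stats::quantile(t_star, alpha, names = FALSE),
      stats::quantile(t_star, 1 - alpha, names = FALSE))
  }
}

#' Relative-fitness estimates per population and transition
#'
#' Summarizes ln-ratio records into one estimate per population x maternal
#' environment x offspring environment x trait: replicate measurements are
#' first averaged within block, the estimate is the mean over blocks, and
#' uncertainty comes from a seeded nonparametric bootstrap over blocks.
#' The default interval is the Student-t interval on the bootstrap standard
#' error (better calibrated than the percentile interval with ~18 blocks);
#' `ci_type = "percentile"` gives the raw percentile interval. With a
#' single block the standard error is reported as `NA`.
#'
#' @param ln_records Output of [ln_relative()].
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level of the interval.
#' @param ci_type Interval type, `"t"` (default) or `"percentile"`.
#' @param seed Optional integer seed for the bootstrap.
#' @return Data frame with columns `regime`, `population`, `maternal_env`,
#'   `offspring_env`, `trait`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `n_blocks`, `n`.
#' @export
population_transition_estimates <- function(ln_records, n_boot = 1000L,
                                            conf = 0.95,
                                            ci_type = c("t", "percentile"),
                                            seed = NULL) {
  ci_type <- match.arg(ci_type)
  stopifnot("ln_rel" %in% names(ln_records))
  key <- interaction(ln_records$regime, ln_records$population,
                     ln_records$maternal_env, ln_records$offspring_env,
                     ln_records$trait, drop = TRUE)
  with_seed(seed, {
    rows <- lapply(split(ln_records, key), function(cell) {
      bm <- tapply(cell$ln_rel, cell$block, mean)
      stats <- boot_block_mean(as.numeric(bm), n_boot, conf, ci_type)
      data.frame(regime = cell$regime[1L], population = cell$population[1L],
                 maternal_env = cell$maternal_env[1L],
                 offspring_env = cell$offspring_env[1L],
                 trait = cell$trait[1L],
                 estimate = mean(bm), se = stats[1L],
                 ci_lower = stats[2L], ci_upper = stats[3L],
                 n_blocks = length(bm), n = nrow(cell))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$regime, out$population, out$maternal_env,
              out$offspring_env), , drop = FALSE]
  })
}

#' Fit relative fitness from a two-generation factorial assay
#'
#' The full relative-fitness pipeline: select one trait, drop zero-valued
#' records (with a message reporting how many; the natural log is undefined
#' for them), compute per-block ancestral means, take the ln ratio of every
#' evolved record over its matching ancestral block mean, and summarize per
#' population x environmental transition with a block bootstrap
#' ([population_transition_estimates()]).
#'
#' @param records Assay table including ancestor rows.
#' @param trait Trait to analyze.
#' @param n_boot,conf,ci_type,seed Passed to
#'   [population_transition_estimates()].
#' @return An object of class `relfit` with elements `estimates` (the
#'   per-population transition table), `ln_records`, `anc_means`,
#'   `n_excluded_zero` and `trait`. Supports `print()`, `summary()` and
#'   `coef()`.
#' @export
fit_relative_fitness <- function(records, trait = "growth_rate",
                                 n_boot = 1000L, conf = 0.95,
                                 ci_type = c("t", "percentile"),
                                 seed = NULL) {
  ci_type <- match.arg(ci_type)
  check_assay_table(records)
  records <- records[records$trait == trait, , drop = FALSE]
  if (!nrow(records)) stop("no records for trait '", trait, "'")
  zero <- records$value == 0
  if (any(zero)) {
    message(sum(zero), " zero-valued record(s) excluded from the ",
            "ln-ratio analysis")
    records <- records[!zero, , drop = FALSE]
  }
  anc_means <- ancestral_block_means(records)
  evolved <- records[records$regime != "ancestor", , drop = FALSE]
  if (!nrow(evolved)) stop("no evolved records in the assay table")
  ln_records <- ln_relative(evolved, anc_means)
  estimates <- population_transition_estimates(ln_records, n_boot = n_boot,
                                               conf = conf, ci_type = ci_type,
                                               seed = seed)
  structure(list(estimates = estimates, ln_records = ln_records,
                 anc_means = anc_means, n_excluded_zero = sum(zero),
                 trait = trait, conf = conf),
            class = "relfit")
}

#' @export
print.relfit <- function(x, digits = 3, ...) {
  cat(sprintf("Relative fitness (ln evolved / ancestral block mean), trait '%s'\n",
              x$trait))
  cat(sprintf("  %d estimates over %d ln-ratio records\n",
              nrow(x$estimates), nrow(x$ln_records)))
  if (x$n_excluded_zero)
    cat("  ", x$n_excluded_zero, "zero-valued records excluded\n")
  print(x$estimates, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.relfit <- function(object, ...) {
  e <- object$estimates
  stats::setNames(e$estimate,
                  paste0(e$population, ":", e$maternal_env, "->",
                         e$offspring_env))
}

#' @export
summary.relfit <- function(object, ...) {
  e <- object$estimates
  reg <- stats::aggregate(estimate ~ regime + maternal_env + offspring_env,
                          data = e, FUN = mean)
  names(reg)[names(reg) == "estimate"] <- "mean_estimate"
  n_pop <- stats::aggregate(population ~ regime + maternal_env + offspring_env,
                            data = e,
                            FUN = function(p) length(unique(p)))
  names(n_pop)[names(n_pop) == "population"] <- "n_populations"
  out <- merge(reg, n_pop,
               by = c("regime", "maternal_env", "offspring_env"))
  structure(list(trait = object$trait, by_regime = out,
                 estimates = e), class = "summary.relfit")
}

#' @export
print.summary.relfit <- function(x, digits = 3, ...) {
  cat(sprintf("Regime-level mean ln relative fitness, trait '%s'\n", x$trait))
  print(x$by_regime, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Geometric mean fitness over experienced transitions (assay scale)
#'
#' `exp(sum_ij weights(i, j) * ln w(i, j))` for a map of per-transition
#' absolute (or relative) fitness values. For the strictly alternating
#' (predictable) regime the weights put 1/2 on each off-diagonal
#' transition; for an unpredictable population the natural weights are the
#' empirical [transition_frequencies()] of the sequence it experienced.
#'
#' @param w 2 x 2 matrix of per-transition fitness values (maternal rows,
#'   offspring columns, order `N`, `A`), strictly positive wherever the
#'   weight is positive.
#' @param weights A [transition_freqs] matrix (or 2 x 2 matrix summing
#'   to 1).
#' @return The geometric mean fitness.
#' @examples
#' w <- matrix(c(1, 1, 2.63, 1), 2, 2) # only N->A differs from 1
#' geometric_mean_fitness_assay(w, stationary_transition_frequencies(1))
#' @export
geometric_mean_fitness_assay <- function(w, weights) {
  weights <- transition_freqs(weights)
  w <- as.matrix(w)
  if (!all(dim(w) == c(2L, 2L))) stop("w must be a 2 x 2 matrix")
  if (any(w <= 0 & weights > 0))
    stop("fitness must be > 0 wherever the transition weight is positive")
  lw <- ifelse(weights > 0, log(w), 0)
  exp(sum(weights * lw))
}

## maternal labels for a sequence under the two boundary conventions
maternal_labels <- function(x, boundary) {
  n <- length(x)
  switch(boundary,
         cyclic = c(x[n], x[-n]),
         prepend = c(x[1L], x[-n]),
         stop("boundary must be 'cyclic' or 'prepend'"))
}

#' Expected adaptation along an environmental sequence
#'
#' The per-generation fitness advantage of an evolved genotype over the
#' ancestor along a specific environmental sequence `s` of length `L`:
#' `A_s = (prod_t w(env[t-1], env[t]))^(1/L)`, the geometric mean of the
#' per-transition relative fitness values along the sequence. The first
#' generation's maternal environment is set by the boundary convention:
#' `"cyclic"` (default) wraps the sequence (`env[0] := env[L]`), keeping
#' `A_s` invariant under rotation; `"prepend"` duplicates the first
#' environment.
#'
#' @param rel_w 2 x 2 matrix of per-transition relative fitness values
#'   (maternal rows, offspring columns, order `N`, `A`), all > 0.
#' @param seq An [env_seq] (length 12 in the enumeration analysis).
#' @param boundary `"cyclic"` or `"prepend"`.
#' @return The per-generation advantage `A_s` (scalar), with the raw
#'   product of relative fitnesses as attribute `"product"`.
#' @export
expected_adaptation <- function(rel_w, seq, boundary = c("cyclic", "prepend")) {
  boundary <- match.arg(boundary)
  rel_w <- as.matrix(rel_w)
  if (!all(dim(rel_w) == c(2L, 2L))) stop("rel_w must be a 2 x 2 matrix")
  if (any(rel_w <= 0)) stop("relative fitness values must be > 0")
  dimnames(rel_w) <- list(env_levels, env_levels)
  x <- as.character(seq)
  m <- maternal_labels(x, boundary)
  w_t <- rel_w[cbind(m, x)]
  prod_w <- prod(w_t)
  structure(prod_w^(1 / length(x)), product = prod_w)
}

#' Enumerate expected adaptation over all binary sequences
#'
#' Scores every one of the `2^length` environmental sequences of the given
#' length with [expected_adaptation()], recording the normoxia frequency of
#' each sequence (used to color the resulting cloud of adaptation scores).
#'
#' @param rel_w As in [expected_adaptation()].
#' @param length Sequence length `L` (enumeration guard: `L <= 20`).
#' @param boundary Boundary convention, see [expected_adaptation()].
#' @return Data frame with `2^L` rows: `sequence` (string of N/A labels),
#'   `a_s`, `product`, `normoxia_freq`.
#' @export
enumerate_adaptation <- function(rel_w, length = 12L,
                                 boundary = c("cyclic", "prepend")) {
  boundary <- match.arg(boundary)
  l <- as.integer(length)
  if (l < 1L || l > 20L) stop("length must lie in [1, 20]")
  rel_w <- as.matrix(rel_w)
  if (!all(dim(rel_w) == c(2L, 2L))) stop("rel_w must be a 2 x 2 matrix")
  if (any(rel_w <= 0)) stop("relative fitness values must be > 0")
  n_seq <- 2L^l
  # environment code matrix: row = sequence, col = generation (0 = N, 1 = A)
  e <- matrix(0L, n_seq, l)
  ids <- 0:(n_seq - 1L)
  for (j in seq_len(l)) e[, j] <- bitwAnd(ids %/% 2L^(l - j), 1L)
  m <- switch(boundary,
              cyclic = cbind(e[, l], e[, -l, drop = FALSE]),
              prepend = cbind(e[, 1L], e[, -l, drop = FALSE]))
  logw <- log(rel_w)  # [maternal + 1, offspring + 1]
  lsum <- rowSums(matrix(logw[cbind(as.vector(m) + 1L, as.vector(e) + 1L)],
                         n_seq, l))
  seq_str <- apply(e, 1L, function(code)
    paste(env_decode(code), collapse = ""))
  data.frame(sequence = seq_str,
             a_s = exp(lsum / l),
             product = exp(lsum),
             normoxia_freq = rowMeans(e == 0L))
}
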