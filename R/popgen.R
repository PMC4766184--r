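## Fixation-probability theory and closed-form diversity summaries.

#' Effective selection coefficient from geometric mean fitnesses
#'
#' `s = G_mut / G_res - 1`, the mutant's geometric mean reproductive output
#' relative to the resident's. With the ancestral resident (no maternal
#' effect, `G_res = 1`) this is simply `G_mut - 1`.
#'
#' @param g_mut Geometric mean fitness of the invading genotype
#'   (vectorized).
#' @param g_res Geometric mean fitness of the resident genotype (> 0).
#' @return Selection coefficient(s).
#' @export
selection_coefficient <- function(g_mut, g_res = 1) {
  if (any(g_res <= 0)) stop("the resident geometric mean fitness must be > 0")
  g_mut / g_res - 1
}

#' Kimura's fixation probability under the Wright-Fisher process
#'
#' The diffusion approximation to the fixation probability of an allele with
#' selection coefficient `s` starting at frequency `p0` in a population of
#' effective size `n_e`:
#' `U = (1 - exp(-c n_e s p0)) / (1 - exp(-c n_e s))`,
#' with `c = scaling`. The default `scaling = 2` corresponds to effectively
#' haploid transmission (appropriate for a selfing hermaphrodite where each
#' individual passes a single genotype to its brood); `scaling = 4` gives
#' the diploid genic convention. The neutral limit `s -> 0` is `p0` and is
#' computed stably via `expm1`; strongly selected alleles are handled
#' without overflow.
#'
#' @param s Selection coefficient(s); vectorized.
#' @param n_e Effective population size (> 0).
#' @param p0 Initial allele frequency in (0, 1).
#' @param scaling Selection scaling constant `c`, 2 (default) or 4.
#' @return Fixation probability(ies) in `[0, 1]`.
#' @examples
#' kimura_fixation_probability(0.1, n_e = 1000, p0 = 0.01) # 1 - exp(-2)
#' @export
kimura_fixation_probability <- function(s, n_e, p0, scaling = 2) {
  if (n_e <= 0) stop("n_e must be > 0")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  x <- scaling * n_e * s
  u <- numeric(length(x))
  deleterious_big <- x < -700  # expm1(-x) would overflow
  ok <- !deleterious_big & x != 0
  u[x == 0] <- p0
  u[deleterious_big] <- exp(x[deleterious_big] * (1 - p0))
  u[ok] <- expm1(-p0 * x[ok]) / expm1(-x[ok])
  u
}

#' Probability that the deterministic strategy prevails
#'
#' When both maternal-effect strategies segregate at low frequency, each may
#' establish; if both establish, the strategy with the higher geometric mean
#' fitness prevails. The probability that the deterministic maternal effect
#' (DME) wins is therefore `U_DME` when `G_DME >= G_RME`, and
#' `U_DME * (1 - U_RME)` otherwise (DME must establish while RME fails to).
#'
#' @param u_dme,u_rme Fixation probabilities of the DME and RME alleles
#'   (vectorized in parallel).
#' @param g_dme,g_rme Geometric mean fitnesses of the two strategies.
#' @return Probability(ies) that DME prevails.
#' @export
establishment_probability <- function(u_dme, u_rme, g_dme, g_rme) {
  ifelse(g_dme >= g_rme, u_dme, u_dme * (1 - u_rme))
}

#' Within-population fixation index
#'
#' `Fis = 1 - Ho / He`, one minus the ratio of observed to expected
#' heterozygosity; near 1 under predominant self-fertilization.
#'
#' @param ho Observed heterozygosity (>= 0); vectorized.
#' @param he Expected heterozygosity under random mating (> 0).
#' @return The fixation index.
#' @export
fis <- function(ho, he) {
  if (any(he <= 0)) stop("expected heterozygosity must be > 0")
  if (any(ho < 0)) stop("observed heterozygosity must be >= 0")
  1 - ho / he
}

#' Effective number of haplotypes
#'
#' `1 / sum(p_i^2)` for haplotype proportions `p_i`: the number of equally
#' frequent haplotypes giving the same homozygosity.
#'
#' @param proportions Nonnegative proportions summing to 1 (within 1e-9).
#' @return The effective number (count-equivalent).
#' @examples
#' effective_number(c(0.5, 0.25, 0.25)) # 8/3
#' @export
effective_number <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  1 / sum(proportions^2)
}
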