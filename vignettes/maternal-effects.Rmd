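---
title: "Modelling maternal-effect evolution in fluctuating environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maternal-effect evolution in fluctuating environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctme)
```

`fluctme` models adaptation to a two-state hatching environment — normoxia
("N") and anoxia ("A") — that fluctuates across maternal-offspring
generations, the setting of *C. elegans* experimental evolution under
fluctuating oxygen regimes. This vignette is the package's account of the
science: the model and its assumptions, the parameters that matter, the
numerical conventions, and what the synthetic-data machinery does and does
not establish.

## The two-phenotype maternal-effect model

Offspring carry one of two phenotypes. The normoxia-adapted phenotype is
the ancestral reference with fitness 1 in both environments. The
anoxia-adapted phenotype has fitness $e^{x_A} \ge 1$ in anoxia and
$e^{-x_N} \le 1$ in normoxia ($x_A, x_N \ge 0$, dimensionless log fitness
effects). A genotype's maternal-effect rule sets the fraction $f$ of the
brood carrying the anoxia phenotype from the mother's own hatching
environment:

* `NONE` — $f = 0$ always (ancestral state);
* `DME` — $f = 1$ after maternal normoxia, $f = 0$ after maternal anoxia:
  every offspring is suited to the environment the mother did *not*
  experience, the right rule when the environment tends to switch;
* `RME` — $f = q$ regardless of the maternal environment (bet-hedging).

Within one generation all offspring compete together, so the brood's
reproductive output across the transition from maternal environment $i$ to
offspring environment $j$ averages *arithmetically*,
$w_k(i,j) = f\,w_\text{anoxia}(j) + (1 - f)$. Across generations,
reproductive output multiplies, so the invasion criterion is the
transition-weighted *geometric* mean
$G_k = \exp\big(\sum_{i,j} p(i,j)\log w_k(i,j)\big)$, with $p(i,j)$ the
frequencies of mother-offspring environmental transitions. Key consequences
the test suite verifies: $G_\text{NONE} = 1$ for every $p$; $G_\text{RME}$
depends on $p$ only through the offspring-environment marginal; and
$G_\text{DME}$ increases with the switching rate.

Assumptions worth making explicit. The maternal environment is *global*:
every mother of a generation hatched in the same environment, as in the
experimental design, so no per-individual maternal state is tracked.
Generations are discrete and non-overlapping. Genotypes are effectively
haploid (a selfing hermaphrodite passes its full genotype to the brood);
there is no mutation, recombination, dominance or demographic
stochasticity in $N$.

### The optimal bet-hedging fraction

$\log G_\text{RME}(q)$ is concave, so `optimal_q()` solves the first-order
condition in closed form: with $a = e^{x_A} - 1$, $b = e^{-x_N} - 1$ and
$m_A$ the offspring-anoxia marginal frequency, the interior root is
$q^* = -(m_A a + m_N b)/(ab)$, used only when the derivative is positive at
$q = 0$ and negative at $q = 1$; otherwise the respective boundary is
returned. Degenerate fitness ($w \equiv 1$) ties break toward the
ancestral phenotype, $q^* = 0$. The closed form is exact to floating-point
precision (well beyond the 1e-6 contract) and is cross-checked against a
10,001-point grid search in the tests.

### Random fitness effects

`sample_fitness_effects()` draws $x_A, x_N$ independently from an
exponential distribution, interpreting its parameter $\gamma$ as the
*rate*: only then is the mean multiplicative effect
$E[e^{x}] = \gamma/(\gamma - 1)$ finite, equal to 2 at $\gamma = 2$ — an
approximately 2-fold average anoxia advantage, the scale of the evolved
responses. Two independent draws (rather than one symmetric one) are
required because the illustrative pair $w = 2.63$ in anoxia and $w = 0.335$
in normoxia is asymmetric ($\ln 2.63 \ne -\ln 0.335$). With
`enforce_ancestral_advantage = TRUE` draws are rejected until
$x_A < x_N$ (strict; ties have probability zero), keeping the ancestral
phenotype's 50/50 geometric mean fitness higher. The 2-fold calibration is
a property of the *raw* draws; the rejection conditions the distribution.

## Fixation theory and Wright-Fisher simulation

The effective selection coefficient of an invading strategy is its
geometric mean reproductive output relative to the resident,
$s = G_\text{mut}/G_\text{res} - 1$, plugged into Kimura's diffusion
approximation $U = (1 - e^{-c N_e s p_0})/(1 - e^{-c N_e s})$. The scaling
constant defaults to $c = 2$, the effectively haploid convention
appropriate for selfing hermaphrodites; $c = 4$ (diploid genic) is an
argument. The neutral limit is handled via `expm1`, not division, and both
tails are overflow-safe. Defaults $N_e = 10^3$ (one order of magnitude
below experimental census size) and $p_0 = 0.01$.

`wf_step()` implements multinomial resampling with probabilities
proportional to frequency times reproductive output; `wf_simulate()`
iterates it along an environmental sequence, using the *previous*
generation's environment as the maternal environment (the sequence has
length `n_gen + 1`; entry one is the founding mothers' environment, so
selection first acts at generation 1). `wf_invasion()` is a vectorized
two-genotype fast path that advances all replicates in parallel with one
binomial draw per generation; replicated checks in the tests confirm that
neutral fixation equals $p_0$ and that constant-selection fixation matches
the Kimura formula within Monte Carlo error ($N = N_e = 200$,
$s \in \{0.01, 0.05\}$).

`fixation_sweep()` reproduces the strategy comparison over random fitness
draws: for each draw and each switching probability $\sigma$, stationary
transition frequencies give $G_\text{DME}$, the per-draw optimal $q^*$
gives $G_\text{RME}$, and Kimura's formula gives $U$. Because the
stationary environment is symmetric, the offspring marginal is always 1/2:
$U_\text{RME}$ is flat in $\sigma$ while $U_\text{DME}$ rises steeply,
crossing near $\sigma = 0.5$. An `adjusted` flag additionally reports
establishment-adjusted probabilities, $U_\text{DME}(1 - U_\text{RME})$
when RME has the higher geometric mean (and symmetrically for RME).

**A deliberately resolved ambiguity.** The headline comparison — the
randomizing allele fixing about one-tenth as often as the deterministic
one — cannot refer to the ratio of grid-averaged means: averaged over
$\sigma \in [0.05, 0.95]$ the ratio is ~0.5, because $U_\text{DME}$ is
essentially zero on the lower half of the grid (DME is deleterious there)
while $U_\text{RME}$ is flat. The ten-fold difference emerges where the two
strategies actually compete, at high switching rates: at $\sigma = 0.95$
(the predictable regime) `mean_u_rme / mean_u_dme` is ~0.12. The
acceptance script therefore reports the high-switching ratio, and
`fixation_sweep()` exposes both the per-$\sigma$ ratios and the
grid-averaged `overall_ratio` so either reading can be inspected.

**Illustrative endpoints are single draws.** A DME allele invading under
$\sigma = 0.95$ fixes at a median generation of ~26-27 across seeded
replicates, consistent with the illustrative single-run value of 24. The
RME invasion under $\sigma = 0.55$ is different: its brood has reproductive
output 0.704 in every normoxia generation, and because the environment is
shared by all copies, runs of normoxia eliminate the allele in roughly a
third of replicates. The unconditional replicate-mean frequency at
generation 60 is therefore ~0.49 (conditional on establishment ~0.73), and
across different realized environmental sequences the replicate mean spans
nearly the whole unit interval. A single-run endpoint such as 0.91 is a
draw from that wide distribution, not an expectation; the package reports
the faithful replicate mean and this vignette records why it sits far below
the illustrative value.

## Environmental sequence design and diagnostics

Sequences are balanced by design (30 of each environment over 60
generations). The canonical encoding is NORMOXIA = 0, ANOXIA = 1
everywhere. Lag terminology: lags are zero-based distances, so
mother-offspring comparisons (59 pairs over 60 generations) are lag 1 and
grandmother-offspring comparisons (58 pairs) are lag 2 — descriptions that
count the generations involved would call these "lag two" and "lag three".

* `make_predictable(n, k)` builds a balanced sequence with exactly `k`
  equal adjacent pairs by construction on runs (a balanced sequence with
  `k` repeats has exactly `n - k` maximal runs); run lengths are randomly
  apportioned given the seed. Feasibility is exactly
  `0 <= k <= n - 2`, and violations raise an explicit error. The
  experimental design is `(60, 3)`: repeat probability 3/59 ≈ 0.05.
* `make_unpredictable(n, k1, k2)` targets exact lag-1 (and optionally
  lag-2) repeat counts with a seeded hill climb over balance-preserving
  label swaps, accepting plateau moves, with a 1e5-proposal budget
  (the original sequences came from a bespoke program; only their lag
  statistics are specified, so any sequence matching them is valid —
  reproducing the archived sequences is a non-goal). Budget exhaustion
  reports the best counts achieved. The experimental design is `(60, 27)`:
  repeat probability 27/59 ≈ 0.46, with lag-2 targets 30/58 ≈ 0.52, 0.34
  or 0.62 for the archived variants.
* `make_constant(n)` is half anoxia then half normoxia;
  `make_markov(n, p_switch)` generates the two-state Markov environment
  used by the simulations, whose stationary transition frequencies are
  `p_switch/2` off the diagonal.

Diagnostics follow the classical time-series conventions on the 0/1
encoding: `env_autocorrelation()` is the biased, mean-centered,
lag-0-normalized estimator (`stats::acf`), which errors on constant
sequences (undefined variance); `cumulative_periodogram()` is the raw
periodogram at Fourier frequencies $j/n$, cumulated and normalized to end
at 1, with no taper and no detrending beyond mean removal — it is a
qualitative whiteness diagnostic (strict alternation puts all power at the
Nyquist frequency; white sequences track the diagonal within a
Kolmogorov-Smirnov band).

## The assay analysis pipeline

Growth rate is `l1_count / 5000` (offspring L1 per maternal L1 seeded over
one full life cycle); its natural log estimates absolute fitness. Relative
fitness is `ln(value / ancestral block mean)`, computed per thawing block
so the shared block effect cancels; zero-valued records are excluded with
a logged count before taking logs (the assays never produced them, so the
contract is ours). `population_transition_estimates()` averages replicates
within block, takes the mean over blocks, and bootstraps *blocks* — the
experimental unit — for the standard error. Record-level resampling would
ignore the within-block correlation induced by dividing every record by
the same noisy ancestral block mean and would understate uncertainty. With
~18 blocks the percentile bootstrap interval is anticonservative, so the
default interval is mean ± $t_{0.975,\,B-1}$ × bootstrap s.e.
(`ci_type = "percentile"` restores the raw percentile interval). This
replaces the mixed-model/REML machinery of a full inferential analysis by
design: cell means with a seeded block bootstrap are transparent,
dependency-free and sufficient for effect recovery; formal LMM inference
is out of scope.

`geometric_mean_fitness_assay()` aggregates per-transition fitness with
the weights a population actually experienced (1/2-1/2 on the two
off-diagonal transitions for the alternating regime; empirical
`transition_frequencies()` of the experienced sequence otherwise).
`expected_adaptation()` scores a length-$L$ sequence as
$A_s = (\prod_t w_t)^{1/L}$ — the per-generation advantage, i.e. the
$L$-th root of the product of per-transition relative fitnesses (the raw
product is also attached, as some presentations omit the root). The first
generation's maternal environment uses the *cyclic* boundary by default
($env_0 := env_L$), which keeps all $2^L$ sequences well-defined and makes
$A_s$ rotation invariant; `"prepend"` (duplicate the first environment) is
the alternative. `enumerate_adaptation()` scores all $2^{12} = 4096$
sequences with the normoxia frequency of each, supporting either
population-specific or regime-averaged relative fitness inputs (which of
the two the original analysis used is not asserted; both work).

## What the synthetic data emulate — and what they do not

`generate_assay_table()` mirrors the assay structure: 18 thawing blocks,
4 replicate populations per regime, 3 measurements per population and
treatment, with multiplicative (log-normal) block, replicate-population
and residual effects around per-transition ancestral means
(`value = ancestor_mean * exp(effect + block + pop + residual)`).
Log-normality mirrors the ln-scale analysis; Poisson L1 counts
(`generate_l1_counts()`) reflect the drop-count observable. Default truth:
ancestral growth rates ~1.5 with normoxia-hatched offspring and ~0.4-0.6
with anoxia-hatched offspring (anoxia roughly halves survival to L1), a
DME-like effect matrix (gain of 0.5 on N→A, 0.3 on N→N, cost of 0.3 on
A→A), and $\sigma_\text{block} = \sigma_\text{pop} = 0.1$,
$\sigma_\text{res} = 0.2$ on the log scale — noise magnitudes a
growth-rate assay of this design plausibly produces. The realized block
and population effects are attached to the table so recovery checks score
each population against its *own* truth (regime effect plus population
effect), the analogue of replicate populations having genuinely different
evolutionary histories. Fecundity and hatchability can be synthesized with
the same machinery; the constraint growth ≈ fecundity × hatchability is
documented, not enforced.

Passing recovery tests (absolute bias below 0.03, interval coverage at or
above 90% across 100 simulated experiments) show the pipeline is
consistent *under this generative model*. Real assays can violate it —
non-log-normal residuals, block-by-treatment interactions, counting error
beyond Poisson, within-brood heterogeneity — so the tests validate the
software and the estimator logic, not the biology.

## Numerical choices and problem sizes

* Environments are validated everywhere; degenerate inputs error with
  named causes (constant sequences in diagnostics, missing ancestor cells,
  zero reproductive output = extinction).
* Zero reproductive output on a used transition yields $G = 0$ with a
  warning, not an exception.
* Frequencies in simulations are exact multiples of $1/N$ (integer founder
  counts), so fixation is detected by equality with 1.
* Multinomial sampling across replicates uses conditional binomials (one
  `rbinom` call per genotype per generation), keeping 2 × 10^4-replicate
  neutrality checks cheap.
* Monte Carlo sizes used by the tests and the acceptance script: 10^6
  sampler draws for the 2-fold calibration; 4,000-10,000 fitness draws for
  the sweep; ~100-200 Wright-Fisher replicates for the illustrative
  invasions; 2 × 10^4 replicates for neutrality; 100 synthetic experiments
  with 1,000 bootstrap resamples for recovery. Each was chosen so that
  Monte Carlo error is small against the tolerance being checked while the
  whole suite runs in seconds.

## Known limitations

Two phenotypes and one locus only; no environment-conditional
randomization (the RME fraction is cue-independent by definition); no
mutation, recombination or dominance; the maternal environment is global;
the assay estimator is a cell-mean/bootstrap summary, not a mixed model;
and the synthetic generator's independence assumptions are idealized. The
archived experimental sequences themselves are not bundled — sequences
matching their printed lag statistics are regenerated on demand.
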