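---
title: "Measuring heterogeneity in numbers equivalent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring heterogeneity in numbers equivalent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renyihet)
```

## The measurement problem

A system's heterogeneity is the degree to which it diverges from perfect
conformity — the state in which every observation is identical. A system has
three components: an event space of distinct categories, a distance between
categories, and an abundance measure over categories (a probability
distribution once normalized). Many familiar statistics — Shannon entropy,
the Gini–Simpson index, variance — *covary* with heterogeneity, but they are
indices on incompatible scales (bits, probabilities, squared units), and
combining them can produce outright contradictions: a distribution of
psychiatric symptom profiles can simultaneously show a near-maximal
probability that two patients differ (Gini–Simpson ≈ 0.96) and an entropy at
barely half its theoretical maximum.

This package adopts a single common unit, the **numbers equivalent**: the
number of categories that a hypothetical *perfectly even* system would need
in order to be exactly as heterogeneous as the system measured. Every
headline quantity in the package either is a numbers equivalent or is
explicitly documented as an index that is not.

## The Rényi heterogeneity family

The core object is
$$\Pi_q(\mathbf p) = \Big(\sum_{i=1}^{n_c} p_i^q\Big)^{1/(1-q)}, \qquad q \ge 0,$$
the exponential of Rényi entropy, known to ecologists as the Hill numbers and
to economists as the Hannah–Kay indices. The elasticity $q$ sets the
sensitivity to rare categories:

* $q = 0$: observed richness $n_c$ (abundances ignored),
* $q \to 1$: perplexity $\exp(-\sum p_i \ln p_i)$, the effective number of
  *typical* categories,
* $q = 2$: inverse Simpson concentration $1/\sum p_i^2$, the effective
  number of *common* categories.

`renyi_heterogeneity()` implements the family, `diversity_profile()`
evaluates it over a grid of orders. Two calibration facts anchor the unit:
a uniform distribution over $n$ categories scores exactly $n$ at every
order, and the profile is non-increasing in $q$.

### Axioms as executable properties

The properties that justify the family are shipped as property-style tests
rather than as prose:

* **Transfers (Pigou–Dalton).** Moving abundance from a more- to a
  less-abundant category increases $\Pi_q$ for $q > 0$ (and Shannon
  entropy and Gini–Simpson, which also satisfy this axiom).
* **Replication.** Pooling $K$ disjoint, equally heterogeneous systems with
  equal weights multiplies $\Pi_q$ by exactly $K$. Shannon entropy instead
  *adds* $\ln K$ and the Gini–Simpson index saturates below 1 — the
  numerical demonstration of why those are indices of heterogeneity, not
  measures of it (the sphere's radius versus its volume).
* **Decomposability.** For grouped data, $\gamma = \alpha \times \beta$
  with $\beta \in [1, G]$ interpretable as the effective number of
  completely distinct groups.

The test suite exercises each over at least a thousand randomized systems
under fixed seeds.

### Decomposition conventions

`decompose_heterogeneity()` computes $\gamma$ on the pooled mixture and the
within-group $\alpha$ as a numbers-equivalent mean. At $q = 1$,
$\alpha = \exp(\sum_g w_g H_g)$ and arbitrary weights are supported. At
$q \ne 1$ the multiplicative decomposition is only well calibrated when the
group weights are equal, in which case
$\alpha = \big(\tfrac1G \sum_g \sum_i p_{gi}^q\big)^{1/(1-q)}$; the
unequal-weight case is refused with an explicit error rather than silently
approximated, because no weighting convention for it is established enough
to adopt quietly. This is a deliberately conservative design decision.

### Numerical choices

* $q = 1$ is evaluated by its analytic limit whenever $|q - 1| < 10^{-9}$;
  the naive formula suffers catastrophic cancellation in $1/(1-q)$.
  Continuity across the switch is tested
  ($|\Pi_{1\pm10^{-6}} - \Pi_1| < 10^{-4}$).
* $\sum p_i^q$ is computed in log space (log-sum-exp), so very large
  category sets and large $q$ neither underflow nor overflow.
* $0 \log 0 := 0$ throughout; zero-abundance categories are retained in
  label sets but excluded from $n_c$ and from all entropy-family sums.

## Richness estimation

Observed richness underestimates the true number of categories whenever
sampling is incomplete, badly so when many categories are rare. `chao1()`
implements the classical lower-bound correction from the singleton and
doubleton frequencies,
$$\hat n_c = \Pi_0 + \frac{f_1^2}{2 f_2} \;(f_2 > 0), \qquad
  \hat n_c = \Pi_0 + \frac{f_1 (f_1 - 1)}{2} \;(f_2 = 0),$$
always at least the observed richness. The singleton-only edge case
($f_1 = 1, f_2 = 0$), where the correction vanishes, is flagged on the
result rather than warned about, so bootstrap loops stay quiet.

For intervals, the default is a subject-level multinomial bootstrap
(1000 replicates, percentile interval, explicit seed): subjects, not
categories, are the exchangeable unit of the sampling process being
emulated. Because resamples lose rare categories, raw percentile bounds can
fall below what is logically certain; the interval is therefore truncated
to contain the point estimate and to stay at or above the observed richness
of the actual sample. A classical analytic variance with log-transformed
bounds is available for comparison (`method = "analytic"`). Both are
approximations for what is, after all, a lower bound rather than an
unbiased estimator, and the vignette's advice is to report the interval
together with the observed richness.

## Combinatorial bounds

For polythetic diagnostic rules ("at least $K$ of $N$ symptoms"),
`count_presentations()` evaluates $S(N,K) = \sum_{k=K}^N \binom{N}{k}$ in
exact integer arithmetic. `count_presentations_constrained()` extends this
to mandatory-symptom clauses ("of which at least $m$ from a designated
subset") by summing over the number of mandatory symptoms included. The
mandatory rule is encoded as the weakest reading consistent with the
classical worked examples: *total size ≥ K and at least m mandatory
members*. Every closed form is verified against `enumerate_presentations()`,
a brute-force subset enumeration refused above 20 symptoms.

## Inequality indices

`lorenz_curve()`, `gini_coefficient()`, `pietra_index()` and
`share_accounting()` measure abundance inequality *independently of event
space size* (the population principle: replicating every category leaves
them unchanged). The curve sorts categories most-abundant first, so it runs
above the diagonal; the Gini coefficient is computed geometrically from the
piecewise-linear curve ($2\,\mathrm{AUC} - 1$) and the Pietra index is the
maximum vertical gap, equal to half the total variation distance from
uniform.

One convention deserves a note: unlike the entropy-family sums, the
Lorenzian indices *retain* zero-abundance categories. A category known to
the design but holding none of the abundance is genuine inequality — the
distribution $(1, 0)$ over two categories has Gini $0.5$, not $0$ — and the
population principle itself requires replicated zero-share categories to
count toward the category axis.

## Distance-based (non-categorical) heterogeneity

When categories are not all equally different, the discrete metric
(`discrete_metric()`; 0 within, 1 between) is replaced by a chosen distance:
`jaccard_distance()` and `hamming_distance()` for binary feature profiles,
or any user-supplied symmetric matrix. `rao_quadratic_entropy()` computes
$Q = \sum_{ij} D_{ij} p_i p_j$, the abundance-weighted mean pairwise
distance. Under the discrete metric $Q$ reduces *exactly* to the
Gini–Simpson index — the algebraic bridge between the categorical and
non-categorical families, asserted to $10^{-12}$ in the tests.

$Q$ inherits the units of $D$, which makes values under different metrics
incomparable and breaks the replication principle; the package keeps it
because it is the standard building block, and demonstrates its known
pathologies instead of hiding them:

* **Pooling anomaly.** Pooling a maximally heterogeneous system with a
  degenerate one can *lower* $Q$ below the heterogeneous subset's value,
  whereas the numbers-equivalent decomposition always keeps
  $\beta = \gamma/\alpha \ge 1$. The test fixture is the discrete-metric
  pair uniform-over-4 + point-mass.
* **Functional Hill insensitivity.** `functional_hill_number()` implements
  the Q-normalized numbers-equivalent transform
  $\big(\sum_{ij} D_{ij}(p_i p_j)^q / Q\big)^{1/(2(1-q))}$ (the exact form
  is documented because the index is named in the surrounding literature
  more often than printed). Under exactly uniform abundances it collapses
  to the category count for *any* distance structure — an idiosyncratic
  blindness the test suite demonstrates directly.

Two stratification-free indices are included for completeness of the
survey: `convex_hull_volume()` (extreme-point sensitive: a single outlier
inflates it while interior density is unchanged) and `dendrogram_fd()`
(density-sensitive: total branch length of an agglomerative tree, which
*decreases* as standardized clusters separate). Their opposed behaviors on
the same point clouds are part of the test suite. The hull is implemented
for 1-D and 2-D coordinates — the planar settings where the index is
typically illustrated; higher dimensions raise an informative error.
Dendrograms default to UPGMA (average linkage), the convention of the
functional-diversity literature, with single and complete linkage exposed.
Note that duplicated points add zero branch length at their own merge under
any linkage, but only single linkage leaves all *later* merge heights
untouched.

## Time series

`normalized_spectrum()` estimates a plain periodogram over the
positive-frequency bins and normalizes it to sum to one; `spectral_entropy()`
is its Shannon entropy and `effective_num_frequencies()` its exponential —
the order-1 Rényi heterogeneity of the spectrum, i.e. the effective number
of frequency bands. The estimator is deliberately the plainest available:
the package targets bin-aligned content where all estimators agree, and the
optional linear detrend and Hann window are provided for real-world series
with trends or off-bin tones. All summaries are invariant to amplitude
scaling by construction. Constant series (and pure linear trends under
`detrend = TRUE`) are rejected as having no defined spectrum.

## The synthetic generators

All tests and examples run on seeded synthetic data
(`population_spec()` / `sample_counts()`, `sample_symptom_profiles()`,
`grouped_systems()`, `tone_series()`), emulating:

* skewed categorical abundances (geometric and Zipf shapes) — the
  many-rare-categories regime where richness correction matters; the
  default Chao-recovery study uses a geometric population of 200
  categories, decay ratio 0.95, sampled at $n = 500$, chosen so that the
  sample observes roughly a third of the population and both estimator
  branches are exercised;
* criteria-conditioned binary symptom profiles (rejection-sampled Bernoulli
  profiles in which every subject satisfies the diagnostic rule);
* grouped systems with a controlled shared fraction of categories, spanning
  disjoint (replication fixture) to identical ($\beta = 1$ fixture);
* multi-tone series with known spectral content.

Generators are pure functions of their seed (the caller's RNG state is
saved and restored), so every stochastic result in the suite is replayable.

What the generators do *not* emulate: realistic symptom covariance
(symptoms are conditionally independent given the criteria), categories
with graded similarity structure, or observation-level measurement error.
Passing tests therefore certify the measurement machinery — its algebra,
axioms, calibration and edge cases — not the clinical fidelity of any
particular synthetic population.

## Problem sizes

The shipped suite uses deliberately modest sizes so a full run stays
comfortably interactive: axiom sweeps use 1000 randomized systems of up to
60 categories; the Chao recovery study uses 200 replicates of $n = 500$;
enumeration cross-checks cover all criteria up to 9 symptoms exhaustively
plus a 12-symptom spot check; cluster/hull figures use 60-point clouds.
All scale linearly if larger studies are wanted.

## Known limitations

* Convex hull volumes above two dimensions are not implemented.
* The $q \ne 1$ decomposition requires equal group weights (by design, see
  above).
* Chao1 intervals are approximate in both offered flavors; neither claims
  exact coverage for a lower-bound estimator.
* Distance-based indices require a category stratification and a metric
  chosen *a priori*; learned or manifold-respecting metrics are out of
  scope.
* Exact integer arithmetic for the combinatorial counts holds below
  $2^{53}$; beyond that a warning is raised.
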