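---
title: "Methods: market-integration gradients and the gut microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: market-integration gradients and the gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migut)
```

## The scientific problem

Economic development changes what people own, how their houses are built,
and what they are exposed to — and, plausibly, which microbes colonise
their guts. `migut` implements a complete analysis pipeline for studies
that relate *household market integration* (measured by style-of-life
indicators) to gut-microbiome structure within a single population living
along a development gradient: five villages, two regions, on the order of
two hundred participants.

The pipeline has five statistical stages:

1. **Latent factor extraction.** Seven lifestyle indicators — five ordered
   house-construction codes (wall, floor, water access, latrine type,
   electricity access) and two item-ownership proportions (traditional
   and market item lists) — are z-scored and decomposed by
   maximum-likelihood exploratory factor analysis into latent
   market-integration factors, canonically *house modernity*,
   *subsistence items*, and *power usage*.
2. **Phylogenetic diversity.** Within-sample (alpha) diversity is Faith's
   PD: the total branch length of the phylogeny spanning a sample's taxa.
   Between-sample (beta) diversity is weighted UniFrac.
3. **Diversity regression.** PD is regressed on the factors plus age,
   rank travel time and region, with backward model selection by nested
   F-tests.
4. **Windowed beta-dispersion.** For each participant, the mean weighted
   UniFrac distance to all participants with a similar factor score
   (within 5% of the observed score range) measures local community
   heterogeneity; its regression on the score asks whether
   market-integrated people have more idiosyncratic microbiomes.
5. **Composition tests.** PERMANOVA partitions the UniFrac distance
   matrix across factors; a partial db-RDA ordination conditions out
   region first; and a per-OTU Pearson screen against the factors uses
   Benjamini–Yekutieli FDR control.

## Statistical details and conventions

### Factor analysis

The `k`-factor model `R = ΛΛᵀ + Ψ` is fitted to the sample correlation
matrix by maximum likelihood, profiling the loadings out of the
likelihood: for fixed uniquenesses `Ψ` the discrepancy is a function of
the `p − k` smallest eigenvalues of `Ψ^{-1/2} R Ψ^{-1/2}`, and the
optimiser works on `Ψ` alone, box-constrained to `[0.005, 1]` to avoid
Heywood cases, from the standard start plus four deterministic
low-discrepancy restarts. Loadings are varimax-rotated with Kaiser
normalisation and sign-fixed so each column's largest loading is
positive. Fit is judged by the Bartlett-corrected likelihood-ratio
statistic `(n − 1 − (2p+5)/6 − 2k/3)·F_min` on
`((p−k)² − (p+k))/2` degrees of freedom; `max_factors(p)` is the largest
`k` keeping that non-negative (3 for 7 indicators). Scores are regression
(Thomson) scores `X R⁻¹ Λ`. Ordinal house codes enter as numeric
z-scores — fidelity to common field practice was preferred over
polychoric machinery.

**The stopping rule.** `select_num_factors()` grows `k` from 1 and stops
either at `max_factors(p)` or when the fit test's p-value crosses 0.05.
Two directions are offered because the natural-language description of
this procedure in the field literature ("increase until the p-value is
less than 0.05") inverts the conventional logic of a goodness-of-fit
test: taken literally (`"stop_when_significant"`, the default) one stops
*because* the model fits badly; conventionally
(`"stop_when_adequate"`) one grows the model *until* it fits. On data
with genuine multi-factor structure the literal rule stops at `k = 1`,
so the pipeline itself uses the conventional direction — with
well-separated factors both the 1- and 2-factor tests reject and the
3-factor solution is selected.

### Diversity metrics

Both metrics are computed from one branch decomposition of the rooted
tree (a tips × edges incidence matrix built in a single postorder
traversal). Faith's PD sums branch lengths over edges with at least one
present descendant; by default the path to the root is included, matching
the most common implementation of rooted-tree PD. Note that PD is
presence-based even though abundances feed the pipeline — abundances
affect PD only through which taxa are present after normalisation.

Weighted UniFrac between relative-abundance vectors `p_a`, `p_b` is
`Σ_b l_b |P_a(b) − P_b(b)|` with `P_x(b)` the total abundance below
branch `b`; the normalised variant divides by
`Σ_b l_b (P_a(b) + P_b(b))`, which algebraically equals the classical
root-to-tip scaling, so the two published normalisation conventions
coincide. All pairwise distances are obtained as branch-length-weighted
Manhattan distances between branch-load vectors, one matrix product plus
one `dist()` call, which keeps a 213-sample analysis interactive.

Counts are normalised either by rarefaction (multivariate hypergeometric
subsampling to the minimum retained library, the default for the
pipeline) or by a median-of-ratios size-factor `log2` transform. Full
parametric variance-stabilisation is out of scope; rarefaction is the
default because the two approaches are expected to agree qualitatively,
and distances are computed on relative abundances with negative values
clamped at zero.

### Windowed beta-dispersion

`D_i` is the mean distance from sample `i` to all samples `j` with
`|f_j − f_i| ≤ w (max f − min f)`, excluding `i` itself; samples with an
empty window are recorded as missing and excluded from the regression,
never imputed — the per-factor regression sample sizes therefore equal
the analysed `n` minus the empty-window count, and the package checks
this reconciliation explicitly. The window is *range-relative* (a
value-relative window breaks near scores of 0) and two-sided with
half-width `w·range`; `w = 0.05` is the default and a sweep over
0.025–0.10 probes sensitivity.

**Why the slope test is a permutation test.** Neighbour counts shrink
towards the ends of the gradient, so `Var(D_i)` is largest exactly at
the high-leverage samples; the classical t-test on the slope of
`D ~ f` is then strongly anticonservative (in null simulations it
rejected at 30–40% instead of 5%). The primary p-value therefore comes
from permuting sample identities against gradient positions and
recomputing the entire windowed statistic, which is exact under
exchangeability; one permutation stream is shared across the window
grid, and the slope is evaluated as a fixed linear functional of the
permuted distance matrix so the sweep costs little more than a single
window. The classical p-value is still reported (`p_classical`) for
comparison with analyses that used it.

### Composition tests

PERMANOVA Gower-centres `−D²/2` and partitions its trace over sequential
(order-dependent) model terms via hat-matrix projections, so Euclidean
distances on a univariate response reproduce classical ANOVA F exactly.
Significance is by free permutation of sample labels with
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, which never returns zero. Partial
db-RDA projects the condition (region) out of the centred matrix first,
residualises the constraints against the condition, and
eigen-decomposes the constrained part; the constraint test permutes the
conditioned matrix, i.e. permutation under the reduced model. Inertia is
reported as sums of squares (the PERMANOVA convention); variance-scaled
ordination software reports the same quantities divided by `n − 1`.

The OTU screen computes Pearson correlations of every (normalised) OTU
against every factor score, t-tests them on `n − 2` degrees of freedom,
and applies the Benjamini–Yekutieli adjustment *jointly* across all
OTU × factor tests (`q_(i) = min(1, p_(i) · m·c(m)/i)`,
`c(m) = Σ 1/j`, monotonised from the largest rank). Zero-variance OTUs
yield missing entries, not zeros, and do not count towards `m`.

## The synthetic-data generator

Real study data are individually identifiable and deposited under
controlled sequence-archive access, so the package ships a generator
that emulates the *statistical structure* of such a cohort, with full
ground truth for power and calibration studies.

* **Cohort.** 213 participants in five villages (two in a low
  travel-time region, three across a mountain range), ages 1–100 drawn
  from a right-skewed gamma, travel rank fixed per village.
* **Latent factors.** Standard-normal scores, exactly standardised, then
  region-shifted (`+0.55, −0.40, +0.55` vs `−0.37, +0.27, −0.37`) so
  region and factors are confounded as in a real gradient.
* **Indicators.** `f·Λᵀ` plus Gaussian noise with unit total variance;
  the default `Λ` gives house codes a dominant modernity factor,
  traditional items their own factor, and electricity + market items a
  power-usage factor, with modest cross-loadings (e.g. subsistence
  households have less infrastructure access) chosen so the three-factor
  structure is actually identifiable at n = 213 — a single-indicator
  factor would not be. House codes are quantile-binned into 4 (or 3)
  ordered levels, which preserves rank correlation; ownership
  proportions are binned to 6ths and 12ths, matching item-list lengths.
* **Communities.** Each participant's accessible pool keeps all
  host-associated taxa plus a nested, modernity-dependent subset of
  "environmental" taxa (half of all taxa): the log-odds of access are
  `qlogis(0.7) + pd_slope · f₁(1 + interaction·f₃)`, so with the default
  `pd_slope = −0.6` expected PD falls as modernity rises and power usage
  amplifies the fall. Composition is Dirichlet-multinomial around a
  fixed heavy-tailed base profile with concentration
  `θ_i = 40 · exp(−disp_slope · f₁(1 + interaction·f₃))`; lower
  concentration provably increases expected pairwise distance, so
  `disp_slope = 0.5` makes high-modernity microbiomes more mutually
  dissimilar. Library sizes are lognormal (`meanlog = log(168951)`,
  `sdlog = 0.95`, truncated below at 20,843), spanning roughly
  20 thousand to a few million reads.
* **Determinism.** One master seed fans out to named sub-streams (tree,
  metadata, communities, rarefaction, each permutation test), so any
  stage can be re-run independently and identical configurations give
  byte-identical output files.

The generator does **not** emulate sequencing error, chimeras, OTU
clustering artefacts, taxon–taxon interactions, or age/diet effects on
the microbiome. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated for data with this covariance
structure — not that real gut communities satisfy the generator's
assumptions.

## Problem sizes, tolerances and numerical choices

* Oracle equivalence is asserted to 1e-10 (diversity metrics vs
  exhaustive branch enumeration on 200 random trees of ≤ 12 leaves) and
  1e-8 (PERMANOVA vs classical ANOVA on 50 random instances).
* Calibration uses 1000 replicate null cohorts of n = 213 on a fixed
  150-taxon tree with 199 permutations per test; all rejection rates at
  α = 0.05 must lie in [0.03, 0.07]. Power/sign-recovery uses 100
  replicates at the default effect sizes. The 150-taxon tree keeps a
  thousand full pipeline replicates comfortable on a laptop while
  leaving UniFrac geometry non-degenerate.
* Rank-deficient designs raise errors naming the aliased terms rather
  than silently dropping columns. Zero-length branches are legal and
  contribute zero. Empty samples are rejected. Permutation p-values are
  reproducible given a seed, and `(1 + exceed)/(1 + n_perm)` keeps them
  positive.
* Backward selection drops the least-significant droppable term while
  `p > 0.05`, respecting marginality (no main effect leaves while its
  interaction remains); the full elimination path is logged in the
  result so alternative selection schemes can be audited.

## Known limitations

* The printed-vs-conventional stopping-rule ambiguity is resolved by
  configuration, not by fiat; users comparing against analyses that used
  the literal rule should set `direction = "stop_when_significant"`.
* PD here is presence-based; analyses that fed variance-stabilised
  abundances into an abundance-weighted diversity metric would differ.
* db-RDA constraint significance uses permutation of the conditioned
  matrix; more elaborate residual-permutation schemes exist and can give
  slightly different p-values in small samples.
* The correlation screen tests linear association only; monotone
  nonlinear responses are better served by rank correlations, which the
  screen does not implement.
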