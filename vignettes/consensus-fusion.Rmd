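---
title: "Comparing data-fusion rules for ensemble-docking consensus scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing data-fusion rules for ensemble-docking consensus scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockfuse)
```

## Scope and model

Ensemble docking produces a compound × structure matrix of docking scores
(lower = better) plus a binary active/inactive label per compound.
`dockfuse` turns the per-structure scores of each compound into a single
consensus score with one of seven fusion rules, measures how well each
rule's ranking enriches actives, and tests whether the differences between
rules are statistically meaningful. This vignette records the methodological
choices behind each stage, including the ones where more than one defensible
convention exists.

## Fusion rules and score orientation

For one compound with scores $DS_1, \dots, DS_n$ the rules are the minimum,
maximum, arithmetic mean, geometric mean, harmonic mean, median, and the
Euclidean norm $\sqrt{\sum_i DS_i^2}$ of the score vector. Two conventions
needed fixing:

* **Signs in GEOM and HARM.** Docking scores are negative, so the textbook
  geometric/harmonic means are undefined or sign-ambiguous. Both are
  computed on the magnitudes and the common sign is restored:
  $\mathrm{GEOM} = s\,(\prod_i |DS_i|)^{1/n}$,
  $\mathrm{HARM} = s\, n / \sum_i |DS_i|^{-1}$ with $s$ the shared sign.
  Mixed-sign or zero inputs are a domain error rather than a silent guess.
* **Orientation of EUC.** For all-negative scores a *larger* Euclidean norm
  means more-negative, i.e. better, scores — opposite to every other rule.
  `fuse_row()` therefore negates the norm (canonicalization), so that every
  fused column shares the lower-is-better orientation before ranking.
  Without this flip the EUC ROC curve would be inverted. Positive-valued
  "higher = better" inputs are deliberately unsupported; the input contract
  is the docking convention.

On the magnitudes the arithmetic–geometric–harmonic mean inequality holds,
so for all-negative rows the canonical consensus values always satisfy
MIN ≤ SUM ≤ GEOM ≤ HARM ≤ MAX; the test suite asserts this chain on
thousands of random rows.

## Enrichment metrics

All metrics consume the canonical lower-is-better scores and are purely
rank-based (invariant under strictly monotone transforms).

* **AUC** uses the Mann–Whitney identity — the probability that a random
  active outranks a random inactive — with ties counted one half
  (midranks). This equals trapezoidal ROC integration and is deterministic
  under ties, which a sort-based sweep is not.
* **Average precision** integrates the precision–recall curve stepwise,
  $\mathrm{AP} = \sum_k (R_k - R_{k-1}) P_k$, over distinct score
  thresholds; tied compounds enter as one threshold group.
* **BEDROC** follows the Truchon–Bayly construction: the robust initial
  enhancement (RIE) is the sum of exponential weights
  $e^{-\alpha r_i / N}$ over the actives' ranks relative to its expectation
  under uniformly random ranks, and BEDROC rescales RIE to $[0,1]$ via the
  hyperbolic closed form (algebraically identical to min–max rescaling by
  RIE's attainable bounds; the tests verify both routes agree to machine
  precision). Actives at tied scores receive average ranks. The default
  $\alpha = 20$ concentrates roughly 80% of the weight on the top ~8% of
  the ranking — the "early recognition" regime a prospective screen cares
  about. $\alpha \to 0$ recovers the AUC ordering of methods.

## Sum of ranking differences

SRD compares each method's ranking with a reference ranking by Manhattan
distance. Stages, in order:

1. **Reference (minimax).** Each structure column is rank-transformed
   across compounds (removing per-structure score offsets), then an
   active's reference value is the minimum (best) of its per-structure
   ranks and an inactive's the maximum (worst): the hypothetical ideal
   method that scores actives as well and inactives as badly as any
   structure allows.
2. **Standardization.** Method columns are z-scored before the analysis.
   Because SRD is rank-based this provably cannot change any SRD value
   (asserted in the tests); the step is retained for fidelity with the
   classical SRD workflow, where columns on different scales are
   standardized as a matter of course.
3. **SRD values.** Both vectors are rank-transformed (average ranks at
   ties, so SRD values can be fractional) and
   $\mathrm{SRD} = \sum_i |r^{method}_i - r^{ref}_i|$ is normalized by the
   maximum $n^2/2$ (even $n$) or $(n^2-1)/2$ (odd $n$) to a 0–100 scale.
4. **Randomization test.** The null distribution of SRD for a uniformly
   random permutation is computed exactly for $n \le 12$ by dynamic
   programming over partial rank assignments (equivalent to full $n!$
   enumeration, which the tests brute-force up to $n = 8$), and otherwise
   by seeded Monte-Carlo sampling (default $10^5$ permutations, matching
   the exact CDF within 0.01 sup-norm at $n = 8$). The exact null assumes a
   tie-free reference; the Monte-Carlo route honours the actual (possibly
   tied) reference ranks. A method is better than random when its SRD falls
   below the null's 5th percentile.
5. **Cross-validation.** Compounds are split into seven label-stratified
   random folds. Stratification matters because with 20 actives among 709
   compounds an unstratified fold can easily contain no actives. Each
   fold's SRD is recomputed *from scratch* on the retained 6/7 of the
   compounds — column re-ranking, reference rebuild, renormalization by the
   subset's own maximum — giving seven values per method. Computing on the
   retained subset (rather than the held-out 1/7) keeps per-fold sample
   sizes large and stable; the enrichment metrics accept
   `subset = "heldout"` for the complementary convention.

## Statistical comparison

`evaluate_all()` produces the (rule × fold) grid of AUC, AP, BEDROC and
normalized SRD; `anova_tukey()` runs, per metric, a one-way ANOVA with the
fusion rule as the single factor over the per-fold values, then Tukey's HSD
on all rule pairs at family-wise α = 0.05. Cells with zero within-group
variance (e.g. duplicated structure columns) are flagged degenerate instead
of producing an undefined F. The `bubble_table()` summary averages the fold
values per rule — AUC on x, AP on y, SRD as bubble size (smaller = better),
BEDROC as colour — and `bubble_plot()` renders it with ggplot2 when
available; the CSV-friendly table is the canonical artifact so nothing
downstream depends on graphics.

## The synthetic generator

Real docking-score matrices from published screens are generally not
redistributable, so the package ships a generator whose defaults define the
evaluation conditions used throughout the tests:

$$DS_{ij} = b_i + \delta_j + \varepsilon_{ij}, \qquad
  b_i \sim N(\mu_{class(i)}, \tau^2), \quad
  \varepsilon_{ij} \sim N(0, \sigma^2)$$

* `mu_act = -12`, `mu_inact = -10` (dimensionless docking-score units):
  a class gap of 2 in a realistic score range. The means sit far enough
  below zero that simulated scores are negative with overwhelming
  probability, respecting the uniform-sign domain of GEOM/HARM.
* `tau = 1`, `sigma = 1`: equal compound-level and structure-level noise,
  giving inter-structure correlation $\tau^2/(\tau^2+\sigma^2) = 0.5$ and a
  single-structure AUC of $\Phi(2/\sqrt{2\cdot 2}) \approx 0.76$; fusing
  five structures by SUM raises the analytic AUC to
  $\Phi(2/\sqrt{2(1+1/5)}) \approx 0.90$ — the averaging mechanism by which
  fusion helps.
* `delta`: per-structure offsets drawn once per preset from $N(0,1)$ with a
  fixed sub-seed, so the rank transform preceding reference construction
  has real work to do. Presets `jak1`, `jak2`, `5ht6`, `alr2`, `er` mirror
  published dataset compositions exactly (e.g. `jak2`: 82 actives, 1437
  inactives, 5 structures; `5ht6`: 20/689/9).

`expected_auc_single()` exposes the closed-form single-structure and
SUM-fusion AUCs, which the tests use to calibrate the simulator at
$N = 2000$ within three Monte-Carlo standard errors (Hanley–McNeil).

**What the generator does not emulate.** Scores are Gaussian and
homoscedastic: no heavy tails, no chemotype clustering among actives, no
decoy property matching, no compound-specific structure preferences. In
particular the model is symmetric around each compound's latent quality, so
the MIN and MAX rules are exchangeable in distribution — whichever of the
two trails at a given seed is a draw, whereas in real screens the asymmetry
of binding (an active needs only one well-fitting conformation) is what
systematically penalizes MAX. Passing the pipeline's tests on synthetic
data therefore demonstrates correctness of the machinery and of the
mean-versus-extreme ordering (the mean-type rules reliably beat both
extreme rules here), not a quantitative prediction for any particular
target.

## Numerical choices and degenerate inputs

* Ties: average (mid) ranks everywhere; deterministic, no random
  tie-breaking anywhere in the pipeline.
* Missing scores (a compound that failed to dock against one structure)
  are a hard error by default; `allow_missing = TRUE` stores `NA` and each
  fusion rule then aggregates over the available values only.
* All randomness (simulation, folds, Monte-Carlo null) flows from explicit
  integer seed arguments; `evaluate_all()` is bit-reproducible given its
  inputs.
* Problem sizes used by the test suite: exhaustive permutation oracles up
  to $n = 8$; Monte-Carlo null checks at $10^5$ draws; generator
  calibration at 2000 compounds; the full qualitative benchmark on the
  JAK2-like preset (1519 compounds, 5 structures, 7 folds). These sizes
  make the checks sharp while keeping a full run of the suite under a
  minute on a laptop.

## Limitations

* The package evaluates fusion rules retrospectively; it does not select
  structure ensembles, dock, or learn weighted consensus models.
* Cutoff-based fusion rules (ANZ/MNZ) and reciprocal-rank fusion are out of
  scope: the former require an arbitrary score cutoff, and the latter is
  known to behave erratically on full (uncut) screening datasets.
* The exact SRD null is limited to $n \le 12$; beyond that the seeded
  Monte-Carlo null is used, with sampling error of order
  $10^{-3}$ in the CDF at the default draw count.
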