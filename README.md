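# dockfuse

Consensus scoring for ensemble docking by rank-based data fusion, with a
full statistical benchmark of the fusion rules.

## The problem

Ensemble docking docks each ligand into several conformationally distinct
structures of the same target to partly account for protein flexibility.
That leaves one docking score per (compound, structure) pair, and a single
consensus score per compound must be produced by **data fusion** before the
hit list can be ranked. The *de facto* standard is to keep the best
(minimum) score, but that is only one of several defensible rules, and
which rule actually enriches actives best is an empirical question.

`dockfuse` is aimed at virtual-screening practitioners who want to choose a
fusion rule on retrospective data instead of by habit. It implements:

- **Seven fusion rules** applied to the per-structure scores
  `DS_1 … DS_n` of each compound (docking convention: lower = better):

  | rule | consensus |
  |------|-----------|
  | MIN / MAX | min(DS_i), max(DS_i) |
  | SUM  | arithmetic mean |
  | GEOM | sign · (∏\|DS_i\|)^(1/n) |
  | HARM | sign · n / ∑ 1/\|DS_i\| |
  | MED  | median |
  | EUC  | √(∑ DS_i²), negated so lower = better |

  Every fused column is canonicalized to the lower-is-better orientation
  before ranking.

- **Enrichment metrics** for a labelled (active/decoy) screen: ROC **AUC**
  (Mann–Whitney formulation, ties at midrank), **average precision** (step
  integration of the precision–recall curve) and **BEDROC** (Truchon–Bayly
  exponentially rank-weighted RIE rescaled to [0, 1], default α = 20).

- **Sum of ranking differences (SRD)**: Manhattan distance between each
  method's rank vector and a *minimax* reference (best single-structure
  rank for actives, worst for inactives), normalized to 0–100, with an
  exact or Monte-Carlo random-ranking null distribution (randomization
  test) and sevenfold stratified cross-validation.

- **Method comparison**: one-way ANOVA (fusion rule as factor) and Tukey
  HSD post-hoc tests on the per-fold AUC / AP / BEDROC / SRD values, plus a
  4D *bubble table* (AUC × AP, SRD as size, BEDROC as colour).

- A **Gaussian synthetic-data generator**
  (`DS_ij = b_i + δ_j + ε_ij`) with presets mirroring published
  screen compositions (e.g. 82 actives vs 1437 inactives over 5
  structures), so the whole pipeline is testable without proprietary
  docking data.

## Worked example

```r
library(dockfuse)

cfg <- preset_config("jak2", seed = 42)   # 82 actives, 1437 inactives, 5 structures
m   <- simulate_scores(cfg)
t   <- evaluate_all(m, k = 7, seed = 42)  # 7 rules x 7 folds x 4 metrics

print(bubble_table(t), digits = 3)
#>   rule   auc    ap srd_norm bedroc
#> 1  EUC 0.903 0.434     19.7  0.545
#> 7  SUM 0.903 0.436     18.7  0.547
#> 2 GEOM 0.902 0.442     17.9  0.551
#> 3 HARM 0.901 0.442     17.2  0.552
#> 5  MED 0.870 0.386     27.2  0.501
#> 4  MAX 0.859 0.387     21.9  0.518
#> 6  MIN 0.852 0.287     33.7  0.398

attr(t, "srd")
#> SRD analysis of 7 methods over 1519 compounds
#>      srd_norm cv_mean cv_sd beats_random
#> HARM    17.17   17.19  0.16         TRUE
#> GEOM    17.84   17.86  0.14         TRUE
#> SUM     18.72   18.74  0.15         TRUE
#> EUC     19.69   19.71  0.17         TRUE
#> MAX     21.85   21.86  0.35         TRUE
#> MED     27.22   27.22  0.19         TRUE
#> MIN     33.74   33.75  0.21         TRUE
#> random-ranking 5% threshold (normalized): 64.88

anova_tukey(t)
#> One-way ANOVA (rule as factor):
#>    metric         F            p degenerate
#>       auc  136.9090 6.152343e-26      FALSE
#>        ap  113.4027 2.554063e-24      FALSE
#>    bedroc  108.7274 5.839340e-24      FALSE
#>  srd_norm 5975.2022 6.841098e-60      FALSE
#> Tukey HSD at alpha = 0.05 - significant pairs:
#>   ap: 14/21  auc: 14/21  bedroc: 14/21  srd_norm: 21/21
```

Reading: all seven rules rank compounds far better than random (the
normalized SRD of every rule is well below the null's 5% threshold of
64.9). The mean-type rules (GEOM, HARM, SUM, EUC) dominate on every
metric; the geometric and harmonic means are the most consistent with the
ideal minimax reference, while the extreme-value rules (MIN here, MAX at
other seeds — the two are exchangeable under the symmetric generator) trail
on early enrichment (BEDROC) and AP. The rule factor is highly significant
for all four metrics.

Scores can also come from files instead of the generator:
`read_score_matrix("scores.csv")` expects a
`compound_id,label,<structure…>` header. A thin command-line front-end with
`simulate`, `fuse` and `benchmark` subcommands ships in
`inst/scripts/dockfuse.R`.

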