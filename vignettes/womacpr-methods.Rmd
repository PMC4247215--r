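---
title: "Deriving and validating WOMAC-based prediction rules: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating WOMAC-based prediction rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(womacpr)
```

This vignette is the package's account of its statistical content: the
scoring and outcome conventions, the tree engine, the rule formalism,
the validity statistics, the bootstrap, and the synthetic cohort
generator — with the reasoning behind every choice that was genuinely
open.

## WOMAC scoring

The WOMAC osteoarthritis index has 24 items — 5 pain, 2 stiffness, 17
physical function — each answered on a 5-level Likert scale coded 0
(none) to 4 (extreme). The published answer categories fix the labels
but not the numeric coding; 0–4 is the standard LK-format convention and
is hard-coded. Subscales are standardized to 0–100 with 0 best:
\[ \mathrm{score} = \frac{\sum_j x_j}{4k} \times 100, \qquad k \in \{5, 2, 17\}. \]

**Missing items.** Following standard user-guide practice, a subscale
with at least 80% of its items answered has its missing items imputed
with the mean of the answered ones; below that threshold the subscale
(and hence the total) is invalid. The 80% floor and the convention are
arguments (`min_present`), not constants.

**The total score.** Two conventions circulate: the sum of all 24 items
over 96, and the unweighted mean of the three standardized subscales.
They differ because the stiffness subscale has only 2 items (weight 2/24
versus 1/3). For the reference cohort this package is calibrated
against, the printed subscale means (53.1, 59.3, 53.5 at baseline) are
consistent with the printed total (55.3) only under the
mean-of-subscales convention — (53.1 + 59.3 + 53.5)/3 = 55.3, while the
item-sum total would be 53.9 — so mean-of-subscales is the default and
the item-sum variant remains available (`total = "sum_items"`).

## Outcome definition

There is no consensus definition of a poor TKA outcome. The package
uses the last-quintile construction: a patient is `poor` when the
six-month total exceeds the cohort's empirical 80th percentile. Two
sub-choices are isolated and configurable:

- **Percentile convention**: linear interpolation between closest order
  statistics, position \(h = (n-1)p + 1\) — the default of most
  statistical software (`stats::quantile` type 7).
- **Tie handling**: strictly greater than the cutoff by default
  (`strict = TRUE`); the source material is ambiguous between `>` and
  `≥`, and with 0–100 scores built from 24 ordinal items, ties at the
  cutoff do occur. Strictness changes only tied patients.

## The tree engine

Rule derivation uses classification trees grown by recursive
partitioning with the Gini heterogeneity criterion
\(G = 1 - \sum_k p_k^2\). Design decisions:

- **Binary, order-respecting splits** `value ≤ t`, `t ∈ {0,…,3}`, so a
  split never separates non-adjacent answer levels. Every (predictor,
  threshold) pair is enumerated; the split maximizing the weighted
  decrease \(\Delta = G(\mathrm{parent}) - \tfrac{n_L}{n} G(L) -
  \tfrac{n_R}{n} G(R)\) wins. With class weights, all counts entering
  \(G\) and the node sizes are weighted.
- **Deterministic tie-breaks**: first predictor in the caller's order,
  then the lowest threshold; a candidate must beat the incumbent by more
  than 1e-12 to replace it. Determinism was preferred over fidelity to
  any particular legacy implementation whose internals are unpublished.
- **Stopping rules** (`treeControl`): `min_parent` (default 10 rows to
  attempt a split), `min_child` (5), `max_depth` (5), `min_decrease`
  (1e-4). Defaults are deliberately permissive; the derivation pipeline
  overrides them (below).
- **No pruning, no internal train/test split** — with cohorts of ~141
  patients the entire sample is the training set, and honesty about
  optimism is delegated to the bootstrap.
- **No surrogate splits**: a record missing a tested item is
  unclassifiable by design; missingness is handled upstream by the
  scoring module's imputation.
- **Class weights**: the leaf label is the weighted majority, ties going
  to `at_risk` — a sensitivity-first default appropriate for a screening
  rule. Weighting `poor` by 4 makes the weighted majority the Bayes rule
  for a 20%-prevalence outcome (a leaf is labelled at-risk exactly when
  its estimated poor-outcome probability exceeds 0.2).

## Sequential rules

A fitted tree flattens into its clinical form: an ordered list of
questions, each routing every answer level to a later question or to a
terminal class (`at_risk` / `not_at_risk`). Jumps are forward-only, so
every answer pattern terminates; `flattenTree` ∘ `applyRule` reproduces
the tree's predictions exactly (this equivalence is tested by exhaustive
sweeps over all answer combinations of the tested items).

**Selection policy.** Among candidate rules, those with specificity
below a floor (default 0.70) are discarded; the highest-sensitivity
survivor wins, with ties broken by fewer questions, then fewer distinct
items, then input order. The floor operationalizes "acceptable
specificity" for a screening instrument whose priority is catching
future poor outcomes.

**The derivation pipeline** (`deriveRule`) is two-stage, mirroring how
such rules are built in practice — an automatic pass over all
predictors, then a restriction to a small eligible candidate set:

1. **Screening**: trees are grown on 25 bootstrap resamples and each
   predictor's node-size-weighted Gini decrease accumulated
   (`screenItems`); the top `n_items` (default 5, the size of a bedside
   questionnaire) are retained. Bagging is essential: single-tree
   importance rankings are noisy, and correlated items can eclipse
   genuinely predictive ones in any one fit.
2. **Candidate ladder**: full-sample trees at depths 1–6 on the screened
   items (control: `min_parent` 20, `min_child` 10, `min_decrease`
   1e-3, poor-class weight 4), flattened and scored, with the selection
   policy choosing the final rule.

## Diagnostic validity

All metrics derive from the 2×2 table (`tp` = predicted at-risk and
actually poor):

- Proportions (Se, Sp, PPV, NPV) carry **Wilson score intervals** by
  default. The Wilson interval inverts the score test, stays inside
  [0, 1], and behaves well at the small denominators typical here
  (28 poor outcomes); it also reproduces, at one decimal, the intervals
  printed for the reference table, which an exact Clopper–Pearson
  interval does not. Clopper–Pearson is available
  (`ci_method = "clopper-pearson"`).
- Likelihood ratios use the footnote identities LR+ = Se/(1−Sp),
  LR− = (1−Se)/Sp with **Simel log-method** intervals,
  \(\exp(\ln LR \pm z\,SE(\ln LR))\),
  \(SE^2(\ln LR^+) = \frac{1-Se}{n_1 Se} + \frac{Sp}{n_0 (1-Sp)}\) and
  symmetrically for LR−. Degenerate cells flag the ratio undefined
  rather than fabricating an interval.
- The AUC of a single binary rule is (Se + Sp)/2 — the rule's ROC curve
  has one interior vertex — with a Hanley–McNeil interval for context;
  the point estimate is the meaningful quantity.
- `cohortAccounting` computes the standard flow proportions
  (eligibility, participation crediting unknown-eligibility patients at
  the observed eligibility rate, and follow-up).

## Bootstrap internal validation

`bootstrapValidate` implements the fixed-rule bootstrap: patients are
resampled with replacement, the panel recomputed from the *fixed*
predictions, and percentile (2.5/97.5) bounds reported alongside the
original-sample point estimates. Point estimates are deliberately those
of the original sample — resampling a fixed classification cannot move
them, which is why both columns of a derivation study's validation table
share identical point estimates. Choices:

- **Percentile bounds** by default; a normal-approximation alternative
  (point ± z·bootstrap SE) sits behind `interval = "normal"`. Both
  bracket small-sample metrics similarly; percentile bounds respect the
  [0, 1] range.
- **Undefined resamples** (e.g. no actual-positive patients drawn) are
  excluded from that metric's percentiles and reported in
  `n_undefined`, never silently imputed.
- **Reproducibility**: a seed is mandatory, the RNG
  (Mersenne-Twister/Inversion) is pinned and recorded in the output, and
  the caller's RNG state is restored.
- An optimism-style refit bootstrap (re-deriving the rule per resample)
  is intentionally out of scope; the package validates a *fixed* rule.

## The synthetic cohort generator

No patient-level data ship with the package; `generateCohort` emulates a
TKA wait-list cohort well enough to exercise every pipeline stage.

**Latent-severity item model.** Patient \(i\) draws a baseline latent
severity \(L_i \sim N(55.7, 11.6)\) on the 0–100 score scale. Item \(j\)
at a timepoint is the number of fixed thresholds {20, 40, 60, 80}
exceeded by \(L_i + s_{g(j),t} + e_{ij}\), with \(e_{ij} \sim N(0, 20)\)
item noise and \(s_{g,t}\) a per-subscale, per-timepoint shift. This
cumulative-threshold construction is the simplest mechanism that yields
correlated 5-level ordinal items with controllable marginals. Six-month
severity applies partial persistence and an improvement draw:
\[ L^{6m}_i = \mu_b - \mu_{imp} + \rho\,(L_i - \mu_b) + \delta\,\mathbb{1}[\text{flagged}_i] - \varepsilon_i,\]
with persistence \(\rho = 0.45\), improvement mean 30.1 and residual SD
10.4. Partial persistence (regression to the mean — sicker patients
improve more) is required: with \(\rho = 1\) the implied
baseline/six-month correlation (~0.9) cannot reproduce both the
six-month dispersion and the change-score dispersion of a realistic
cohort.

**Calibration targets.** The defaults were fixed once, by simulation at
n = 30,000, to match a reference TKA cohort: baseline total 55.3
(SD 15.2), six-month total 28.0 (SD 16.3), mean change −27.3 (SD 15.8),
subscale means 53.1/59.3/53.5 baseline and 22.5/33.3/28.1 at six
months, and covariate marginals (age 66 ± 9.5, 66% female, BMI
31.2 ± 6.2, psychological distress 7.2 ± 7.0 on 0–42, 52% high social
support, comorbidity burden 6.5 ± 2.2, 72% contralateral knee pain,
symptom duration 7.9 ± 8.1 years). Skewed covariates use gamma or
log-normal marginals so that their means and SDs match without
truncation bias. Covariates carry no outcome signal by default,
mirroring a derivation in which the final rule used WOMAC items only.

**The planted rule.** A bundled five-item sequential rule (taking off
socks F11, toilet F15 asked at two thresholds, morning stiffness S1,
rising from bed F10, light domestic duties F17) labels ~39% of patients
at-risk at baseline. Flagged patients receive the additive six-month
shift \(\delta\); `calibrateRuleEffect` solves for \(\delta\) by root
finding on a single large simulated cohort (shared base draws make the
objective smooth) so that, against the quintile outcome, the planted
rule attains sensitivity 0.82 — flag prevalence then pins specificity
near 0.72 through the prevalence identity. The packaged default is
\(\delta = 13.59\) (achieved Se 0.820, Sp 0.733 at n = 30,000). The
rule's thresholds are calibrated to this generator and are clearly
marked a synthetic stand-in, not a published instrument; its qualitative
anchors (a mild-difficulty toilet answer routing toward risk early, a
severe-difficulty answer on the same item routing away later, all-none
mapping to not-at-risk, all-extreme to at-risk) are preserved.

**Design of the rule and the dependence structure.** Two generator
properties are in tension: heavy label noise (the quintile outcome
agrees with the flag only at Se/Sp ≈ 0.82/0.72, i.e. PPV ≈ 0.42) and
recoverability of the planted items by the derivation pipeline. The
planted rule is therefore a decision list giving each item one direct
at-risk trigger of comparable reach, with weaker-signal items asked
earlier, and the item noise SD (20) keeps inter-item correlation modest
so that proxy items cannot eclipse the genuinely predictive ones. Both
are free choices — the reference marginals constrain neither the exact
answer-pattern rule nor the dependence structure — and are documented
here precisely because they were made, once, with recoverability in
mind.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: item-level effects beyond a single latent
dimension (real WOMAC items have item-specific difficulty and
discrimination), informative missingness (generated cohorts are
complete), covariate–outcome confounding, floor/ceiling clustering of
real questionnaires, and any longitudinal structure beyond two
timepoints. Recovery results on synthetic cohorts say the pipeline finds
a rule *of the planted form under the planted noise model* — not that a
five-item rule is recoverable from any real cohort of this size.

## Numerical choices and degenerate inputs

- Quantile type 7 everywhere a percentile is computed (cutoffs,
  bootstrap bounds), for consistency with the software default.
- Split tie tolerance 1e-12; with integer counts at the sample sizes
  involved, genuinely distinct Gini decreases differ by far more.
- Pure nodes, empty predictor sets, zero denominators, degenerate 2×2
  margins and all-one-class cohorts raise typed errors or flagged
  `NA`s — never silent zeros.
- Seeds: every stochastic routine takes an explicit seed, uses a local
  RNG scope, and restores the caller's `.Random.seed`.
- Problem sizes in the shipped tests were chosen to exercise the
  asymptotics that matter (marginal calibration at n = 5,000–8,000,
  recovery at n = 2,000 over 20 replicates, engine-versus-oracle
  equivalence on 100 small datasets) while keeping a full run in the
  low minutes on one core.

## Known limitations

- The tree engine is greedy: it matches exhaustive level-wise split
  enumeration exactly (tested), but no greedy tree is guaranteed to find
  the globally misclassification-optimal tree of a given depth.
- AUC inference for a single binary rule is of limited value; the
  Hanley–McNeil interval is provided for completeness only.
- The selection policy compares training-sample validity; with small
  cohorts the selected rule's training sensitivity is optimistic, which
  the fixed-rule bootstrap quantifies only partially (it does not refit).
- `n_items = 5` in the default derivation encodes an ease-of-use prior,
  not a statistical optimum.
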