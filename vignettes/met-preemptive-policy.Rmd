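---
title: "Mining MET records and modelling a pre-emptive fluid policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MET records and modelling a pre-emptive fluid policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metminer)
```

## The setting

A hospital Medical Emergency Team (MET) is activated whenever a patient
meets one of a closed list of physiological calling criteria.  Each
activation is logged: the triggering criterion (as a categorical label —
the source systems record *which* criterion fired, not the underlying
vital-sign value), the ward, the therapies given, and the immediate
outcome.  Admission systems contribute demographics, the admitting
clinical unit, a chapter-level diagnosis code, and dates.

`metminer` asks of such records: *is there a patient group whose MET
calls are so stereotyped that the usual treatment could be started by
ward staff immediately, without activating the team?* — and, for a
candidate rule, *what would its deployment have changed, counted against
a held-out period?*

The package works at two analysis levels.  Development analyses use one
record per patient — the **first** call of the admission, with ties on
the timestamp broken by the lexically smallest call id — because repeat
calls by the same patient are strongly dependent.  Counterfactual
accounting uses the full call stream.

## Association rule mining

The discovery engine searches all rules `A → c` where the consequent
`c` is a target item (here: intravenous fluid at the first call) and
the antecedent `A` is a set of one to three items over the categorical
attributes (trigger, ward, unit, diagnosis, other interventions,
outcome flags).  For a rule with `n` records, cover count `|A|`,
support count `|A ∧ c|` and consequent count `|c|`:

* strength (confidence) = `|A ∧ c| / |A|`
* lift = strength ÷ `(|c|/n)`
* **leverage** = `|A ∧ c|/n − (|A|/n)(|c|/n)`

Leverage — the excess joint frequency over what independence would
predict — is the default ranking measure: it directly expresses
"co-occurring more than chance", favours combinations that are both
common and discriminative, and is bounded in `[-0.25, 0.25]`.  Lift and
strength favour rare-but-pure rules; all five classical measures
(leverage, lift, strength, support, coverage) are available in
`mining_config()`.

### Guarding against spurious rules

Exhaustively scoring every antecedent up to size three performs tens of
thousands of implicit tests, so two filters are applied:

1. **Productivity.**  A rule must genuinely improve on every immediate
   generalisation (its antecedent minus one item; for single-item
   antecedents, the empty antecedent whose strength is the consequent
   base rate).  For each generalisation `G` the test is the one-sided
   Fisher/hypergeometric tail for the rule's support within `G`'s
   cover; the rule's p-value is the *maximum* across generalisations.
   This kills the classic artefact where an irrelevant item rides on a
   strong parent rule.
2. **Bonferroni.**  A rule is significant iff its productivity p-value
   is at most `alpha / S`, where `S` is the exact number of candidate
   (antecedent, consequent) pairs in the configured search space —
   counted combinatorially for the given matrix and size cap, i.e. the
   number of tests this search could perform, not a notional universe.

Under a null of independent columns this controls the probability of
reporting *any* rule at `alpha`; the test suite verifies familywise
error ≤ 0.05 over 500 null replicates.

### Search and admissibility

At the scale this package targets (≤ a few hundred item columns, tens
of thousands of rows), counts for all candidates are computed
vectorised: single-item counts by column sums, pair counts by
`crossprod`, triple counts by `crossprod` on per-item row subsets.  On
top of this, an admissible pruning step skips the triple expansion of a
base item when a leverage upper bound shows no specialisation can reach
the provisional k-th best significant leverage.  The bound uses the
fact that a specialisation's support can only shrink and its cover is
at least its support:

`leverage(A ∪ X → c) ≤ (|A ∧ c|/n) (1 − |c|/n)`.

Pruning therefore never changes results — `exhaustive = TRUE` disables
it and the suite asserts bit-identical output, and equality with an
independent brute-force oracle on dozens of random instances.  Ties in
the ranking are broken deterministically: smaller antecedent first,
then lexical order.

## The classical battery

Mining output is validated with conventional statistics:

* `odds_ratio()` — cross-product 2×2 odds ratio; when any cell is zero
  all four cells get +0.5 (Haldane–Anscombe) so the estimate and its
  Woolf log-normal interval stay finite.
* `compare_groups()` — one row per variable.  Categorical: χ² without
  continuity correction, switching to Fisher's exact test when any
  expected cell is < 5.  Continuous: Wilcoxon rank-sum by default; a
  Welch t-test only when both groups pass a deterministic normality
  screen (n ≥ 30, non-zero variance, |skewness| ≤ 1).  "As appropriate
  for the distribution" is not a reproducible policy; this screen is.
  No multiplicity adjustment is applied in this battery, by design.
* `fit_logistic()` — `stats::glm` binomial fit, odds ratios with Wald
  95% intervals (matching standard `glm` reporting; profile-likelihood
  intervals would differ in the third decimal here).  Separation is
  flagged (`converged = FALSE`) rather than silently reported.  The
  default model is the development model: fluid at the first call on
  respiratory-ward, cardiac-diagnosis and heart-failure-unit
  indicators, restricted to first-call sole-hypotension patients.

## The policy and its counterfactual

`policy_config()` encodes the decision rule: a qualifying trigger
(default: hypotension as the *sole* criterion), minus categorical
exclusions (respiratory ward, circulatory/cardiac diagnosis,
heart-failure unit).  Sole-trigger matching is the default because the
development counts treat combination calls as a separate category and
the test-period denominators match the sole-criterion reading;
`require_sole_trigger = FALSE` is available for sensitivity analysis.
`decide()` is pure: eligibility iff the trigger condition holds and no
exclusion matches, with every violated exclusion listed.

`counterfactual()` removes from the call stream **all**
trigger-matched calls of policy-eligible patients (eligibility judged
on the first call), then recomputes totals.  Scoping averted calls to
the whole history — not just the first call — is the one reading under
which a cohort's call-level and patient-level reductions can be
simultaneously consistent: a patient only leaves the "patients with at
least one MET call" count if *no* calls remain.  The published impact
arithmetic for the test period (2,541 of 3,697 hypotension calls and
1,448 of 7,106 patients removed) has exactly this structure.  The
confusion matrix crosses the policy's prediction with the fluid
actually recorded at the first call; reported percentages are rounded
to one decimal place while exact rationals are kept internally.
Outcome comparisons between true and false positives
(`compare_tp_fp()`) are descriptive only — no causal claim is attached.

## Synthetic cohorts

`generate_cohort()` exists so every stage is testable without any
hospital data.  Its defaults *are* the study conditions:

| quantity | default | source of the value |
|---|---|---|
| first-call trigger categories | 20-category table (sole hypotension 2459/7936, …) | published frequency table |
| unit / ward / diagnosis composition | hypotension-cohort proportions (heart failure 125/2459, respiratory ward 67/2459, cardiac diagnosis 562/2459) | published comparison table |
| fluid at hypotension calls | logistic: log-odds `log(0.41)`, `log(0.61)`, `log(0.29)` for ward/diagnosis/unit; intercept calibrated so the marginal rate is 0.70 | published adjusted odds ratios and marginal rate |
| fluid at other calls | 739/5477 | published comparison |
| calls per patient | shifted Poisson, mean 13656/7936 | published totals; the simplest distribution with guaranteed minimum 1 and the observed mean |
| in-hospital mortality | 0.05 sole-hypotension first call, 0.11 otherwise | published outcome rates |
| length of stay | log-normal, median 9, IQR 4–17 days (quantile-matched, ceiling to whole days) | published medians/IQRs |
| laboratory values | log-normals quantile-matched to the published medians/IQRs | plausibility only |

The intercept calibration solves
`E[plogis(b0 + βᵀx)] = 0.70` by `uniroot` over the eight covariate
combinations under independent covariate draws.  Covariates are drawn
independently — the generator makes no attempt to model unit–diagnosis
correlation, seasonal call-rate trends, per-call vital-sign dynamics,
or informative timing.  Consequently, passing tests demonstrate that
the *pipeline* is correct under the stated margins, not that the
generator is a faithful simulator of ward physiology.  A single seeded
RNG stream drives each run (`(seed, params)` fully determines the
cohort, and the caller's RNG state is restored).

`build_fixture()` is the deterministic counterpart: block-assigned
cohorts whose recomputed margins equal printed summary-table counts
*exactly*, including the joint structure needed by the impact
arithmetic (eligible patients carry hypotension-only call histories).
Joint distributions beyond the printed margins are arbitrary, and two
printed cells that contradict the record model's own invariants are not
reproduced: "advice or consult only" is exclusive of every other
intervention, so the advice-only count inside the fluid-given column is
set to zero, and the patient partition sizes always sum to the cohort
size.

## Numerical and testing choices

* Multi-valued CSV cells are stored sorted and de-duplicated, so
  writing is byte-stable and round-trips are identities.
* Hypergeometric tails come from `stats::phyper`; the independent test
  oracle uses `stats::fisher.test` so the two routes never share code.
* Problem sizes: moment checks use single cohorts of 20,000 patients
  with 99% binomial bands; parameter-recovery uses 200 replicates of
  8,000 patients (replicate seeds drawn once from a base seed);
  mining-vs-oracle equivalence uses 50 random instances of ≤ 12 columns
  and ≤ 500 rows; familywise-error simulation uses 500 null replicates.
  These sizes give Monte-Carlo error comfortably below the asserted
  tolerances while keeping a full run around a minute and a half.
* Wald coverage of a 95% interval is asserted at ≥ 93% over 200
  replicates; long-run coverage measured over 800 replicates is ≈ 0.956,
  so the margin accommodates batch-level Monte-Carlo noise.

## Known limitations

* Trigger labels are categorical; no numeric blood-pressure threshold
  can be evaluated, including any lower "still call the MET" safety
  bound.
* The counterfactual holds recorded outcomes fixed; it counts calls,
  and cannot say what earlier fluid would have done to outcomes.
* The generator's independence assumptions understate real-world
  confounding; refitting on generated data recovers the configured
  coefficients precisely *because* the model is correctly specified
  there.
* Margin-matched fixtures pin joint cells that the printed tables do
  not constrain; analyses of cells beyond the reproduced margins are
  reconstructions, not data.
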