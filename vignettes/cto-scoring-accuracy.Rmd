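---
title: "Complexity scores and diagnostic accuracy for hybrid CTO PCI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity scores and diagnostic accuracy for hybrid CTO PCI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctohybrid)
```

## The problem

A chronic total occlusion (CTO) is a completely blocked coronary artery
(TIMI flow grade 0) of at least three months' standing. Percutaneous
recanalisation of a CTO is among the hardest procedures in interventional
cardiology, and operators grade lesion difficulty beforehand with additive
point scores read either from invasive angiography (J-CTO) or, increasingly,
from coronary CT angiography (CCTA): CT-RECTOR, KCCT, and the CCTA
re-readings of J-CTO and RECHARGE. Under the *hybrid algorithm* the operator
starts with antegrade wiring (AW) and escalates, as time accrues, through
antegrade dissection and re-entry (ADR), retrograde wiring (RW) and
retrograde dissection and re-entry (RDR).

This package computes the five scores from per-lesion feature tables,
derives the procedural endpoints of a hybrid-algorithm case series, and
evaluates how well each score predicts each endpoint, with ROC/AUC analysis
under DeLong inference. Because patient-level data of this kind are
confidential, the package also ships a deterministic 110-lesion count
fixture (encoding a published cohort's procedural counts) and a synthetic
cohort generator, so every stage of the analysis is runnable and testable
end to end.

## Scores

All five scores are sums of binary (or, for KCCT calcification, ordinal)
risk indicators:

| System | Components (1 point each unless noted) | Max |
|---|---|---|
| CT-RECTOR | multiple occlusions; blunt cap at entry *or* exit; severe calcification; bend > 45°; duration > 12 mo/unknown; reattempt | 6 |
| KCCT | proximal blunt cap; proximal side branch; length ≥ 15 mm; bend > 45°; duration > 12 mo/unknown; reattempt; calcification (severe peripheral = 1, central = 2) | 8 |
| J-CTO (CCTA) | proximal blunt cap; length ≥ 20 mm; severe calcification; bend > 45°; reattempt | 5 |
| RECHARGE (CCTA) | proximal blunt cap; length ≥ 20 mm; severe calcification; bend > 45°; diseased distal landing zone; prior CABG to vessel | 6 |
| J-CTO (angio) | blunt stump; any calcification; bend > 45°; length ≥ 20 mm; reattempt | 5 |

Decisions that were genuinely open, and how they were settled:

* **KCCT calcification is an exclusive ladder.** The grade definitions
  ("either severe peripheral … or central") read as alternatives, so
  central calcification contributes 2 points, never 1 + 2. The ladder is
  `none < present_nonsevere < severe_peripheral < central`, with central
  requiring a 360° arc *and* 100% cross-sectional area (CSA), and severe
  peripheral an arc ≥ 180° with area ≥ 50% CSA.
* **"Severe calcification" outside KCCT is area-only** (calcified area
  ≥ 50% of CSA, no arc requirement), since the three scores that use it are
  defined by that single criterion.
* **Threshold inclusivity is literal**: length thresholds "≥ 15 mm" and
  "≥ 20 mm" are inclusive; "> 45°" and "> 50%" are strict. The test suite
  asserts these at 15.0/14.999 mm and 45.0/45.01°.
* **Missing data are never imputed.** A score whose required field is
  unknown is uncomputable with an explicit reason; this preserves the
  integrity of a clinical score at the cost of convenience.
* Tortuosity is stored as a continuous maximal-bend angle; the > 45° flag
  is always derived, so continuous summaries and score components come from
  one field and cannot drift apart.

## Endpoints

From each procedure record three endpoints are derived:

* **Time-efficient guidewire crossing**: successful crossing within 30
  minutes of first wire insertion. *Within* is read inclusively
  (≤ 30.0 min); the boundary is tested explicitly.
* **Final procedural success**: crossing at any time with restored flow —
  residual stenosis strictly below 50% and TIMI flow grade 3. A record with
  a crossing time but no recorded TIMI flow is rejected, not assumed
  successful.
* **Need for any non-AW strategy**: ADR, RW or RDR used at any point.

Consistency rules are enforced on input: `final_strategy = "none"` exactly
when no crossing time exists, the final strategy must be among the used
ones, and TIMI flow must lie in 0–3. A successful crossing within 30
minutes qualifies as time-efficient regardless of which strategy crossed.

## Diagnostic accuracy machinery

The ROC layer is written around an explicit direction convention: for the
two success endpoints the positive class is success and *low* scores
predict it (criteria render as "≤ k"); for the escalation endpoint high
scores predict the positive class ("> k"). Orientation is never
auto-flipped — an AUC below 0.5 is reported as such, because silent
flipping hides coding errors.

* **AUC** is the tie-corrected Mann–Whitney statistic scaled by
  `1/(n_pos·n_neg)`, computed via midranks; it equals the trapezoidal area
  of the tie-grouped empirical curve, and the tests verify exact agreement
  with a pair-enumeration oracle on a thousand tied instances.
* **DeLong inference** uses placement values: the variance of one AUC is
  `var(V10)/n_pos + var(V01)/n_neg`; the paired comparison builds the 2×2
  covariance of the placement vectors of both predictors, giving
  `z = ΔAUC / se(Δ)` and a two-sided normal p. When the difference and its
  variance are both zero the p-value is 1 by convention. The variance is
  cross-checked against pROC and against a leave-one-out jackknife (within
  10% on n = 100 sets), and null p-values pass a Kolmogorov–Smirnov
  uniformity screen over 1,000 replicates at n = 200.
* **The 95% CI for an AUC** is a normal interval on the logit scale using
  the DeLong standard error, back-transformed — so it stays inside [0, 1]
  without ad hoc clipping. An exact-binomial variant would be defensible
  too; one had to be chosen, and the DeLong-based interval matches the
  test used for "AUC = 0.5".
* **Youden cutpoints** maximise J = sensitivity + specificity − 1 over the
  achievable thresholds (including the degenerate all/none corners). Ties
  in J are broken toward higher sensitivity (screening use), then toward
  the less extreme threshold, so output is deterministic. Tie detection
  uses a 1e-9 float tolerance.
* **Fisher's exact test** uses the probability-mass two-sided definition
  (sum of tables no more probable than the observed one) — the common
  default, stated because mid-p and doubling variants differ. The
  implementation is validated against full hypergeometric enumeration for
  every 2×2 table with margins up to 15.
* **Mann–Whitney** enumerates all group assignments exactly for combined
  n ≤ 12 (valid under ties), otherwise uses the tie-corrected normal
  approximation with continuity correction. **Student's t** is the
  pooled-variance form; zero-variance degenerate inputs are flagged rather
  than erroring.
* **No multiplicity adjustment** is applied anywhere; pairwise DeLong
  p-values are reported raw with the comparison count attached, matching
  how such case-series tables are conventionally reported.
* Report rounding: percentages to one decimal, AUC to three; rounding is
  applied only when writing CSVs, never in memory.

## The count fixture

The fixture encodes a published cohort's *counts*, not its patients: 59
lesions crossed time-efficiently, 51 not, with per-group strategy-use,
final-strategy, crossing and TIMI-flow counts reproduced exactly. The
failure group's joint strategy assignment is solved from the printed
margins by inclusion–exclusion (e.g. |ADR ∩ RW| − |triple| = 14), which
pins down a block structure: 13 AW-only, 5 AW+ADR, 6 AW+RW, 4 primary
retrograde, 14 AW+ADR+RW, 2 AW+ADR+RDR, 3 AW+RW+RDR, 4 all-four.
Continuous fields carry arbitrary values consistent with group membership
(success-group crossing times ≤ 30 min). Feature flags are laid out
cyclically with varying offsets so no two features are perfectly
collinear, while the calcium flags share one offset so their nesting
(100% CSA ⊂ ≥ 50% CSA ⊂ any calcium) holds by construction. One printed
inconsistency exists in the source tables (successful AW 64.5% in the
table vs 64.6% in the text; 71/110 = 64.5%); the fixture follows the
table.

```{r fixture}
agg <- aggregate_endpoints(fixture_table2_cohort()$procedures)
agg[agg$measure %in% c("time_efficient_crossing", "final_procedural_success",
                       "any_non_aw"), ]
```

## The synthetic generator

A single latent difficulty factor `d ~ N(0,1)` induces all feature–outcome
correlation. This is the simplest structure consistent with how the scores
are built: they are additive proxies for one underlying construct, the
difficulty intrinsic to the lesion. Concretely:

* each binary feature is Bernoulli with probability
  `plogis(alpha_f + beta_f d)`, with `alpha_f` solved by numerical
  integration so the *marginal* prevalence equals its configured target
  exactly, whatever the loading;
* calcification is generated from one latent normal shifted by `d` with
  three cutpoints, so the nested calcium marginals are consistent by
  construction;
* occlusion length and bend are lognormal with location shifted by
  `loading × d` and the *total* marginal log-sd held fixed (the residual
  sd absorbs the loading), so the configured medians and spreads are
  loading-invariant; a loading at or above the total spread raises an
  "unreachable" error naming the distribution;
* the crossing time is lognormal with location `log(20) + gamma·d` and a
  *fixed residual* log-sd of 1.53 (total spread 1.73 at the default
  `gamma = 0.8`, matching a median of 20 min with IQR ≈ 8–83). Holding the
  residual fixed — rather than the total — makes the expected
  time-efficient rate strictly decreasing in `gamma`, a property the test
  suite checks on a `gamma` grid with common random numbers;
* a never-cross event is logistic in `d` (marginal 9.1%); escalation to a
  non-AW strategy occurs when the crossing time exceeds an independently
  drawn switch time (median 27 min, IQR ≈ 19–52) or the lesion is never
  crossed, with a 3.6% primary-retrograde fraction; the escalated strategy
  set is drawn from configured conditional frequencies;
* the angiographic reading passes the CT features through symmetric 10%
  misclassification noise, with the angiographic calcification flag
  derived from the *central* (100% CSA) CT grade — invasive angiography
  sees only dense calcium — and angiographic length/bend drawn as ratio
  noise around the CT values (ratios 0.72 and 0.93, reflecting systematic
  angiographic underestimation).

All draws come from one seeded generator in a frozen, documented order, so
`config + seed` reproduces a cohort bit-identically across sessions.

**What the generator does and does not emulate.** Configured marginals
(the Table-style prevalences, length/bend medians, crossing-time scale)
are reproduced faithfully — at n = 10^4 every binary prevalence lands
within three binomial standard errors and the length median within 5%.
Emergent quantities are only approximate: the escalation rate at the
default switch-time independence assumption comes out near 49% (observed
cohorts report ~36%), and the derived angiographic calcification marginal
is ~23% rather than ~16%. The real dependence between switch time and
eventual success is not characterised in published data; independence is a
modelling convenience, flagged here. Passing tests on synthetic cohorts
therefore demonstrate correctness of the *machinery* and recoverability of
*configured* signal, not fidelity to any real cohort's joint distribution
or its published AUC point estimates.

## Calibration and parameter recovery

`calibrate_discrimination()` scales every difficulty pathway (binary
loadings, the calcium ladder, length/bend loadings, `gamma`, the
never-cross loading) by one common factor, found by `uniroot` on the
simulated population AUC of a chosen score for a chosen endpoint. Common
random numbers (one fixed inner seed for all candidate factors) make the
objective effectively deterministic and monotone; continuous-feature
loadings are capped just below the total spread they must fit inside. A
target of exactly 0.5 returns the zero-loading config; targets near 1 are
unreachable for bounded integer scores and error out. With an inner
simulation of 10^5 lesions the achieved population AUC sits within 0.005
of target, and across 100 independent 2000-lesion replicates the DeLong
95% CI covers the configured AUC of 0.84 in ~94% of replicates (the suite
requires ≥ 90%).

## Problem sizes

The shipped analyses and tests use: the 110-lesion fixture; 10^4 lesions
for marginal fidelity; 5 × 10^4 lesions per calibration step (10^5 in the
recovery study); 100 replicates of 2000 lesions for CI coverage; 1,000
replicates of n = 200 for the DeLong null screen; and full enumeration up
to margins of 15 (Fisher) and 2^10 factor combinations (scores). These
sizes give Monte Carlo error comfortably below the tolerances asserted.

## Known limitations

* The ordinal KCCT calcification ladder assumes its grades are mutually
  exclusive; if the original score intended cumulative points, KCCT totals
  of centrally calcified lesions would be one point higher.
* The CI flavour for AUCs (logit-normal DeLong) and the "AUC = 0.5" test
  (DeLong z) are choices among defensible alternatives; exact-binomial
  variants would differ slightly in small samples.
* The generator's single-factor dependence structure cannot represent
  feature clusters that correlate beyond their shared difficulty loading
  (e.g. calcification and age), and its strategy-escalation model is
  deliberately minimal.
* Scores are computed from features as recorded; the package does no image
  analysis and cannot detect feature-reading errors beyond schema and
  consistency validation.
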