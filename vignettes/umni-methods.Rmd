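---
title: "Quantifying unmet medical need: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying unmet medical need: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umni)
```

## The composite index

`umni` quantifies the *relative* unmet medical need of diseases. Each
disease receives eleven integer scores on a 1–5 scale — higher means
greater need — across three categories: patient suffering (commonality,
duration, QALYs lost, 5-year mortality), current standard of care
(disease-modifying activity, adverse events, administration route and
frequency), and accessibility of that care (cost to patients, supply
robustness, regulatory barriers). The composite is a plain weighted sum,

$$T = \sum_{j=1}^{11} w_j \, s_j, \qquad s_j \in \{1,\dots,5\},\; w_j \ge 0,$$

with no normalization. The default weight scheme emphasises rare diseases
lacking an effective, disease-modifying standard of care with high
mortality/morbidity: mortality and disease modification carry weight 1,
the three accessibility criteria 0.25 each, and the eleven weights sum to
5.75. Every valid score vector therefore yields a total that is a multiple
of 0.25 in $[5.75, 28.75]$ — a useful integrity check that the test suite
asserts on random score vectors. Totals are presented as competition
ranks (ties share the smallest rank) and as "top $100 r/N$ %" rounded to
one decimal; competition ranking was chosen because it is standard, stable
under permutation, and keeps the percentile well defined under ties.

Weights encode organisational priorities, not truth; the package treats
them, like all rubric anchors, as configuration (`default_weights()`,
`read_weights_json()`), and a sensitivity analysis is advisable before
adopting a different scheme.

## Rubric scoring

The deterministic rater maps a structured disease attribute profile to the
eleven scores through threshold tables (`default_rubric()`): four strictly
increasing cut-points per numeric attribute, giving five half-open,
lower-inclusive bands on the attribute's own scale, or an explicit
category→score map. Two conventions matter:

* **Band edges are lower-inclusive.** A 5-year mortality of exactly 30%
  falls in the 30–60% band (score 4), not the 10–30% band.
* **Direction flags.** Most numeric criteria are need-increasing; the
  commonality criterion is need-*inverted* relative to prevalence (rarer
  ⇒ higher need), consistent with the rare-disease intent of the default
  weights.

The default numeric anchors (mortality bands <1 / 1–10 / 10–30 / 30–60 /
≥60%; prevalence per 100,000 descending 500 / 50 / 5 / 0.5; duration in
years 0.1 / 1 / 5 / 20 with lifelong in the top band; QALY-loss fractions
0.1 / 0.3 / 0.5 / 0.7; dosing 0.25 / 1 / 7 / 21 doses per week) fix the
*shape* required of any rubric — measurable units, five ordered bands —
but are deliberately configuration, never constants: organisations with
different thresholds load their own JSON rubric and every downstream
computation is unchanged. `rubric_coverage_check()` verifies totality
(every admissible value maps to exactly one score, every score is
reachable) before any scoring happens. Profiles expose prevalence rather
than incidence as the commonality attribute; incidence users can supply a
rubric keyed to their own attribute column.

## The rater layer

Raters are callbacks `(disease, criterion) → reply text`, so expert CSV
imports, deterministic rubric scores, recorded language-model replies, and
seeded mocks all flow through one surface.

For language-model raters, `build_prompt()` renders a system prompt that
fixes the role (a medical doctor and professor of epidemiology
prioritising diseases for research), names the criterion, and constrains
the reply to a JSON object with the single key `"response"`; the user
prompt asks for one number from 1 to 5 and spells out all five score
anchors in measurable units. Synonyms are appended as
`"name (also known as: s1; s2)"` — long descriptive disease names are a
known failure mode for language models, which sometimes score a fragment
of the name, and synonym injection mitigates it. `parse_response()`
accepts integer-valued strings and decimals (`"4"`, `3.0`) and types every
failure (`not-json`, `missing-key`, `noninteger`, `out-of-range`); the
audit loop (`audit_and_regenerate()`) re-queries failing cells at most
`max_regenerations` times (default one regeneration with unchanged
parameters) and flags survivors unresolved rather than guessing. No
network adapter ships; a recorded-fixture rater stands in for a live
`send(system, user)` implementation so the whole pipeline is exercisable
offline. Temperature defaults to 0 in `rater_config()` to minimise
sampling variability, though identical prompts can still drift across
model versions — pin model identifiers in the run manifest.

The mock rater (`mock_rate()`) perturbs a base matrix cell-wise: ±1 point
with probability $p_1$, ±2 with $p_2$, sign uniform, clamped to $[1,5]$.
Clamping (rather than rejection or re-draw) keeps the perturbed marginal
on the score scale but has a visible consequence: on boundary scores half
of the ±1 shifts realize as no change, so a full-spectrum base shows
*fewer* observed disagreements than $p_1 + p_2$. Calibration checks
therefore use an all-3 base, where no clamping occurs and realized shift
frequencies estimate the configured rates directly. The default rates
(20.45% and 5.45%) reproduce the disagreement structure observed between
two independent human experts scoring 40 diseases.

## Reconciliation and agreement

Two-expert reconciliation (`mediate()`) follows the rule that one-point
differences are a reasonable margin of uncertainty: such cells take the
arithmetic mean of the two raters (half-integers permitted in consensus
space), while differences above one point take a third rater's score
verbatim and are logged. The mean convention for agreeing cells is an
assumption — published per-criterion expert means are not integer-
consistent with a single rater, implying *some* merged value, but the
exact merging rule is not documented anywhere we could follow; the
post-condition that every consensus cell lies within one point of at
least one original rater is asserted as a property test.

Agreement between an expert matrix and a candidate rater is summarised
per criterion by both raters' means and sample SDs (n−1 denominator), the
differences **expert − rater**, and two inclusive performance gates:
|mean difference| ≤ 1 point and |SD difference| ≤ 0.5 points. Pooled
statistics are Spearman's rank correlation (average ranks for ties) with
a 95% percentile bootstrap interval (1,000 paired resamples; degenerate
resamples with a constant vector are redrawn), MAE and RMSE, and a paired
Wilcoxon signed-rank test of zero median difference. The signed-rank test
drops zero differences, uses the exact null distribution when the
effective n is ≤ 25 with untied absolute differences, and otherwise a
normal approximation with tie and continuity corrections; the exact
branch is verified in the tests against full $2^n$ sign enumeration, and
both branches against `stats::wilcox.test()`. The percentile (rather than
BCa) bootstrap was chosen for transparency; a simulation in the
acceptance suite confirms ~95% coverage at n = 40 against a planted rank
correlation of 0.8.

## Factor suite

Before factoring, two diagnostics gate the analysis: Bartlett's test of
sphericity, $\chi^2 = -(n - 1 - (2p+5)/6)\ln\det R$ on $p(p-1)/2$ degrees
of freedom (55 at eleven criteria), and the Kaiser–Meyer–Olkin measure of
sampling adequacy from anti-image partial correlations, with the
conventional bars MSA > 0.6 per item and > 0.5 overall. `factor_report()`
refuses to extract factors when the data are not factorable and says so.

The retained factor count comes from parallel analysis on the *reduced*
(communality-adjusted, squared-multiple-correlation diagonal) correlation
matrix: observed principal-factor eigenvalues are compared against
simulated uncorrelated data of identical shape. Two comparison curves are
offered. The mean of the simulated eigenvalues is the default and is what
the planted-structure recovery tests use; the 95th-percentile curve is
the right tool for guarding against chance capitalization — under pure
noise the first *observed* eigenvalue exceeds the simulated *mean* about
half the time by symmetry, so "noise ⇒ zero factors" is only a meaningful
assertion against the upper-percentile curve, and that is how the test
suite asserts it.

Extraction is maximum likelihood via `stats::factanal()`, with factors
labelled `ML1..MLk`. The oblique rotation is **promax**; an oblimin
rotation would be equally defensible but promax is what the standard R
factor-analysis stack provides, and the dominant-loading groupings the
package reports are insensitive to the choice among oblique rotations in
the planted-structure tests. Groupings assign each criterion to the
factor with the largest *absolute* loading (a strong negative loading,
e.g. disease modification on a modifiability factor, groups with its
factor), ties broken to the lowest factor index with a warning. Heywood
cases (uniqueness at its bound) are flagged.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline needs offline:

* `gen_profiles()` inverse-constructs attribute profiles from a
  *spectrum plan* (target score distribution per criterion, uniform by
  default) — sample the target score, then draw the attribute uniformly
  within that score's rubric band. This emulates a calibration set
  deliberately spanning the full spectrum of expected scores.
* `gen_rater_pair()` draws an expert matrix from the plan and perturbs it
  with the mock rater, emulating two independent raters with a controlled
  disagreement structure.
* `gen_factor_scores()` draws from a planted latent-factor model —
  loadings, factor correlations, uniquenesses $1 - \mathrm{diag}(L\Phi
  L')$ — and discretizes standardized scores at latent cut-points
  (−1.5, −0.5, 0.5, 1.5 by default, chosen once so the discrete marginals
  roughly match observed 1–5 usage). `four_factor_model()` plants the
  empirically observed four-group structure with its published dominant
  loadings and zero cross-loadings.

Passing tests on these data demonstrate that the *statistical machinery*
recovers known structure: they do not show that real expert or
language-model scores have that structure. Two honest gaps deserve
emphasis. First, real score matrices have cross-loadings and correlated
residuals that the zeroed-out planted model lacks; at n = 40 the planted
structure yields an overall KMO around 0.5 (population value 0.657), so
the factorability property is asserted at n = 500 where sampling noise no
longer dominates — real data that printed KMO 0.81 at n = 40 were more
strongly inter-correlated than their dominant loadings alone imply.
Second, generated profiles are attribute vectors, not diseases: nothing
semantic (names, synonyms, clinical plausibility of attribute
*combinations*) is emulated.

## Numerical and reproducibility choices

* Skewness is the population Fisher–Pearson $g_1 = m_3/m_2^{3/2}$; the
  small-sample adjusted estimator differs negligibly at the landscape
  scales where a skewness is interesting, and the choice is fixed so
  reruns agree to the bit.
* Missing score cells are representable (`NA` plus audit flags) but every
  downstream statistic refuses them; imputation would be invented
  behaviour in a pipeline whose reference runs report no missing data.
* All randomness flows through explicit seeds via an internal
  `with_seed()` that restores the caller's RNG state; every pipeline
  command writes a manifest (package version, seed, md5 of the canonical
  config) and reruns with an identical manifest are byte-identical, which
  the acceptance suite checks with file hashes.
* Problem sizes in the tests are the package's own choices: planted-
  structure recovery and factorability at n = 500 (50 seeded runs for
  retention-rate properties), bootstrap coverage with 500 replications of
  1,000 resamples at n = 40, mock calibration on 11,000 mid-scale cells.
* Degenerate inputs are first-class: constant vectors make rank
  correlations undefined (flagged, never silently zero), zero variance
  makes skewness undefined, an identity correlation matrix makes KMO 0/0
  (`NaN`, flagged), and all-zero differences make the signed-rank test
  degenerate with p = 1.

## Known limitations

Confirmatory factor analysis is deliberately out of scope: at 40-disease
scale it is underpowered and the exploratory structure shows
cross-loadings, so a CFA would lend false precision. Live language-model
querying, provider API clients, and cost accounting are likewise out of
scope — the rater layer's contract is exactly what a live adapter must
satisfy, and everything else runs offline. Published pooled agreement
values and the landscape-wide score distribution cannot be reproduced
here because the underlying raw score data are not published; the test
suite substitutes oracle-equivalence and parameter-recovery properties,
which is the strongest check available without those data.
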