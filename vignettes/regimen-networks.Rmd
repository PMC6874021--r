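---
title: "Valuing regimen evidence networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing regimen evidence networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regimenrank)
```

## The model

`regimenrank` treats a body of pairwise randomized-controlled-trial (RCT)
evidence as a temporal network: regimens are vertices, each two-arm
comparison is a dated edge. A vertex's value is the sum of signed
contributions over its incident edges,

$$v \;=\; \sum_{y=1}^{m} -\log_{10}(P_y)\; \cdot\; RV_y \;\cdot\; E_y
\;\cdot\; \log_{10}(N_y) \;\cdot\; f(\alpha_y),$$

with the positive share going to the favored arm and the negative share to
the other, so every edge is zero-sum and so is the whole network. The value
is unitless and deliberately **not normalized**: its magnitude carries the
weight of accumulated evidence, and the interpretation bands (positive =
recommendable, negative = contraindicated, near zero = insufficient
evidence) act on the signed value directly.

Key modelling assumptions worth making explicit:

* one outcome per comparison enters the valuation (see the selection rule
  below); conflicting endpoints within a trial do not average;
* each trial is its own edge — multiple trials of the same pair are not
  meta-analytically pooled;
* a noninferiority result, or a reported effect of exactly 1 with no
  favored arm, carries no superiority information and contributes zero
  (its vertices and patient counts still enter the network);
* evidence value decays smoothly with calendar age and can be restored by
  interim updates or by the refresh mechanism.

## Endpoint selection and relative value

Endpoints are graded by surrogacy: STRONG (overall survival) <
INTERMEDIATE (progression-free/event-free survival, time to progression) <
WEAK (response rates, molecular/cytogenetic markers). The selection rule
per comparison:

1. among the trial-defined primary endpoints, take the least surrogate
   (ties broken by lower P value, then input order);
2. if that primary is met (P ≤ `p_met`, default .05) and a strictly
   less-surrogate secondary reaches marginal significance (P ≤
   `p_marginal`, default .10), the secondary replaces it;
3. if the primary is not met, it is kept regardless of the secondaries.

The selected endpoint's class maps to a relative value RV of 1.0 / 0.8 /
0.7. The shipped endpoint table (`default_rv_table()`) is deliberately
small and fully overridable — via `rv_table()`, per-file YAML
(`rv_overrides`), or `scale_rv()` — because endpoint naming varies across
disease settings. `rv ≤ 1` is treated as a defining property: the
sensitivity analysis caps rescaled weights at 1.0 so the strong class
remains the reference.

## The five factors

| factor | definition | default / units | notes |
|---|---|---|---|
| significance | `min(−log10 P, cap)` | cap 3; P < .001 truncated | very small P values are not allowed to dominate |
| relative value | RV of the selected endpoint | 1.0/0.8/0.7, unitless | uniform rescaling cancels in single-class networks |
| effect | `max(e, 1/e)` signed by winner | ≥ 1, unitless | an HR of 0.5 and an OR of 2 weigh equally |
| size | `log10(N)` of the comparison | N ≥ 2 patients | doubling patients adds ~0.3, not 2× |
| aging | `2^(−α/half_life)` | half-life 10 years | α from the latest of publication and interim updates |

The half-life default of 10 years reflects the practical horizon over
which untreated-era results stop informing current practice in oncology;
it is configurable (`half_life_years`) and every aging-related behaviour
(decay, refresh, opacity in plots) follows it consistently. The base-2
exponential form was chosen so that "refresh by one half-life" is exactly
a doubling of the aging coefficient, capped at 1.

## Propagation and refresh

The straw-man countermeasure replays publication years in ascending order.
For each year, every node's net value change attributable to that year's
new edges becomes an event. A losing node passes `propagation_fraction`
(default 0.5 — "half of the newly assigned blame is the comparator's")
of its loss to the regimens it had previously beaten; a gaining node
passes the same fraction of its gain to the regimens it had previously
lost to. Propagation is strictly single-generation: the transfer follows
existing prior edges only, never their transitive closure. Each edge
through which value passes is refreshed: its effective age is rewound by
one half-life (floored at zero), at most doubling its contribution.

Design choices where the mechanism was genuinely open:

* **Transfer valuation.** Event deltas are computed from the year's new
  edges *as valued at the evaluation year* (i.e. already aged). This is
  equivalent to transferring at full value in the event year and letting
  the transferred amount age on the same clock as the evidence that caused
  it, and it makes the bookkeeping exact: transfers are recorded as
  vertex-level adjustments that sum to zero, the signed edge decomposition
  remains auditable, and `propagation_fraction = 0` reproduces the plain
  valuation bit for bit.
* **Event granularity.** All new edges incident to a node in one year
  aggregate into a single event; events are processed in ascending year,
  then by earliest contributing trial id, then node id, so replay is
  deterministic.
* **Split among targets.** EQUAL shares by default; PROPORTIONAL (to the
  magnitude of each qualifying prior edge's contribution) is available for
  networks where prior wins differ greatly in strength.
* **Refresh scope.** Only the edges through which value actually passed
  are refreshed, not all edges of the involved nodes — the analogy is
  reduced impedance along the conducting path.

With refresh disabled, total network value is conserved under any event
sequence (transfers are zero-sum); with refresh enabled the total remains
zero as well, because refresh rescales both signed shares of an edge
symmetrically.

## Diagnostics

`value_size_correlation()` is the straw-man detector: Pearson correlation
of vertex value against vertex size (total patients studied under the
regimen), through `stats::cor.test` — the 95% CI is the Fisher
z-transform interval and the P value comes from the t statistic on n − 2
degrees of freedom. It refuses networks with fewer than 3 usable vertices
or zero variance. `sensitivity_rv()` re-runs the full pipeline under
uniform RV rescalings (±5/10/20% by default) and reports whether rank
order and value signs survive; `compare_rankings()` supplies the exact
equality flag and Kendall's τ.

The near-zero band for "insufficient evidence" is ε = 0.5 (configurable):
a single weakly significant (P = .05), weak-endpoint, small (N = 100),
modest-effect trial contributes ≈ 1.3, so half a unit is comfortably below
any single decisive result.

## The synthetic scenario generator

Real trial lists are assembled by literature curation and cannot ship
here, so `generate_strawman()` emulates the *structure* that matters for
exercising the method:

* **Sticky standards.** A current standard of care is the comparator with
  probability `strawman_intensity` (default 0.8). A regimen that beats the
  standard at P ≤ .05 is *adopted* as the new standard only with
  probability `adoption_prob` (default 0.1): guidelines are sticky, so a
  standard keeps being trialled against — and beaten — for about a decade
  before rotation, which is precisely the straw-man mechanism. The
  default reproduces the ~2–3 standard-of-care eras per few decades seen
  in real treatment landscapes.
* **Recent experimental arms.** Debutants enter on a fixed schedule (one
  every ~1.7 years at the defaults); non-debut experimental arms are drawn
  from regimens introduced within the preceding decade — trials test
  recent entrants, not revivals of 25-year-old regimens.
* **Newcomer advantage.** The more recently introduced arm wins with
  probability `newcomer_win_prob` (default 0.8), matching the observed
  record in which regimens trialled against a long-standing comparator
  were almost always neutral or superior.
* **Endpoint drift.** The probability mass on strong endpoints decays
  linearly by `endpoint_drift` (0.4) per decade, so late-era trials are
  almost exclusively judged on surrogate endpoints.
* **Realistic joint distributions.** P values are generated from a
  two-sided normal test of the observed log effect with standard error
  ∝ 1/√N, so significance, effect size, and trial size covary instead of
  being drawn independently. Trial-size location doubles per decade
  (`n_growth_per_decade = 2`, start location 150 patients), reflecting the
  secular growth of oncology RCTs; without it every era's vertices are
  equally sized and the propagated loss cascade cannot shift the
  value–size relation the way it does in real networks.

`generate_null()` is the negative control: comparators are drawn uniformly
from the existing regimens *and* the newer-arm win probability is set to
one half. Both neutralizations are needed — with the win asymmetry left
in place, older regimens are simultaneously the largest and the
systematically beaten vertices, and the value–size correlation stays
markedly negative under any comparator scheme, which would make the
"null" a biased control rather than a bias-free one.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: patient-level survival and censoring,
multi-arm trials (supported by `expand_multiarm()` but not generated),
publication bias and unpublished trials, between-study effect modifiers,
and the curation noise of real endpoint naming. Conclusions from the
simulation study are about the method's behaviour under a plausible bias
mechanism, not estimates of any real network's parameters.

## The simulation study and its sizes

The acceptance suite runs 200 generator seeds at the defaults (20
regimens, 1990–2020, two trials per year — 62 trials per stream, the same
order of magnitude as curated single-disease trial lists) and checks
three qualitative properties: the median pre-propagation value–size
correlation is below −0.3; propagation and refresh shrink |r| in at least
80% of seeds, with the median post value nearer zero; and the null
scenario's median correlation lies within ±0.15 of zero. These sizes keep
the whole suite within a few minutes while leaving the medians stable
across re-runs.

A note on the null bound: with 20 vertices the sampling distribution of a
truly null Pearson r has standard deviation ≈ 1/√19 ≈ 0.23, so the median
of |r| for a *perfect* negative control is
`sqrt(qbeta(0.5, 0.5, 9))` ≈ 0.16. A bound of 0.15 is therefore only
meaningful for the *median signed* correlation (which is ≈ 0 under the
null), and that is the form the suite asserts; per-seed |r| values near
0.2 are expected chance behaviour at this vertex count, not bias.

## Numerical and degenerate-input conventions

* Rank ties break alphabetically by regimen id; replay and generation are
  fully deterministic given seeds, and the generator restores the caller's
  RNG state.
* P values are validated into (0, 1]; effects must be positive; a draw
  (`favored_arm = "NONE"`) with a non-unit, non-noninferiority effect is
  rejected at load time rather than silently zeroed.
* `significance_weight` applies both the P truncation and the cap, which
  coincide at the defaults (`p_truncation = .001`, cap 3).
* Zero-sum is asserted to 1e−9 *relative* tolerance (values can reach
  hundreds in long streams).
* Vertex size counts the full `n_total` of every comparison the regimen
  appears in, published by the evaluation year; unreported arms of
  multi-arm trials are not counted (only the expanded pairwise
  comparisons contribute).

## Known limitations

* The aging half-life and propagation fraction are empirical knobs; the
  rankings' sensitivity to RV is tested, but a full ensemble analysis over
  all coefficients is future work.
* Effect sizes reported as absolute differences must be converted to a
  ratio by the user before loading; only ratio-scale measures are modeled.
* The correlation diagnostic treats vertices as independent observations;
  with few vertices its CI is wide, and the zero-sum constraint induces
  mild negative coupling between values that the Pearson machinery
  ignores.
* Propagation semantics are one faithful reconstruction of a
  restore-and-inherit mechanism; alternatives (e.g. transferring only
  losses, or refreshing all edges of an involved node) would change
  magnitudes, though the structural identities tested here would still
  hold.
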