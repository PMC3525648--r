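---
title: "Estimating genetic susceptibility from twin concordance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic susceptibility from twin concordance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsus)
```

## The model

We treat genetic susceptibility as binary: an individual's genotype either
can (`G`) or cannot (`G-`) produce the disease under some attainable
environmental exposure. Within the susceptible set, each genotype `i` has
its own penetrance `z_i` (a lifetime disease probability); `z = E[z_i]` is
the set-level expected penetrance and `sigma2` its variance. The observables
are the population prevalence `P(D)`, proband-wise MZ twin concordance, DZ
and sibling concordance, and the case/population frequencies of partition
markers (risk-allele carrier status, gender).

Three assumptions carry the weight:

1. **Twins are representative.** The genetic composition of the twin
   population matches the general population, so the MZ co-twin of a case is
   a draw from the case's genotype with the population's environment.
2. **The shared childhood environment is negligible, the shared
   intra-uterine environment is not.** DZ twins and siblings share genes to
   the same degree; their concordance difference isolates the intra-uterine
   (IU) excess. Multiplying the MZ rate by the sibling/DZ ratio removes it.
   For diseases where the childhood environment does matter (registry data
   for some neurodegenerative diseases suggest this), the adjustment is
   wrong in a known direction; the package exposes `mode = "none"` and the
   simulator can generate violating cohorts, but no correction for a
   childhood-environment effect is attempted.
3. **Markers are susceptibility-related.** Non-genetic cases carry a
   partition marker at its population frequency.

Three identities then do most of the work.

**Size-biased concordance.** Conditioning on an affected proband samples
susceptible genotypes proportionally to penetrance, so the adjusted MZ
concordance among genetic cases is `b' = E[z_i^2]/E[z_i] = z + sigma2/z`,
not `z`. This is why concordance overestimates typical penetrance, why
`z_upper = b` is an admissible bound in the lower-bound formula, and how the
penetrance variance is recovered from `b' = b/g`.

**Simultaneous constraints on P(G).** Split `G` at its mean penetrance into
high and low halves. Whichever half carries at least half the mass has mean
penetrance at least `b'/2 >= b/2`, and the cases it alone produces cannot
exceed `P(D)`; hence `P(G) <= 2 P(D)/b`. The package implements the bound in
exactly this closed form: it reproduces the headline estimate and every
regional and cross-disease upper bound from printed inputs.

**Partition feasibility for g.** For a partition with population frequency
`A0` and case frequency `A`, writing `g1, g2` for the susceptible fractions
of the two case subgroups, marker-neutrality of non-genetic cases forces

```
g1 = [A - (1-g) A0] / A        g2 = [(1-A) - (1-g)(1-A0)] / (1-A)
```

(the approximation `P(marker|G-) ~ A0` is valid precisely because `P(G)` is
bounded above at a few percent). Any `g` must keep `g1, g2` and the
susceptible-only concordances `t' = t/g1`, `s' = s/g2`, `b' = b/g` inside
`[0, 1]`. For a partition whose enrichment is allele-frequency-only — judged
by the observable ratio `s/b` within `mech_tol` of 1 — carrier status leaves
penetrance unchanged among susceptibles, so `t' = s' = b'`; the small
*observed* excess of `t` over `s` must then be explained entirely by
non-genetic cases diluting the marker-negative subgroup, and that pins `g`
to a narrow interval. The gender partition (where penetrance clearly
differs) contributes only its box constraints, and the estimate is the
intersection over all supplied partitions.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `mech_tol` | 0.10 | classification band on `s/b - 1` for the allele-frequency-only call; the reference carrier partition sits at 0.96 (inside), the gender partition at 0.27 (outside), and simulated mechanism-1 cohorts at realistic counts stay within 0.10 in well over 95% of seeds |
| `ratio_tol` | 0.01 | band on the `t'/b'` and `s'/b'` equalities for a mechanism-1 partition. Published concordances are rounded to three decimals; the two algebraically redundant routes to `g` (via `t` and via `s`) disagree by ~0.5–1% at full precision purely from that rounding, so a 1% band treats the equality as exact up to reporting precision |
| `grid_step` | 1e-4 | initial feasibility grid over `g`, endpoints refined by 40 bisection steps; deterministic |
| `plateaus` | 0.28 / 0.06 | gender response ceilings for `P(D, E|G)`; the upper ends of the per-gender penetrance ranges implied by the partition analysis |
| `near-unity threshold` | 0.9 | penetrance defining "purely genetic" genotypes in the Chebyshev mass bound |
| `n_events_min` | 3 | minimum count of required environmental events; a configured input carried into reports, not derived here |
| `hazard_scale`, `r` | 1, 1 | response-curve rate constant and proportional-hazard ratio; the exposure axis is dimensionless, so the scale is a unit choice |

Probabilities are unitless lifetime probabilities throughout; registry
prevalences may be supplied per 100,000 and are converted on ingest.

## Numerical and design choices

- **Pooled IU factor.** The sibling/DZ ratio is computed from pooled rates
  (0.029/0.054 for the bundled reference data) and applied uniformly to all
  subgroups. Per-gender ratios are dominated by tiny male sibling counts and
  do not reproduce the published per-gender adjusted penetrances; they
  remain available by calling `iu_adjustment_factor()` on subgroup
  observables explicitly.
- **Ascertainment calibration.** Registries publish proband-wise rates but
  rarely the double-ascertainment probability. `calibrate_ascertainment()`
  solves the one-parameter equation on the pooled table and applies the same
  study-wide factor to its subgroups; a user-supplied factor is accepted. A
  rate implying a factor outside `[1, 2]` is a hard error with the implied
  value in the message.
- **Renormalization target.** Subgroup tables are rescaled so their pooled
  adjusted rate equals the overall `b`. In published mode (rounded
  proband-wise inputs) the target is `b` at its reported precision and the
  rescale is skipped when the table already agrees at that precision —
  matching how the published subgroup penetrances were themselves formed.
  The full-precision mode (simulated or count-level data) always rescales to
  `b` exactly.
- **Bound conventions.** Regional tables use `lower = g P(D)/b` with
  `g = 0.94` and the IU-adjusted `b`; cross-disease tables (no sibling/DZ
  data) use the upper-bound formula at both prevalence ends with no IU
  factor. Both are explicit modes of `region_table()`. A
  distribution-specific `z_max` tighter than `b` may be supplied to
  `prob_g_lower()`; none is assumed by default.
- **Penetrance-range coherence.** The conservation range for `z` can be
  intersected with a second constraint interval; a subgroup-derived lower
  boundary is not identified without distributional assumptions, so the
  lower boundary falls back to (is "minimally modified" to) the conservation
  bound, and disjoint constraint sets raise a diagnostic rather than being
  averaged.
- **Purely-genetic bound.** The maximal mass at penetrance `>= tau` given
  `(z, sigma2)` is the one-sided Chebyshev value
  `sigma2/(sigma2 + (tau - z)^2)`, attained by a two-point distribution; the
  test suite verifies it against brute-force search over discretized
  two-point distributions.
- **Selection-weight tie-breaks.** Genotype-dose enrichment is classified
  geometric `(1, w, w^2)` versus dominant `(1, w, w)` and recessive
  `(1, 1, w)` by minimum relative deviation; a geometric call within
  tolerance is preferred, with a warning when an alternative deviates less.
- **Response-curve form.** Only "threshold plus proportional hazard" is
  specified by the model, so the package uses the minimal constant-hazard
  form `c (1 - exp(-h r (x - lambda)))`. The female curve anchors the
  dimensionless exposure axis (`lambda_F = 0`); `fit_gender_curves()` solves
  the male threshold offset, the hazard ratio, or an offset at a fixed
  ratio. Both strata exactly at saturation make the parameters
  unidentifiable and return a degenerate flag instead of an arbitrary fit.
- **Degenerate inputs.** Zero concordant pairs give rate 0; `sib >= dz`
  yields factor 1 with a warning (no negative IU excess); `A = A0` with
  `t = s` makes a partition uninformative (its admissible interval is the
  whole range allowed by the generic penetrance constraints); empty
  registries return empty tables with a warning.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws individual genotypes (susceptible or not, carrier
or not, a penetrance value from a point, two-point, or Beta distribution),
gives MZ co-twins identical genotypes, lets DZ twins/siblings share
susceptibility status with a configurable probability (default 0.5),
inflates the concordant cell of co-gestated pairs by a symmetric
`iu_effect`, and ascertains affected pairs with configurable double
ascertainment. Carrier models implement the two enrichment mechanisms:
a susceptibility multiplier (allele-frequency mechanism) or a penetrance
multiplier, with the marginal susceptible fraction held at `p_g`.

This validates the estimators' logic: size-biased convergence of
concordance to `E[z^2]/E[z]`, coverage of the `P(G)` interval, detection and
removal of the IU inflation, and separation of the two mechanisms. It does
**not** emulate real registries' age structure, mortality, zygosity
misclassification, diagnostic drift, or assortative mating — so passing
simulation tests demonstrates internal consistency under the model's
assumptions, not robustness of the assumptions themselves. DZ/sibling
genetic sharing is a single status-sharing probability rather than explicit
multilocus genetics: the estimators consume only concordance rates, for
which this is sufficient.

Validation problem sizes were chosen so that Monte-Carlo error is several
times smaller than the tolerance being asserted: 200,000 pairs for the 2%
size-bias check (binomial error ~0.5%), 100,000 pairs per seed for the
200-seed coverage study, 80,000 pairs per seed for mechanism separation.

## Known limitations

- The partition identification of `g` leans on the mechanism-1 equality
  being exact; a partition with a genuine but small penetrance effect inside
  `mech_tol` would bias `g`. Supplying several partitions tightens this:
  inconsistent partitions produce an explicit infeasibility report.
- Published tables round intermediates; a handful of reference cells (four
  regional lower bounds, one regional upper bound on a half-ulp boundary,
  one cross-disease lower bound, one subgroup proband-wise rate) differ from
  full-precision recomputation by one unit in the last printed digit.
  `reproduce_reference_tables()` flags these as known discrepancies rather
  than silently matching them.
- The exposure-sufficiency summary reports the saturation fraction
  `z/plateau` as a lower bound on `P(E|G)`; sharper statements (population
  `P(E)` bounds, minimum event counts, secular prevalence trends) require
  gender-ratio trajectory data over time and are out of scope — the
  relevant fields are configuration inputs, never derived values.
- No confidence intervals: the published registries report none, and the
  bounds here are deterministic functions of point inputs. The
  `sensitivity_sweep()` grid is the supported way to propagate input
  uncertainty.
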