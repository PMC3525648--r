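# twinsus

Estimation of the genetic and environmental architecture of complex disease
from twin-study concordance and basic epidemiology.

## The problem

For a complex disease such as multiple sclerosis (MS), a handful of
quantities are directly observable: the lifetime prevalence *P(D)*, the
proband-wise concordance of monozygotic (MZ) and dizygotic (DZ) twins and of
ordinary siblings, and the frequency of a risk marker (an HLA allele, or
gender) among cases and in the population. Quantities that clinicians and
geneticists actually want are not observable: the fraction of the population
*P(G)* that is genetically *susceptible* (capable of developing the disease
at all), the fraction of cases *g = P(G|D)* that require susceptibility, the
penetrance distribution of the susceptible genotypes, whether a risk allele
acts by making carriers more likely to be susceptible or by raising
penetrance, and how disease probability responds to environmental exposure
in each gender.

`twinsus` converts the former into the latter, for analysts working with
twin-registry and genetic-epidemiology data. Its core identities:

- **Adjusted MZ concordance.** The raw proband-wise MZ rate is corrected for
  double ascertainment (a study-wide inflation factor *f ∈ [1,2]* solved
  from the pooled table) and for the shared intra-uterine environment (the
  sibling/DZ concordance ratio), leaving *b = P(D | IG_D)* — the probability
  of disease given only an identical genotype with an affected co-twin.
- **Susceptibility bounds.** Splitting the susceptible set at its mean
  penetrance and conserving cases gives *P(G) ≤ 2 P(D)/b*; conservation
  *z·P(G) = g·P(D)* with the size-biased bound *z ≤ b* gives
  *P(G) ≥ g·P(D)/b*.
- **Susceptible-case fraction.** For a two-way partition (carrier status,
  gender) with population frequency *A₀* and case frequency *A*, non-genetic
  cases carry the marker at *A₀*, forcing
  *g₁ = [A−(1−g)A₀]/A* and *g₂ = [(1−A)−(1−g)(1−A₀)]/(1−A)*.
  When a partition's enrichment is allele-frequency-only (subgroup
  concordance ratio *s/b ≈ 1*), the susceptible-only concordances must agree
  (*t′ = s′ = b′*), which identifies *g* sharply; `estimate_g()` intersects
  the admissible intervals of all supplied partitions.
- **Penetrance decomposition.** The co-twin of an affected proband samples
  genotypes size-biased by penetrance, so *b′ = b/g = z + σ²/z* recovers the
  within-set penetrance variance; a one-sided Chebyshev bound on mass near
  penetrance 1 bounds the "purely genetic" fraction.
- **Environmental response.** Gender-specific saturating exposure-response
  curves (threshold + constant hazard) are fitted through the adjusted
  penetrances under a proportional-hazard assumption, with plateaus bounding
  *P(D, E|G)*.

A forward twin-cohort simulator generates synthetic populations obeying the
model's assumptions (and violating them on request), so every estimator is
validated against known truth without any external data.

## Worked example

```r
library(twinsus)
fit <- fit_susceptibility(ms_observables())
summary(fit)
```

```
Twin-study genetic susceptibility model
  adjusted MZ concordance b        : 0.134
  susceptible-case fraction g      : >= 0.941
  susceptible population P(G)      : 1.05% - 2.24%
  susceptible-set penetrance z     : 0.063 - 0.134 (b' = 0.142)

Per-table adjustment chain:
  hla: f = 1.542; proband-wise 0.309/0.287; adjusted 0.166/0.154; renormalized t = 0.139, s = 0.129
      mechanism: s/b = 0.97 -> allele_frequency_only
  gender: f = 1.514; proband-wise 0.340/0.067; adjusted 0.183/0.036; renormalized t = 0.183, s = 0.036
      mechanism: s/b = 0.27 -> both

Susceptible-case fraction g: admissible interval [0.9409, 0.9493]
  hla: [0.9409, 0.9493]
  gender: [0.3830, 1.0000]

Carrier analysis: susceptible carriers <= 5.1%; allele contributes for 41% of cases
Environment: P(E|G) >= 0.65 (women), 0.60 (men); plateaus 0.28 / 0.06
```

Reading the output: only ~1–2.2% of the population is genetically
susceptible to MS, yet at least ~94% of cases occur in susceptible
individuals. The DRB1\*1501 carrier partition behaves as a pure
allele-frequency mechanism (non-carrier penetrance ratio 0.97): the allele
makes susceptibility more likely but does not change penetrance, fewer than
~5% of carriers are susceptible, and it contributes to susceptibility in
only ~41% of cases. The gender partition shows both mechanisms: susceptible
women (adjusted penetrance 0.183) are five times more penetrant than
susceptible men (0.036), consistent with women responding more strongly to
environmental exposure (both genders are already at ≥60% of their response
plateaus).

Downstream methods:

```r
coef(fit)                                   # named vector of estimates
predict(fit, ms_region_registry())          # per-region P(G) bounds
predict(fit, ms_disease_registry(), mode = "unadjusted")
plot(fit)                                   # gender response curves
sim <- simulate(fit, seed = 1)              # synthetic cohort at the fitted parameters
reproduce_reference_tables()                # cell-by-cell check against published values
```

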