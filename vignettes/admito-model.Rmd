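---
title: "The admito model: diet, mitochondrial dynamics and AD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The admito model: diet, mitochondrial dynamics and AD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admito)
```

## The model

admito implements a probabilistic prognosis model for prodromal or mixed
Alzheimer's disease (AD) built on three ingredients:

1. **A prior probability table.** Each binary biomarker — the
   mitochondrial-dynamics proteins DRP1, FIS1 (fission) and OPA1, MFN1,
   MFN2 (fusion), plus lifestyle risk factors (hypertension, oxidative
   stress, obesity, depression, physical activity) — carries a published
   marginal probability of being abnormal/positive, and four age brackets
   carry AD risk weights (<65: 0.04, 65–74: 0.15, 75–84: 0.43,
   ≥85: 0.38). Two markers (ATP, diabetes) have no published estimate and
   default to 0.5, consistent with the model's blanket use of uniform
   distributions; both are configurable.
2. **A signed acyclic influence graph.** Diet (high-fat fish-oil "HFO",
   high-fat lard "HL", starvation, caloric restriction "CR", or no
   intervention) influences the markers; OPA1/MFN1/MFN2 feed a derived
   *fusion* flag and DRP1/FIS1 a derived *fission* flag; markers, dynamics,
   age and lifestyle converge on the AD node. Edge signs are symbolic
   (`promoting` / `deterrent`); the source figure's (+)/(−) glyph glosses
   are swapped relative to the usual convention, so admito stores semantic
   signs and keeps them config-visible rather than trusting glyphs.
3. **Bayesian machinery.** The continuous variables are modelled as
   Uniform(0, a); the conjugate prior for the upper bound a is
   Pareto(b, K), with the closed-form update
   Pareto(max(b, max y), K + n). Discrete (binary-node) posteriors are
   normalised prior×likelihood products. Conditional probabilities are
   estimated from the simulated cohort by direct counting, each with a
   Monte-Carlo error — the binomial standard error sqrt(p(1−p)/n). The
   source description invokes "MCMC" by name but specifies only direct
   Monte-Carlo counting; admito implements exactly that and no Markov
   chain.

## The cohort simulator

`simulate_cohort(n, seed, config)` generates the stated world: `n`
patients (default 1000), each with

* an integer age uniform on 30–95,
* a diet category uniform over the five categories — the source
  enumerates four interventions, but its printed results include a row
  with diet "0", so a `none` category is first-class,
* one independent Bernoulli draw per marker at its *effective*
  probability: the table prior pushed through the diet's odds-scale
  modifier. This realises the model's "activation function": a marker
  activates (value 1, abnormal) when its uniform draw falls below the
  effective activation probability,
* derived fusion/fission flags and the deterministic AD probability from
  the case evaluator.

**Reproducibility.** One seeded generator per cohort, consuming exactly 14
draws per patient in the fixed order (age, diet, markers in the cohort
column order). The implementation vectorises this by reshaping a single
`runif(n * 14)` patient-major, which is stream-identical to calling the
per-patient samplers in a loop; a unit test asserts the equivalence.

**Diet modifiers.** The source gives edge signs but no magnitudes, so the
bundled modifiers are symmetric placeholders on the odds scale: 2.0 for a
risk-promoting diet effect and 0.5 for a protective one (HFO lowers
oxidative stress, raises MFN2/ATP; HL raises FIS1/obesity, lowers MFN2;
starvation raises MFN1/OPA1/ATP; CR raises FIS1/DRP1). Odds scaling was
chosen because it maps (0,1) to (0,1) for any positive multiplier, keeps 0
and 1 as fixed points, and makes the identity modifier exactly 1. These
are placeholders, set once and not tuned; frequency-recovery checks use
`identity_diet_modifiers()` so that each marker's empirical frequency can
be compared against its raw prior.

**CPT support.** Every marker can alternatively be linked to earlier
markers through a 2×2 (or 2^k) conditional probability table
(`cpt_overrides` on the network), covering the four parent-state
combinations False|False … True|True. The bundled default samples
marginally, because the source's simulation protocol references only the
marginal prior table; whether the original program linked markers through
CPTs during simulation is not stated. Overrides require parents to precede
the child in the marker order so that a single left-to-right pass per
patient suffices.

## The case evaluator

`evaluate_ad_probability()` maps an evidence pattern (12 markers, diet,
age) to a probability through a deterministic cascade:

1. if any mitochondrial marker is abnormal → the prior of the
   highest-priority abnormal one (default priority
   opa1 > mfn2 > mfn1 > drp1 > fis1);
2. else if diet is `none` → the no-diet baseline 0.743;
3. else if any lifestyle marker (ht, dp, ob, pa, os) is positive → the
   maximum prior among the positive ones;
4. else → the age-bracket weight.

This cascade is **reverse-engineered**, not quoted: the source never
states the mapping from evidence to output, but its five worked cases all
return numbers that coincide exactly with prior-table entries
(0.614 = OPA1 twice, 0.278 = MFN1, 0.2 = hypertension, 0.743 = DRP1). The
cascade is the minimal deterministic rule consistent with all five rows.
Two elements deserve flags:

* the priority order among mitochondrial markers is under-constrained
  (the cases only show opa1 beating mfn1/mfn2/fis1); the default order is
  a documented choice, and the whole rule — priority, lifestyle set,
  baseline — is configurable through `case_rule()`;
* the fifth case returns 0.743 (numerically the DRP1 prior) although its
  drp1 flag is 0 and no marker-based rule can produce it; admito encodes
  it as a standalone `no_diet_baseline` constant. Why that case equals the
  DRP1 prior is unexplained in the source.

The derived-dynamics rules are reverse-engineered the same way: fusion is
1 iff at least two of {opa1, mfn1, mfn2} are abnormal (ATP is excluded
because one published row has atp = 1 with fusion = 0), and fission is
1 iff drp1 = 1 or fis1 = 1 — in each case the simplest monotone rule
consistent with all five published rows. No claim is made that these are
the original authors' rules.

## Numerical choices

* Oxidative stress is published as a range (25–30%); the bundled prior is
  the midpoint 0.275, configurable.
* All probabilities the evaluator can emit have at most three decimals, so
  the CSV rendering (`%.3f`, matching the published table) is lossless and
  cohort files round-trip exactly.
* `posterior_from_likelihood` rejects priors that do not sum to 1 (within
  1e-8) and errors on all-zero products (degenerate evidence) rather than
  returning NaN; `estimate_conditional` likewise errors when no record
  matches the evidence.
* Uniform sampling of discrete values maps `runif` through
  `floor(u * k)` with a clamp at `k - 1`, so the theoretical edge case
  `u == 1` cannot index out of range.
* The configuration digest is a small polynomial string hash kept below
  2^24 so all arithmetic stays exact in doubles; it identifies
  configurations in logs and reports, nothing more.

## What a green test establishes — and what it does not

The synthetic cohort emulates the stated simulation protocol: uniform
age/diet, independent Bernoulli markers at published marginal priors, and
deterministic downstream derivations. It does **not** emulate real
patient data: no correlation between markers beyond optional CPT links, no
age-dependence of marker prevalence, no longitudinal progression, no
measurement noise. A green frequency-recovery test establishes that the
simulator samples the configured world correctly — not that the
configured world is clinically calibrated. The published clinical claims
(diet biology, disease associations) are narrative and are not tested
here.

## Known limitations

* The influence-graph edge list is reconstructed from the source's text
  captions and case narratives, since the figure itself is an image; the
  quantitative diet modifiers are placeholders.
* Whether the published AD column was produced by the authors' simulation
  or curated by hand is unknown; admito reproduces it deterministically.
* No structure or parameter learning from data; the model is a fixed,
  configurable prior structure.
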