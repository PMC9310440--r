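# admito

Diet, mitochondrial dynamics and Alzheimer's disease (AD) risk: a seeded
Monte-Carlo cohort simulator plus the Bayesian machinery to reason about it.

## Who this is for

Researchers modelling how diet type (high-fat fish-oil, high-fat lard,
starvation, caloric restriction, or none) shifts mitochondrial
fission/fusion biomarkers (DRP1, FIS1, OPA1, MFN1, MFN2) and lifestyle risk
factors, and how those shifts translate into the probability of prodromal or
mixed AD progression. The package is a research tool for prognosis
modelling, not a clinical instrument.

## The model in brief

* Each binary biomarker *m* carries a marginal prior probability of
  abnormality `p_m` taken from published clinical estimates; age brackets
  carry AD risk weights (`<65`: 0.04, `65–74`: 0.15, `75–84`: 0.43,
  `≥85`: 0.38).
* A cohort of *n* patients is simulated with age ~ U{30,…,95},
  diet ~ U over five categories, and each marker an independent Bernoulli
  draw at its diet-modified prior — the model's "activation function".
  Fusion (≥2 of {OPA1, MFN1, MFN2} abnormal) and fission (DRP1 or FIS1
  abnormal) flags are derived per patient.
* Continuous quantities use a Uniform(0, a) likelihood,
  `f(y|a) = ∏ 1/a · 1[0 ≤ yᵢ ≤ a]`, whose conjugate prior is
  Pareto(b, K), `p(a) = K b^K / a^(K+1)` for `a ≥ b`; the posterior after
  n observations is `Pareto(max(b, max y), K + n)`.
* Conditional probabilities `P(outcome | evidence)` are estimated by
  counting over the simulated cohort, each with its Monte-Carlo error
  `sqrt(p(1−p)/n)`.
* A deterministic case evaluator maps one evidence pattern (12 markers,
  diet, age) to an AD probability through a documented cascade over the
  prior table; it reproduces the five published worked cases exactly
  (0.2, 0.614, 0.278, 0.614, 0.743).

See `vignettes/admito-model.Rmd` for assumptions, parameter defaults and
the parts of the rule set that are reverse-engineered from the published
cases.

## Worked example

```r
library(admito)

cohort <- simulate_cohort(1000, seed = 42)
head(cohort, 3)
#>   id atp opa1 mfn1 mfn2 drp1 fis1 db os ht ob dp pa diet age fusion fission    AD
#> 1  1   1    0    0    0    1    1  0  0  0  0  0  0 none  90      0       1 0.743
#> 2  2   0    1    0    0    0    1  0  0  1  0  0  0 none  60      0       1 0.614
#> 3  3   0    0    0    0    1    0  1  1  0  0  0  0 none  59      0       1 0.743
```

Each row is one synthetic patient: 0/1 marker flags (1 = abnormal/positive),
diet category, age, the derived fusion/fission dynamics flags, and the
AD-progression probability. Patient 2, say, has an abnormal OPA1, so the
evaluator returns the OPA1 prior 0.614.

```r
estimate_conditional(cohort,
  evidence = function(d) d$diet == "HL",
  outcome  = function(d) d$fission == 1)
#> P(outcome | evidence) = 0.9348  (n = 184, MC error = 0.0182)
```

Among the 184 simulated lard-diet patients, 93.5% have active fission
(the HL diet doubles the FIS1 odds on top of its 0.60 prior), estimated
with a binomial Monte-Carlo error of 0.018.

```r
pareto_posterior_update(pareto_params(1, 2), c(0.5, 0.8))
#> Pareto(b = 1, K = 4)   # conjugate update: b' = max(b, max y), K' = K + n

ev <- evidence_pattern(mfn1 = 1, atp = 1, ob = 1, dp = 1,
                       diet = "starv", age = 70)
evaluate_ad_probability(ev)
#> [1] 0.278   # the MFN1 prior: third published worked case
```

Command line (after install):

```sh
Rscript -e 'admito::ad_cli(commandArgs(TRUE))' simulate --n 1000 --seed 7 --out cohort.csv
Rscript -e 'admito::ad_cli(commandArgs(TRUE))' table2 --out cases.csv
Rscript -e 'admito::ad_cli(commandArgs(TRUE))' evaluate --evidence 'mfn1=1,diet=starv,age=70'
```

A ready wrapper is installed at
`system.file("cli/admito", package = "admito")`.

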