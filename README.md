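# dmsdt: signal detection analysis of pattern perception in binary sequences

`dmsdt` implements the complete computational machinery for studying how
observers discriminate *patterned* from *random* binary token sequences in a
yes/no signal detection task. The stimuli are sequences of 20 blue/yellow
tokens. A **random** sequence draws each token as an independent fair coin. A
**disrupted Markov sequence (DMS)** is built in two stages: a Markov chain
whose tokens repeat their left neighbor with probability *p*<sub>r</sub>
(0.9 throughout), then independent per-token flips with disruption
probability *p*<sub>d</sub>. Disruption plays the role of noise: the three
study conditions are *p*<sub>d</sub> = 0.1 (LD), 0.2 (MD) and 0.3 (HD), with
100-trial sessions of 50 random and 50 DMS stimuli in random order.

The package is aimed at psychophysicists and cognitive modelers who want the
full model stack for this task without human data: a synthetic-observer
simulator with the same statistical structure the analysis assumes makes
every fitting stage testable by parameter recovery.

## What it computes

**Full Bayesian ideal observer.** The posterior odds that a sequence *S* is
patterned,

    λ = P[S | DMS] / P[S | RANDOM],

with equal prior odds by design; respond DMS iff λ > 1. P[S | RANDOM] =
0.5<sup>n</sup>; P[S | DMS] marginalizes over the 2<sup>n</sup> hidden
undisrupted Markov sequences by a two-state forward recursion (emission:
token equals the hidden token with probability 1 − *p*<sub>d</sub>).
Sensitivity is available **exactly** — complete enumeration of all
2<sup>20</sup> sequences — and by Monte Carlo (default 5,000 replications).

**Feature observers.** Four candidate pattern features: F1 = longest run of
one color, F2 = longest alternating stretch (used sign-flipped, −F2, so
larger always means more patterned), F3 = number of repetitions of adjacent
tokens, F4 = color predominance |#blue − #yellow|. Each ideal single-feature
observer applies the likelihood-ratio rule on the feature's exact
distribution under the two generators.

**Feature-combination GLM.** Logistic regression of per-trial judgments on
any feature subset, E[P(respond DMS | S)] = ψ(β₀ + Σ βₖ fₖ(S)), with
Menard's *fully standardized* coefficients β\*ₖ = βₖ·s(xₖ)·R / s(logit ŷ)
for cross-observer comparison, the dominant feature (largest β\*), all 15
subset models, AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), and evidence ratios
exp(ΔAICc/2).

**SDT metrics.** Equal-variance Gaussian d′ = z(H) − z(F), criterion
c = −(z(H)+z(F))/2, 1/(2N) correction for perfect cells, and efficiency =
observer d′ / exact full-model d′.

## Worked example

```r
library(dmsdt)

# exact ceiling performance in the low-disruption condition
exact_performance(ideal_observer(p_r = 0.9, p_d = 0.1))
#> SDT estimate: H = 0.8701, F = 0.1014, d' = 2.4003, c = 0.0733

# a synthetic observer that relies on the repetition count, with lapses
s    <- build_session("LD", n_trials = 100, seed = 7)
obs  <- observer_spec(beta0 = -14.4, beta = c(f3 = 1.2), lapse = 0.1)
resp <- simulate_observer(obs, s, seed = 8)
score_session(resp, s)
#> SDT estimate: H = 0.8000, F = 0.2200, d' = 1.6138, c = -0.0347
efficiency(score_session(resp, s), p_r = 0.9, p_d = 0.1)
#> efficiency = 0.6723 (observer d' = 1.6138, full model d' = 2.4003)

# which feature drove the judgments?
fit <- feature_glm(resp, s, subset = 1:4)
dominant_feature(fit)
#> [1] "f3"   (tie = FALSE, reliable = TRUE)

# AICc comparison of all 15 feature-subset models
head(as.data.frame(multimodel_table(fit_all_models(resp, s))), 4)
#>   model k    loglik     aicc delta_aicc evidence_ratio supported
#> 1     3 2 -32.46750 69.05870  0.0000000       1.000000      TRUE
#> 2    23 3 -31.86677 69.98355  0.9248426       1.587914      TRUE
#> 3    34 3 -32.36015 70.97030  1.9115918       2.600740      TRUE
#> 4    13 3 -32.46732 71.18464  2.1259386       2.894954      TRUE
```

The observer is correctly recovered as an F3 user: their hit rate of 0.80
against a false-alarm rate of 0.22 gives d′ = 1.61, about 67% of the
Bayesian ceiling of d′ = 2.40, and the single-feature model "3" wins the
AICc ranking.

`run_pipeline()` chains all stages (simulate → featurize → fit 15 models →
compare → SDT) for a cohort and writes CSV/JSON outputs; `write_session()` /
`read_session()` round-trip sessions through a plain CSV plus a JSON
parameter sidecar.

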