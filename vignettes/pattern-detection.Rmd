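---
title: "Models and methods: detecting disrupted Markov patterns in binary sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: detecting disrupted Markov patterns in binary sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsdt)
```

## The task and the generative model

An observer views a row of `n = 20` binary tokens (blue = 1, yellow = 0) and
judges whether it came from a **random** generator — independent fair
Bernoulli draws — or a **disrupted Markov sequence (DMS)** generator. A DMS
is produced in two stages: a Markov chain starts with a fair token and
repeats the previous color with repetition probability `p_r`; each token of
the result is then independently flipped with disruption probability `p_d`.
Disruption is the task's noise. The study design fixes `p_r = 0.9` and runs
three conditions, `p_d = 0.1` (LD), `0.2` (MD) and `0.3` (HD), in 100-trial
sessions containing exactly 50 stimuli from each generator in random order.
`build_session()` reproduces that design; since the design could also be
read as choosing the generator per trial by a fair coin, `balanced = FALSE`
offers that variant, but the exact 50/50 split is the default.

Two degenerate limits anchor everything: at `p_d = 0` a DMS is a pure Markov
sequence with closed-form probability `0.5 * p_r^R * (1-p_r)^(n-1-R)` where
`R` counts adjacent equal pairs; at `p_d = 0.5` flipping destroys all
structure and the DMS distribution collapses to the uniform distribution of
the random generator.

## The full Bayesian observer

The ideal observer computes the posterior odds
`lambda = P[S|DMS] / P[S|RANDOM]` (prior odds are 1 by design) and responds
DMS exactly when `lambda > 1`. `P[S|RANDOM] = 0.5^n` is immediate. `P[S|DMS]`
requires marginalizing over the unobserved, undisrupted Markov sequence —
a sum over `2^n` hidden sequences. The generative process is a two-state
hidden Markov chain (fair start, stick probability `p_r`, emission correct
with probability `1 - p_d`), so the marginal is computed by the standard
forward recursion with per-step rescaling, `O(n)` per sequence and stable
for any length. The recursion is certified in the test suite against an
independent brute-force oracle that sums over all hidden sequences via
Hamming distances, for every sequence up to `n = 12` in all three
conditions, to relative error below 1e-10.

Numerical choices worth stating:

* **Ties.** The response is DMS only for `lambda` strictly above the
  criterion; `lambda = 1` resolves to RANDOM. Ties have probability zero
  except in the collapse case below.
* **Collapse case.** At `p_d = 0.5` every emission probability equals 0.5,
  so `P[S|DMS] = 0.5^n` for every sequence — an identity, which the code
  applies directly rather than recomputing through the recursion. This
  keeps `lambda` exactly 1 (not 1 plus float dust) and makes the exact
  d-prime exactly 0 in that limit.
* **Complement symmetry.** The emission terms are written in a form
  symmetric under swapping the two colors, so
  `likelihood_dms(S) == likelihood_dms(complement(S))` holds bitwise, and
  reversal invariance (the stationary symmetric chain is reversible) holds
  to machine rounding.

### Exact and Monte Carlo performance

`exact_performance()` enumerates the full sequence space: the hit rate is
the DMS-generator probability mass of the decision region, the false-alarm
rate its uniform mass. The enumeration represents sequences as the bits of
an integer index and runs the forward recursion vectorized across all `2^n`
indices at once; `n = 20` (1,048,576 sequences) takes a few seconds, and a
cap at `n = 24` keeps memory bounded, with an explicit error beyond.
Because the likelihood-ratio rule is accuracy-optimal, the exact hit rate
always dominates the false-alarm rate. `mc_performance()` instead simulates
fresh sequences per generator (default 5,000 replications, the size used
for the published model contours) and estimates the same quantities
empirically.

## Pattern features and ideal feature observers

Four candidate features summarize a sequence:

| id | definition | range |
|----|-----------|-------|
| f1 | longest contiguous run of one color (tokens) | 1..n |
| f2 | minus the longest contiguous strictly alternating stretch | -n..-1 |
| f3 | number of adjacent equal pairs ("repetitions") | 0..n-1 |
| f4 | color predominance, absolute count difference | 0..n |

Two definitional points were genuinely open and are resolved as follows.
"Longest repeating/alternating subsequence" is read as a *contiguous* block
measured in tokens (a single token is a block of length 1): contiguity is
what a visual streak is, and token count rather than transition count
matches "length of the longest sequence of a single color". Predominance is
taken as the absolute difference `|n1 - n0|` rather than `max(n1, n0)`; the
two are affinely equivalent (`max = (n + |diff|)/2`), so classifiers and
GLM fits differ only in intercept and scale, and the absolute form is
color-symmetric. The alternation feature is stored negated so that larger
values of every stored feature point toward "patterned"; with that
convention all generative weights are expected positive and the dominant
feature is a signed argmax. All four features are invariant to color
complement and to reversal, and `f3` plus the alternation count is always
`n - 1` — the two encode the same information.

An **ideal feature observer** sees only one feature value `v` but uses it
optimally: `exact_feature_distribution()` accumulates the exact probability
of every feature value under both generators over the enumerated space, and
the observer responds DMS when `P[v|DMS] > P[v|RANDOM]` (ties to RANDOM).
For monotone-likelihood-ratio features this is an upper threshold. The rule
maximizes accuracy; maximizing d-prime over thresholds instead is
degenerate — pushing the threshold into the extreme tail inflates
`z(H) - z(F)` while accuracy collapses — so the accuracy-optimal rule is
used throughout.

A consequence the test suite computes explicitly: the repetition count
(f3) is the best single feature at LD and MD, but at HD the longest run
(f1) edges it out (exact d-prime 0.619 vs 0.551 against a full-model
ceiling of 0.723). Sensitivity of the full model degrades strictly with
disruption: exact d-prime 2.400, 1.451, 0.723 across the three conditions.

## The feature-combination GLM

Human-like observers are modeled as weighted feature combiners:
`E[P(respond DMS | S)] = psi(beta0 + sum_k beta_k f_k(S))` with `psi` the
logistic function (any location shift of `psi` is absorbed into the
intercept, since the two cannot be identified separately). `feature_glm()`
fits this by maximum likelihood (IRLS via `stats::glm`, convergence
tolerance 1e-10, no penalization — AICc comparisons stay on a pure ML
footing). Complete separation is detected (all fitted probabilities at
their response's boundary) and flagged with a warning; the reported weights
are the finite values where IRLS stopped. A constant feature column is a
hard error, not a silent NA.

Weights are also reported in Menard's *fully standardized* form,

```
beta*_k = beta_k * sd(x_k) * R / sd(logit(fitted))
```

with `R` the correlation between fitted probabilities and responses: a
one-SD change in the feature changes the predicted logit by `beta*_k`
standard deviations, so weights are comparable across features and
observers. The formula is exposed in `standardize_menard()` for audit. The
**dominant feature** is the largest standardized weight (ties break to the
lowest feature index and are flagged); the call is flagged unreliable when
the winning feature's raw weight is indistinguishable from zero (|z| < 2),
as for a guessing observer.

## Model comparison

All 15 non-empty feature subsets (4 + 6 + 4 + 1 models, named by
concatenated indices, "13" = F1 and F3) are fitted per observer and ranked
by the small-sample corrected AIC, `AICc = -2*loglik + 2k +
2k(k+1)/(n-k-1)` with `n = 100` trials per observer-session and `k` the
weight count including the intercept. Evidence for the best model over
another is `exp(delta_AICc / 2)`; the supported set uses a default cutoff
of 10 (strong evidence), with 3/30/100 as the other conventional levels —
a model exactly at the cutoff is still counted as supported. For a cohort,
AICc is averaged across observers per subset before ranking, and the
parsimony ladder reports the best model per size with the evidence ratio
against the best model one size up.

## SDT metrics

Sensitivity and criterion come from the equal-variance Gaussian model:
`d' = z(H) - z(F)`, `c = -(z(H) + z(F))/2` (positive `c` = conservative,
biased toward "random"). Observed rates of exactly 0 or 1 are replaced by
`1/(2N)` and `1 - 1/(2N)` — the standard correction, since the study does
not state one — and the estimate is flagged so downstream analyses can
exclude corrected cells. Exact rates from enumeration are interior by
construction and need no correction; the only boundary case is chance
performance with `H = F`, where d-prime is 0 by definition. Efficiency is
the ratio of an observer's d-prime to the exact full-model d-prime of the
same condition, and is undefined (an error) when the ceiling is not
positive, i.e. at `p_d = 0.5`.

## Synthetic observers

Human responses are replaced by a generator with exactly the statistical
structure the analysis assumes: response probability
`lapse/2 + (1 - lapse) * psi(beta0 + sum_k beta_k f_k(S) + noise)`, with a
lapse rate (fair guess regardless of the stimulus) and zero-mean Gaussian
noise on the linear predictor. This deliberate match makes parameter
recovery well-posed: the GLM, standardization, dominance, AICc and SDT
stages can all be validated end to end. Reference settings used in the
tests and the acceptance script, chosen once as plausible for the task:
an F3-driven observer has `beta3 = 1.2` with intercept `-14.4` (centering
the predictor near the mixed-session mean repetition count of about 12),
lapse rates between 0 and 0.2, and weaker multi-feature users around
`beta = 0.2..0.5`. With 500 replicate observers at 100 trials each, the
dominant feature of an F3-only observer is recovered in well over 95% of
replicates; raw weights are recovered within sampling error at 10,000
trials.

What the simulator does *not* emulate — and what recovery therefore does
not establish about real data: learning or drift across trials, sequential
dependencies between responses, response biases that vary with recent
feedback, and observers whose decision rule is outside the weighted-linear
family (e.g. a full-Bayesian responder fit by feature GLMs is
misspecified; the model-comparison machinery can be exercised on such
observers, but the recovered weights then describe a projection, not the
true rule).

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; sessions derive a
recorded per-trial seed from the master seed so any single trial can be
regenerated in isolation. The test suite certifies the forward recursion
against brute force at `n <= 12` (4,096 sequences x 4,096 hidden
sequences at the largest size), runs the exact enumerations at the study's
`n = 20`, uses 5,000-replication Monte Carlo checks against exact values,
and 100-500 replicate recovery simulations; these sizes keep the full
suite at a few minutes on one core while leaving every statistical check
at four standard errors or tighter. Sequence data round-trip through plain
CSV with a JSON parameter sidecar (`write_session()` / `read_session()`),
and `run_pipeline()` chains the whole analysis deterministically from one
seed.

## Known limitations

* Exact enumeration is capped at `n = 24` tokens; longer sequences are
  served by Monte Carlo only.
* The feature registry ships exactly the four features above; it is
  extensible in code but no further features are provided.
* Unequal-variance SDT, ROC fitting from ratings, priors other than 1:1,
  and nonlinear feature combination are out of scope.
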