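---
title: "Deep survival modelling of coded health-event sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep survival modelling of coded health-event sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Administrative health data — hospital diagnoses, procedures and dispensed
medications, coded month by month — carry predictive signal for
cardiovascular disease (CVD) beyond the handful of covariates that
traditional risk equations use. `seqrisk` implements a combined
survival-analysis and deep-learning approach to 5-year CVD risk prediction
from such data: a recurrent neural network maps a person's coded event
sequence and pre-specified covariates to a scalar log relative risk
$f(x)$, which replaces the linear predictor of a Cox proportional hazards
model,

$$\lambda(t \mid x) = \lambda_0(t)\, e^{f(x)},$$

and is trained by maximizing the Cox partial likelihood. A conventional
sex-specific Cox model on the same pre-specified covariates serves as the
comparator. Because the administrative data this class of model is built
for are access-restricted, the package ships a synthetic-cohort simulator
with known planted effects; every claim the package makes is tested
against that known truth.

# Data model

A cohort is two tables. `persons.csv` holds one row per person: sex, age
(30–74 years), ethnicity (five levels, European as reference), deprivation
quintile, five binary flags (diabetes, prior atrial-fibrillation
hospitalization, baseline dispensing of blood-pressure-lowering,
lipid-lowering and antiplatelet/anticoagulant medications), and the
right-censored outcome — follow-up in days (1–1826) and an event
indicator. `events.csv` holds one row per code listing: person, code, a
code type (primary/secondary diagnosis, external cause, procedure,
medication) and a calendar-month index 0–59 within the five-year lookback
(59 = index month). A hospitalization spanning several months lists its
codes once per month; repeats are kept. Codes carried by fewer than
`min_persons` distinct people are excluded from the vocabulary
(national-scale analyses use thresholds like 500 out of millions;
desk-scale cohorts here use 50 of a few thousand, which plays the same
noise-control role at a larger relative threshold because rare-code
effects cannot be estimated from a few hundred events at all).

Covariates are centred so that the all-zero vector describes the
*reference person*: mean age of the training stratum, deprivation quintile
3, reference ethnicity, all flags false, empty history. Six pairwise
interaction terms are exact products of their factors. Sex is handled by
stratification — two independent models — and never enters the covariate
vector.

# The network

Each retained event contributes a code embedding plus a type embedding
(shared dimension $d$, default 16; desk default 4), concatenated with the
gap $\Delta t$ in months since the previous retained event ($\Delta t = 0$
for the first). Three stacked bidirectional GRU layers (hidden size per
direction equal to the input size $d{+}1$, 10% inter-layer dropout during
training) contextualize each event; a learned query vector pools the
outputs by dot-product attention into one context vector; the context is
concatenated with the covariates, passed through a size-preserving fully
connected layer with ELU activation, and mapped linearly to the scalar
$f$. An empty history contributes a zero context vector. Evaluation mode
is deterministic.

Numerical choices worth knowing:

* **$\Delta t$ scaling.** The gap is fed as months/60. Raw 0–59 values
  saturate the GRU gate pre-activations at any standard weight scale,
  which silences the gradient path into the code embeddings; the
  normalized gap preserves the information and keeps the gates in their
  responsive range.
* **Initialization.** Embeddings $N(0, 0.3^2)$; weights uniform
  $\pm 1/\sqrt{\text{fan-in}}$; reset-gate bias $+1$ and update-gate bias
  $-1$ (gates start open); attention query zero (uniform attention); the
  size-preserving head starts at identity-plus-noise. Early training is
  then a near-linear bag-of-codes-plus-covariates model, so code effects
  and covariate coefficients receive first-order gradients from the first
  step; depth and attention differentiate later.
* **Padding** (index 0) is excluded from attention by masking, and masked
  positions carry the recurrent state through unchanged in both
  directions, so padding never influences any output.

# Training

Training maximizes the Cox partial likelihood through its case–control
reduction: each epoch iterates over all events (cases) in shuffled order;
each case is matched to one control drawn uniformly from its risk set
(anyone else still under observation at the case's event time, sampled
with replacement across epochs); each matched pair contributes the
sampled-risk-set loss $\log(1 + e^{-(f_\text{case} - f_\text{control})})$,
which is the negative log partial likelihood of a risk set of size two.
The published configuration — Adam at learning rate 0.001 with betas
(0.9, 0.999), 256-case batches, 10 epochs, ensembles of 10 — is the
default of `model_config()`. Ensemble predictions are the arithmetic mean
of member log risks; members differ only in derived seeds.

`desk_model_config()` is the configuration the package's own experiments
use, adapted to cohorts of $10^3$–$10^4$ persons (hundreds of events
rather than tens of thousands): embedding dimension 4, 64-case batches, 20
epochs with the learning rate decayed linearly from 0.006 to roughly
0.001, ensembles of 5. It was chosen the same way the original 10-epoch
rule was: by watching where held-out performance turns over. At this scale
overfitting is the binding constraint — gentler, shorter optimization with
ensemble averaging recovers the covariate coefficients to near-Cox
accuracy while still extracting code-sequence signal. The `lr_decay`
option defaults to 0, leaving the published constant-rate behaviour
untouched.

# Absolute risk and local hazard ratios

Relative risks are anchored at the reference person by the Breslow
estimator: $\hat\Lambda_\text{ref}(t) = \sum_{t_j \le t} d_j / \sum_{i \in
R(t_j)} e^{f_i - f_\text{ref}}$, $S_\text{ref}(t) =
e^{-\hat\Lambda_\text{ref}(t)}$, and the absolute 5-year risk is $1 -
S_\text{ref}(1826)^{\exp(f_i - f_\text{ref})}$. The same machinery serves
the Cox comparator with $f = \hat\eta$.

*Local hazard ratios* interrogate a trained model: perturb the reference
person — set one covariate, or append one coded event at the index month —
and report $e^{f(\text{perturbed}) - f(\text{reference})}$, averaged over
$K$ models retrained from different initializations, with a percentile
2.5/97.5 interval across replicates ($K$ defaults to 10 at desk scale; the
original analysis used 100; the interval construction is this package's
choice, as the source does not state one). Continuous predictors are
reported as per-unit ratios $e^{f(v+1)-f(v)}$ averaged over a grid of
observed values. Applied to the Cox model the harness returns
$e^{\hat\beta_j}$ exactly for binary perturbations, which the tests use as
a closed-form check. These are model-explanation quantities, not causal
effects: they are conditioned on the trained model and the reference
person, and redundancy between flags and codes biases them toward one.

# Evaluation

* **Harrell's C**: comparable pairs are $(i,j)$ with $t_i < t_j$ and an
  event for $i$, or tied times with exactly one event; prediction ties
  count ½. Checked against exhaustive pair enumeration.
* **Royston–Sauerbrei D and $R^2_D$**: scores are rank-transformed to
  Blom rankits scaled by $\kappa = \sqrt{8/\pi}$; D is the Cox coefficient
  of that single covariate; $R^2_D = (D^2/\kappa^2)/(\pi^2/6 +
  D^2/\kappa^2)$. Invariant under strictly increasing transforms; a
  constant score returns D = 0 with a flag.
* **Integrated Brier score** with Graf's inverse-probability-of-censoring
  weights; the censoring distribution is a Kaplan–Meier estimate (left
  limits for event terms) taken from the *training* half, and the grid is
  the distinct event times capped at 200 points by quantile thinning.
* **Decile tables**: deciles of predicted 5-year risk (stable ties,
  sizes within one); observed risk per decile is 1 − KM at 5 years
  (censoring-adjusted; a raw-fraction option exists); discrimination is
  each decile's share of observed events.
* **Stratified 5×2 cross-validation**: five event-stratified halvings;
  both models share every train/test split; the combined F test refers
  $F = \sum d_{rj}^2 / (2\sum_r s_r^2)$ to F(10, 5). Metric intervals
  across the ten folds are t-based, a stand-in where the source reports
  none. No fold computes vocabulary, centering, baseline or censoring
  weights from its own test half.

One caution this package's own tests document: under independent null
difference matrices the combined 5×2 F test is *conservative* — its
rejection rate at nominal 5% is about 1.5%, a property inherited from the
approximation that treats numerator and denominator as independent.

# The simulator and what passing tests mean

`sim_config()` defines the generative truth: covariates from documented
distributions (age uniform 30–74, deprivation uniform, ethnicity and
flags at roughly the prevalences seen in national data); Poisson event
counts (default 0.25/person-month over 60 months); Zipf code popularity
(exponent 1.2) over 90 diagnosis/procedure and 30 medication codes;
condition-linked codes deposited with probability `redundancy_strength`
when the matching flag is set, emulating flag/code redundancy; true log
hazard $\eta^* = x'\beta^* + \sum_c \gamma^*_c w_c$ with recency weights
$w_c = e^{-\Delta m_c/\tau}$ (indicator when $\tau = 0$); exponential
event times at rate $\lambda_0 e^{\eta^*}$; censoring by exponential
non-CVD death and emigration plus administrative cut-off at 1826 days,
with day-ceiling rounding. Every person draws from an independent
substream of the seed, so growing a cohort never perturbs existing
persons.

Default effect sizes mirror published administrative CVD equations (age
HR ≈ 1.07/year, graded ethnicity and deprivation effects, condition flags
1.4–2.2, small negative interactions). The baseline hazard
(2.8×10⁻⁵/day ≈ 9% 5-year event fraction) is deliberately higher than the
2–4% of the national cohort so that desk-scale folds of a few thousand
persons keep enough events for stable metrics. Three presets define the
package's study conditions:

* `linear` — no code effects: the Cox comparator is correctly specified.
* `nonlinear` — 14 code effects (HRs 0.7–2.4) under recency weighting
  with $\tau = 12$ months: signal a linear-in-covariates model cannot
  represent. The effects are sized so that an oracle given the true code
  signal gains about +0.016 in C over the covariate-only Cox model — the
  order of separation this model class has demonstrated over Cox
  comparators on real administrative data; recency weighting halves what
  a *static indicator* model could recover, which is precisely the
  designed advantage of a sequence model that sees $\Delta t$.
* `planted_code` — one code at HR 2 with $\tau = 0$, for local-HR
  recovery.

The simulator is a stand-in, not a portrait: codes have no semantics,
times are exponential with a constant baseline (the modelling code never
exploits this), there is no seasonality and no post-index information.
Passing tests therefore demonstrate that the implementation is correct
and that the method behaves as designed *under its own assumptions* —
they do not certify performance on real administrative data.

# Problem sizes used by the tests and acceptance script

Metric oracles run on instances of up to 200 persons; Cox recovery uses
n = 20 000; local-HR recovery n = 10 000 with K = 10 replicates;
the deep-vs-Cox comparison a full 5×2 scheme at n = 8 000 (and a single
split of a linear-preset cohort of the same size); the D-statistic and
decile-calibration checks n = 20 000 and n = 50 000 without training.
These sizes keep full runs in the tens of minutes on one CPU while
leaving every comparison comfortably powered; the methods and
thresholds do not depend on them.

# Known limitations

* The recurrent stack and attention are trained from a few hundred
  events at desk scale; the published configuration assumed three to
  four orders of magnitude more.
* Local HRs probe the model far outside the data distribution (a person
  with a single coded event); they are reported with across-replicate
  intervals for that reason.
* Hyperparameter search is out of scope; the defaults are fixed and
  documented.
* The Cox comparator's tie handling (Efron by default) and the CI
  construction for cross-validated metrics are documented package choices
  where the source is silent.
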