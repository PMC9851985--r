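---
title: "Ordinal disease-course mapping of ataxia rating scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal disease-course mapping of ataxia rating scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saradyn)
```

## The problem

The Scale for the Assessment and Rating of Ataxia (SARA) is the reference
clinical outcome in spinocerebellar ataxia (SCA): eight ordinal items
(gait 0–8, stance 0–6, sitting 0–4, speech 0–6, four kinetic items 0–4)
summing to 0–40.  Planning trials on SARA — or on its four-item f-SARA
variant — requires knowing how fast each item moves, whether progression
is linear across the score range, and how much it varies between
patients.  `saradyn` provides a generative ordinal model of scale
progression, Bayesian estimation, the downstream psychometric and
trial-design analyses, and a synthetic cohort generator so the entire
pipeline can be exercised and validated without patient-level data.

## The model

Each subject carries two individual parameters: a log acceleration factor
$\xi_i$ and a start-of-progression age $\tau_i$ (the age at which the
first item leaves zero).  Observation ages $t$ are mapped onto a common
disease clock by
$$\psi_i(t) = e^{\xi_i}\,(t - \tau_i),$$
with $\xi_i \sim N(0, \sigma_\xi^2)$ and
$\tau_i \sim N(\tau_{pop}, \sigma_\tau^2)$.  The population mean of the
individual effects is zero by construction, so the population curve is
the trajectory of the "typical" subject.

On the disease clock, item $k$ (maximum level $L_k$) is an ordered
sequence of logistic exceedance curves sharing a steepness $s_k$ (years):
$$P(Y_k \ge l \mid \psi) =
  \operatorname{logit}^{-1}\!\big((\psi - c_{k,l})/s_k\big),
  \qquad l = 1,\dots,L_k,$$
with thresholds built from *level durations*
$c_{k,1} = \theta_k$, $c_{k,l+1} = c_{k,l} + \delta_{k,l}$.  The
parameter $\delta_{k,l} > 0$ is directly interpretable as the average
time in years spent at level $l$ before moving on; $\theta_k \ge 0$
delays item $k$'s first point relative to the start of progression
($\theta_1 = 0$ anchors $\tau$ to the first item).  Level probabilities
are adjacent differences of the exceedance curves, which guarantees a
proper distribution for any strictly increasing thresholds.  Missing
items simply drop out of the likelihood.

The ordered-logistic form is a design choice: it is the simplest proper
ordinal likelihood whose parameters have exactly the "years per level"
reading used throughout the analyses, and it needs only the two
individual parameters above — no per-item random effects.

The univariate variant treats the scale total as one pseudo-item (SARA:
40 levels, 39 durations), which is how global linearity of the sum score
is assessed.

## Estimation: MCMC with stochastic approximation

`fit()` runs, per chain:

* **Individual parameters** — vectorized per-subject random-walk
  Metropolis, one block for all $\xi_i$ and one for all $\tau_i$
  (subjects are conditionally independent, so proposals are accepted
  subject-wise in parallel).
* **Population parameters** — per-parameter random-walk Metropolis on
  unconstrained transforms ($\log\delta$, $\log s$, raw $\theta \ge 0$)
  under diffuse Normal(0, $10^6$) priors, each update touching only the
  observations of its item.
* **Hyperparameters** ($\tau_{pop}, \sigma_\tau, \sigma_\xi$) — during
  warm-up, decreasing-step stochastic approximation of the empirical
  mean/SD of the current individual draws (steps 1/2 for the first half,
  then $k^{-0.65}$); during sampling, conjugate Gibbs draws under
  flat/Jeffreys priors so hyperparameter uncertainty propagates into the
  population intervals.

Proposal scales adapt toward 0.3 acceptance in warm-up windows of 40
iterations and are frozen afterwards, preserving detailed balance in the
sampling phase.  The default budget is 5500 warm-up + 3500 retained
iterations (no thinning) over two chains; `profile = "test"` is a
reduced 1000 + 500 budget for simulation studies.  Convergence is
checked with trace plots and the Geweke statistic (AR-spectral variance
estimator; $|z| < 2$ read as converged).

Three numerical decisions deserve a note:

* **Identifiability of the speed scale.**  Shifting every $\xi_i$ by $m$
  while rescaling all thresholds and steepnesses by $e^{-m}$ leaves the
  likelihood unchanged.  During warm-up the sampler recentres $\xi$ to
  mean zero each iteration and absorbs the compensation into the deltas,
  which steers the population parameters to the mean-zero
  parameterization.  In the sampling phase the recentring is switched
  off: applied there it would make the likelihood exactly flat along the
  speed ridge and let the delta scale random-walk freely (we observed
  multi-fold drifts).  Left to itself, the $\xi$ prior pins the ridge,
  the chain remains a valid MCMC, and the posterior mean of $\xi$ stays
  within $\sigma_\xi/\sqrt{n}$ of zero.
* **Early-warm-up freeze.**  The hyperparameters are frozen for the
  first quarter of warm-up.  Updating $\sigma_\xi$ from the empirical
  spread of the draws from iteration 1 collapses it onto the initial
  point mass (all $\xi_i$ start at 0), which pins $\xi$ at zero
  permanently; the freeze lets the individual draws disperse first.
* **Bounded supports.**  $\log\delta$ and $\log s$ are restricted to
  $[-8, 8]$ and offsets to $[0, 200]$ years.  Durations of levels that a
  cohort never reaches are likelihood-flat; without bounds their
  adaptive random walks overflow.  The bounds are far outside any
  clinically meaningful value and act only on such unidentified
  parameters (whose posteriors should be read as "no information"
  rather than as estimates).

Initialization is data-driven: the pooled within-subject slope of the
total score sets the time scale (deltas), per-subject intercepts set
$\tau_i$, steepness starts at 0.3 times the smallest delta.

## What the synthetic generator emulates

`generator_config()` encodes the structure of the pooled natural-history
cohorts the model is designed for: four genotypes (SCA1/2/3/6) in
proportions 267/331/410/202 out of 1210, genotype mean onset ages
32.7/33.0/37.2/51.0 years, 1–6 visits at jittered one-year intervals,
per-item missingness (3%), level durations drawn in the bands 2.5–5
years (gait, stance), 5–7.5 (sitting, speech) and 9–12.5 (kinetic
items), CAG repeat lengths centred on the genotype medians
(46.5/39/70/22) with a within-genotype correlation of $-0.7$ between
onset age and log CAG, and a pre-ataxic (RISCA-like) 12% of subjects
first seen before their start of progression.  Within-genotype onset SD
is 8 years and $\sigma_\xi = 0.4$; transition steepness defaults to 1
year.  Scores are drawn from the model's own level distributions, so the
generator and the likelihood are self-consistent by construction — real
rating noise (inter-rater variation, centre effects, severity-dependent
dropout) is *not* emulated, and passing recovery tests therefore
validates the estimator, not the model's fit to real clinics.

**Entry process and why it matters.**  By default the baseline visit
falls at $\tau_i + U(0, 15)$ years, mimicking enrolment some years after
clinical onset.  This makes observation times informative about
$\tau_i$: a likelihood that (like this one, and like standard
disease-course models) conditions on visit ages without modelling
enrolment is then systematically biased — an independent marginal-ML
check reproduces the same tilt, with onset shifted early and early-level
durations stretched.  The generator therefore also offers
`entry_model = "age"`, drawing entry age independently of $\tau_i$;
estimator-validation studies (the recovery tests) use that variant,
because they are about the estimator under a correctly specified
observation process.  Analyses of cohorts enrolled post-onset should
treat absolute onset ages and the first levels' durations with caution;
pre-ataxic subjects observed before onset mitigate but do not remove the
effect.

The recovery studies use a 10-level pseudo-item with equal one-year
durations, steepness 0.5 years, $n = 300$ subjects with 4 annual visits,
a single genotype (so the model's normal onset prior is well
specified), entry ages $N(37, 5^2)$, and the reduced 1000 + 500 budget
over 3 chains — sizes chosen so a full 20-replicate study runs on a
single desktop core in minutes.

## Scale tools and trial design

* `map_to_fsara()` collapses the four retained SARA items onto 0–4.  No
  single published collapse table is canonical, so the shipped default
  is a proportional collapse
  (gait 0/1–2/3–4/5–6/7–8 → 0..4; stance and speech 0/1–2/3–4/5/6 →
  0..4; sitting unchanged), which preserves endpoints and monotonicity;
  any table can be substituted as JSON.
* `cronbach_alpha()` uses unbiased variances and resamples subjects
  (rows) with replacement, 1000 times by default, reporting the 2.5/97.5
  percentile interval.  By default it should be fed baseline visits
  (one row per subject) to avoid within-subject dependence.
* `sample_size()` uses the two-sided normal-approximation formula
  $n_{arm} = \lceil (z_{1-\alpha/2}+z_{power})^2\, 2\sigma^2 /
  (f\mu)^2\rceil$ on change scores; `empirical_power()` verifies any
  scenario by simulating seeded trials with a pooled-SD z-test; and
  `scenario_grid()` crosses groups, scale variants and closed
  baseline-score inclusion windows.  Change statistics exclude
  pre-ataxic subjects, whose near-floor scores would dilute the
  progression estimate.

## Linearity and speed analyses

`test_linearity()` operationalizes "non-overlapping delta
distributions" as: any per-pair 95% equal-tailed credible interval of
delta differences excluding zero.  Visual overlap is not testable; the
CI rule is the reproducible core of the criterion.  No multiplicity
correction is applied across pairs — intervals are raw posterior 95%
CIs, and with $m$ levels there are $m(m-1)/2$ pairs, so under an exactly
linear item the flag rate is above 5% (the calibration test bounds it at
20% for three levels).  Item speed is the posterior of the per-draw mean
delta; its IQR is the variability measure used to compare items — this
reading (IQR of the posterior of the mean, not of pooled per-level
deltas) is a documented interpretation choice.

## Known limitations

* Population parameters of levels never reached by a cohort are
  unidentified; their draws fill their bounded support and inflate
  per-item mean-delta summaries for rarely-reached items.
* The onset prior is a single normal; for genotype mixtures with very
  late-onset components (SCA6) the marginal is skewed and group-level
  onset contrasts should be computed from the individual draws (as
  `group_dynamics()` does) rather than from $\tau_{pop}$.
* Enrolment-time bias under post-onset entry, as discussed above.
* The reduced-budget profile trades Monte-Carlo error for speed; the
  analysis profile (5500 + 3500) is the default for real use.
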