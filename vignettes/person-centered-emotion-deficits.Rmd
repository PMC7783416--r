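---
title: "Person-centered subgrouping of emotion-processing deficits: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-centered subgrouping of emotion-processing deficits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emopheno)
```

## The problem this package addresses

Group-level comparisons between youths with conduct disorder (CD) and
typically developing controls (TDC) on emotion-processing tasks yield small
effects, which is compatible with two very different worlds: every case being
slightly impaired, or a minority being substantially impaired. The
person-centered approach distinguishes these by classifying each individual
as *deficient* or *intact* per domain — emotion recognition, emotion
learning, and emotion regulation — against a normative cutoff (the bottom 10%
of age-matched controls, roughly 1.3 SD below the control mean), and then
asking how deficits overlap.

Because no raw data from such multi-site cohorts are publicly deposited, the
package pairs the full analysis pipeline with a synthetic cohort generator
whose latent structure makes the pipeline's estimand — the prevalence of each
deficit class — well-defined and recoverable. Everything downstream of the
generator is exactly the analysis one would run on real data.

## The generative model

Each participant belongs to one of $2^3 = 8$ latent deficit classes (the
subsets of {recognition, learning, regulation}), drawn from a group-specific
multinomial. Latent abilities (in SD-like units, higher = better) are

$$a_d = \beta_{age}(age-14) + \beta_{iq}(IQ-100) + \beta_{sex}\,male
        - \delta\,[d \in \text{class}] + \gamma\,[\text{CD, } d \notin \text{class}]
        + \sigma z_d,$$

with $z \sim MVN(0, R_{dom})$.

Key choices, made once at design time:

* **CD mixture.** The shipped replication configuration constrains the eight
  cell probabilities to every published aggregate: domain margins 23% / 13% /
  18% (recognition / learning / regulation), no-deficit 56.3%, pervasive cell
  1%, at-least-one 43.7%. These constraints leave the three pairwise-overlap
  cells underdetermined by one degree of freedom; we fix rec∩reg = 0.040,
  rec∩lrn = 0.025, lrn∩reg = 0.018 (their sum, 0.083, *is* determined). The
  TDC mixture is independence at 10% per domain, which reproduces the
  published control aggregates (24.6% / 2.4% / 0.1%) almost exactly.
* **Deficit shift $\delta = 1.8$ SD.** Places deficient individuals well
  below — but not trivially below — the normative cutoff.
* **Within-class dispersion $\sigma = 0.5$ SD.** This is the "high
  separability" setting and is *not* arbitrary: the cutoff is estimated from
  the control sample, which itself contains 10% deficient individuals per
  domain. The 10th percentile of the mixture
  $0.9\,N(0,\sigma^2) + 0.1\,N(-1.8,\sigma^2)$ sits at $\approx -1.15$ for
  $\sigma = 0.5$ but at $\approx -1.65$ for $\sigma = 1$; in the latter case
  classification structurally under-recovers the configured prevalences
  (about 18% recovered of a configured 23%). $\sigma = 0.5$ keeps
  within-class overlap realistic while making the estimand recoverable.
* **Intact-CD group shift $\gamma = -0.15$ SD.** Produces the small
  dimensional case-control effects characteristic of this literature without
  moving many intact cases over the cutoff.
* **Latent domain correlation 0.3.** The study reports adjusted mean
  correlations of 0.37 within domains and 0.12 between; if within-domain
  correlation reflects variable communality (~0.37), attenuation implies a
  latent correlation near 0.12/0.37 ≈ 0.32. Not otherwise identified — a free
  parameter, flagged as such.
* **Covariate effects** (age 0.08/yr, IQ 0.015/pt, male −0.10) are nuisance
  structure that the adjustment stage must remove; ages are uniform on
  [9, 19) with left-closed brackets 9–12, 13–15, 16–18.

Deficit classes are drawn independently of covariates; the only structural
risk-factor effect in the generator is maternal smoking on the learning
class (odds ratio 3.2), so the association layer has one known positive to
recover and true nulls elsewhere — matching the published pattern of mostly
null clinical correlates. The published sex and IQ associations with
recognition deficits are *not* generated.

## Task measurement models

Each domain is measured by its task's published design, simulated at trial
level:

* **Emotion Hexagon** (recognition): 5 blocks × 30 morphs over six expression
  continua at 90:10, 70:30, 50:50, 30:70, 10:90 mixtures. Correct-label
  probability is logistic in ability with an easier intercept for 90:10 than
  70:30 morphs; errors fall mostly on the continuum's other prototype;
  timeouts (1%) count as errors. Scoring counts errors over the 20 trials
  whose majority prototype is each expression; the thirty 50:50 morphs (one
  per continuum per block) are unscored — 120 scored trials = 6 × 20, the
  only assignment consistent with the published 0–20 per-expression range.
* **Passive Avoidance** (learning): 8 stimuli (4 rewarded / 4 punished;
  magnitudes 1, 700, 1,400, 2,000 points), 10 blocks with block 1 practice,
  bank starting at 10,000. Each stimulus carries a response propensity
  (initialized at a participant's response-bias draw) updated toward
  respond/avoid *only on feedback trials* (i.e., when the participant
  responded), with rate $base \times \mathrm{logit}^{-1}(s\,a) \times w_m$.
  Commission errors = responses to punished stimuli; omission errors =
  non-responses to rewarded stimuli, both as % of the nine scored trials.
* **Emotional Go/Nogo** (regulation): six pairing blocks of 35 go + 13 nogo
  trials; false-alarm probability is logistic in ability with a small
  emotional-interference offset per pairing. Only nogo false alarms are
  analyzed; go omissions are logged but unused.

Measurement parameters are design choices with two explicit criteria: each
variable group reaches the internal consistency the study reports
(Cronbach's α ≥ 0.70), and the factor scores track their latent abilities
well enough for prevalence recovery. The passive-avoidance settings
(base rate 1.0, ability slope 1.8, magnitude weights 0.4/0.7/0.85/1.0, bias
SD 0.10) are where these criteria bind: the task's fixed 8 × 9 scored-trial
design caps the reliability of its rate variables, and a steep
ability-to-learning-rate map is required to reach α ≥ 0.70. A consequence of
keeping response bias small is that commission and omission errors load with
the *same* sign on the learning component, unlike the published bipolar
pattern (punishment errors positive, reward errors negative), which indicates
a bias-dominated component; a bias-dominated component cannot recover
learning-deficit prevalence, so we prioritize the recoverable structure and
note the difference.

Pipeline-scale runs draw scores from the same per-trial models vectorized
across participants (binomial sums for hexagon/go-nogo; the sequential
propensity chains iterated across all participants for passive avoidance) —
score-level sampling from identical distributions, not an approximation.

## Analysis stages

1. **Adjustment.** Each of the 20 raw variables is regressed on age, IQ and a
   sex indicator (OLS; pooled sample by default, controls-only available) and
   the residuals standardized by the fit-sample residual SD — mean 0, SD 1
   over the fit sample, zero correlation with each covariate, idempotent.
2. **Diagnostics.** Pearson correlations; Olkin–Pratt corrected mean
   correlation within vs between domains, $r(1 + (1-r^2)/(2(n-3)))$ applied
   element-wise before averaging, with percentile bootstrap CIs over
   participants (2,000 resamples by default) and a Fisher r-to-z contrast;
   KMO from the inverse correlation matrix; Bartlett's sphericity
   $-(n-1-(2p+5)/6)\ln|R|$ on $p(p-1)/2 = 190$ df.
3. **Confirmatory PCA.** Eigendecomposition of the correlation matrix, the
   first $k = 3$ components retained *a priori* (no eigenvalue > 1 rule);
   varimax with Kaiser normalization (convergence 1e-10); column signs
   oriented so salient loadings (|λ| ≥ 0.30, display threshold only) are
   majority-positive; components assigned to domains by the task block with
   the largest mean absolute loading over all bijections. Rotated
   "eigenvalues" are post-rotation sums of squared loadings and are labeled
   as such. Rotation preserves communalities to 1e-10 and the full spectrum
   sums to 20.
4. **Anderson–Rubin scores.** $F = Z_c R^{-1} L\,(L'R^{-1} S R^{-1} L)^{-1/2}$
   (symmetric inverse square root): exactly mean 0, SD 1, mutually
   uncorrelated. Because every battery variable is an error score, a
   component's raw orientation indexes *poor* performance; scores are
   reflected (per component, against the mean adjusted error level of its
   salient variables) so that higher = better before classification. The
   loading matrix itself is reported unreflected.
5. **Classification.** Per domain × age bracket, the cutoff is the empirical
   10% quantile of control factor scores — linear-interpolation order
   statistics (R type 7) by default, nearest-rank (type 1) as an option; a
   score exactly at the cutoff is deficient ("within the bottom 10%").
   Controls are classified in-sample against their own bracket thresholds
   (no leave-one-out), so with bracket sizes divisible by 10 exactly 10% of
   controls are flagged per domain. `q = 0` is allowed and flags nobody.
6. **Overlap analytics.** Cell/margin/aggregate proportions per group;
   Pearson chi-square (no continuity correction) per domain between groups;
   the closed-form independence expectation $1-(1-q)^k$, $\binom{k}{m} q^m
   (1-q)^{k-m}$. At $q = 0.10, k = 3$ the any-deficit expectation is 27.1% —
   the published parenthetical "≥30%" does not match this closed form, and
   the package reports the closed form.
7. **Dimensional statistics.** A 3 (domain, within) × 2 (group, between)
   split-plot ANOVA with sums of squares computed directly (an `aov()`
   `Error()` stratum materializes an n-level subject design and does not
   scale to cohort-sized samples; `aov` is retained as a test oracle);
   partial $\eta^2 = SS_e/(SS_e + SS_{err})$ with 95% CIs by noncentral-F
   inversion and the 0.01/0.06/0.14 benchmark labels; Greenhouse–Geisser
   epsilon alongside uncorrected tests; Bonferroni per-domain contrasts.
   With $n$ participants the correct within df are $2(n-2)$ — the published
   df pair (2,500)/(1,250) is internally inconsistent with $n = 1252$ and is
   not reproduced. Logistic discrimination of group membership from the
   three scores reports the likelihood-ratio model chi-square (3 df), Wald
   chi-squares, odds ratios, Hosmer–Lemeshow over 10 risk deciles, and
   sensitivity/specificity at a 0.5 posterior cutoff (configurable; the
   published cutoff is unstated) with Wilson score CIs.
8. **Correlates.** YPI CU traits: a trait is endorsed when ≥1 item of its
   subscale scores 4; the LPE proxy requires ≥2 endorsed traits. The source study
   does not list the subscale item indices, so a documented 3 × 5 map
   (`ypi_cu_map()`) is fixed as the single source of truth for generator and
   scorer; missing YPI items are a validation error (no prorating). RPQ:
   fixed 11/12 item partition. Association layer: per outcome one
   linear/logistic model on the three flags plus per-flag two-group contrasts
   (Pearson chi-square / Welch t), uncorrected p-values as published
   (Benjamini–Hochberg available but off in replication mode); risk-factor
   models: one logistic model per domain flag on sex, IQ, smoking, SES,
   parental delinquency, CECA, SAHA.

## Reproducibility and numerics

One master seed drives everything; each stochastic stage derives its own
substream seed from the master seed and a stage label, so stage-level reruns
are reproducible. Reruns of `run_pipeline()` with the same configuration are
byte-identical apart from the manifest's timestamps. Bootstrap CIs consume a
dedicated substream. Degenerate inputs fail loudly: non-positive-definite
correlation configs, zero-variance or collinear adjustment inputs, singular
correlation matrices (Bartlett), complete separation in logistic fits, empty
normative brackets.

## What the simulations show — and what they cannot

Test problem sizes are chosen to make Monte-Carlo error small relative to
the quantities checked: mixture recovery at $n_{CD}=5{,}000$; the
independence overlap at $n = 10^5$ (3 Monte-Carlo SEs ≈ 0.4 pp for the
any-deficit proportion); end-to-end prevalence recovery at 5,420 CD / 7,100
TDC (ten times the study's CD group). Passing these shows the pipeline is
internally coherent: it recovers the latent structure its generator encodes,
under measurement models that respect the published task designs and
reliabilities. It cannot validate distributional features of real cohorts
that the generator does not emulate — site effects, missingness, floor
effects in clinical controls, non-Gaussian ability distributions, or
questionnaire response styles. Conclusions about real data rest on the
analysis stages, whose correctness is established against independent
oracles (closed forms, hand computations, grid searches), not on the
generator.

## Known limitations

* The learning domain's measurement ceiling (72 scored trials) caps its
  factor-ability fidelity near 0.8; learning prevalences recover with a
  ~1 pp downward bias at the replication settings.
* The three pairwise-overlap cells of the CD mixture are one design choice
  among those compatible with the published aggregates.
* The generator's clinical-correlate nulls make the association layer's
  specificity testable but give no positive signal except the configured
  smoking-learning effect.
* No reaction times, site effects, or missing data are simulated.
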