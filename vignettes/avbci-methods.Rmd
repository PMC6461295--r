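---
title: "Modelling audiovisual spatial localisation with hierarchical causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling audiovisual spatial localisation with hierarchical causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avbci)
```

## The scientific problem

When a sound and a flash occur together, an observer must decide whether
they came from one event (and should be integrated) or from two (and should
be kept apart) — the *causal inference* or *binding* problem. In the spatial
ventriloquist paradigm, synchronous auditory and visual stimuli are
presented at independently sampled azimuthal locations and the observer
reports the location of one modality. Cross-modal biases, their dependence
on spatial disparity, visual reliability and task relevance, and the
time-resolved neural representations of space together diagnose the
computation the brain performs.

`avbci` implements the complete analysis chain for this paradigm:

1. the factorial **design** (4 visual x 4 auditory locations x 2 visual
   reliabilities x 2 report modalities, plus unisensory conditions);
2. the hierarchical **Bayesian causal inference (BCI) observer model** and
   its special cases;
3. maximum-likelihood **fitting** of discrete localisation responses and
   **random-effects Bayesian model selection**;
4. the circular **audiovisual weight index** with permutation inference;
5. multivariate **decoding** of spatial estimates from trials x channels x
   time activity, with temporal generalisation;
6. **synthetic-data generators** so the whole chain runs end-to-end without
   any recordings.

## The observer model

The generative model assumes a common cause with prior probability
$p_{\mathrm{common}}$. Under a common cause the source location $S$ is drawn
from a central spatial prior $N(0, \sigma_P^2)$ and both internal samples
are noisy readings of it, $x_A \sim N(S, \sigma_A^2)$,
$x_V \sim N(S, \sigma_V^2)$; under independent causes each modality has its
own source. Visual noise takes one of two values,
$\sigma_{V1}$ (high-reliability cloud) or $\sigma_{V2}$ (low), auditory
noise is $\sigma_A$. The posterior probability of a common cause combines
the prior with the two marginal likelihoods, which are Gaussian and are
evaluated in closed form; `posterior_common_cause()` is verified against
numerical quadrature to $10^{-6}$ in the test suite.

Conditional on the causal structure the optimal estimates are the
reliability-weighted *fusion* estimate (common cause) and the *segregated*
single-modality estimates (independent causes). The decision rules
combine them:

* **model averaging** (the default): posterior-weighted average of fusion
  and the task-relevant segregated estimate;
* **model selection**: the estimate of the more probable structure, with a
  posterior of exactly 0.5 routed to segregation;
* **probability matching**: stochastic selection against a uniform draw.

Forced fusion is the model with $p_{\mathrm{common}} = 1$ fixed; full
audiovisual segregation has $p_{\mathrm{common}} = 0$; the unisensory
read-out models report one modality's segregated estimate regardless of
task. Free-parameter counts are 5 (BCI variants), 4 (fusion, audiovisual
segregation), 3 (visual read-out) and 2 (auditory read-out); the prior mean
is fixed at zero (central bias) throughout.

## Fitting discrete responses

Responses are four buttons at $-10^\circ, -3.3^\circ, 3.3^\circ, 10^\circ$;
a continuous estimate maps to the nearest button, exact midpoints to the
leftmost. The per-condition response distribution has no closed form, so it
is marginalised by Monte Carlo: `n_sim` draws of $(x_A, x_V)$ per condition
are pushed through the decision rule and binned. The per-condition draws
come from fixed, condition-indexed streams (common random numbers), so the
likelihood surface is deterministic for the optimiser and bit-reproducible
for a given seed. The log likelihood is multinomial with the count-only
coefficient dropped (it cancels in every comparison); predicted
probabilities are floored at $10^{-6}$ before logging.

Optimisation is a grid search (defaults: prior 0.1–0.9 in steps of 0.2,
every SD in 0.5–32 degrees doubling) followed by Nelder–Mead simplex
refinement on transformed scales (logit for the prior, log for SDs). Two
numerical choices matter in practice and are exposed as options:

* the simplex is **restarted** from its incumbent until no improvement —
  in five dimensions a single Nelder–Mead run frequently terminates on a
  collapsed simplex several nats short of the optimum;
* an optional **polish stage** reruns the simplex on a larger simulation
  size; a more precise surface settles the optimum along nearly flat
  ridges. The $p_{\mathrm{common}}$–$\sigma_P$ profile is such a ridge: at
  96 trials per condition the two parameters trade off within a fraction of
  a nat, which is the dominant source of between-dataset scatter in
  recovered priors. Recovery simulations at ten-fold data volume confirm
  the estimator is consistent ($\hat p_{\mathrm{common}} \to 0.15$,
  $\hat\sigma_P \to 36$ at the group-mean generating values).

One identifiability caveat: with buttons spaced $6.6^\circ$ apart, any
high-reliability visual noise below about one degree predicts essentially
deterministic visual responses, so $\sigma_{V1}$ is identified only by an
upper bound.

Fit quality is summarised by a likelihood-ratio coefficient of
determination against the uniform-guessing null ($\ln 0.25$ per trial),
scaled by its maximum attainable value $1 - 0.25^2 = 0.9375$ and clipped to
$[0, 1]$. Model evidence uses the information criterion in the form
$-\ln\hat L + k \ln n$ (natural logarithms); this halves the conventional
$-2\ln\hat L$ scale, a deliberate fidelity choice — `bic(conventional =
TRUE)` provides the usual form, and because the same convention enters every
model's evidence the group-level selection is unchanged in ordering, though
absolute evidence differences are halved.

## Group-level model selection

`rfx_bms()` treats the model behind each subject's data as a random effect
with population frequencies $r \sim \mathrm{Dirichlet}(\alpha_0 = 1)$ and
fits the variational scheme to the per-subject log evidences ($-\mathrm{BIC}$).
Exceedance probabilities come from Dirichlet sampling (default $10^6$
draws, seeded). The Bayes omnibus risk (BOR) compares the free energy of
the random-effects model with the equal-frequency null, and the protected
exceedance probability is
$\mathrm{PEP} = \mathrm{EP}\,(1 - \mathrm{BOR}) + \mathrm{BOR}/K$.
With identical evidences the scheme is exchangeable by construction
(PEP $= 1/K$); note that with a typical cohort size the BOR at exactly
identical evidences is high but not 1 — protection saturates only as the
evidence differences vanish relative to what $n$ subjects could detect.

## The audiovisual weight index

For each of the eight cells of the 2 (reliability) x 2 (task) x 2
(disparity: $\le 6.6^\circ$ versus larger) factorial, one ordinary
least-squares regression predicts the reported (or decoded) locations from
the true visual and auditory locations — 16 slope regressors plus an
intercept. The weight index is the four-quadrant angle
$w_{AV} = \mathrm{atan2}(\beta_V, \beta_A) \cdot 180/\pi$: $90^\circ$ is
pure visual dominance, $0^\circ$ pure auditory, values above $90^\circ$
indicate auditory repulsion. Behavioural regressions use button locations
in degrees (the responses *are* locations); neural regressions use the
continuous decoded estimates.

Because $w_{AV}$ is an angle, all statistics are circular. Means and 68%
confidence intervals use the standard Upton/Zar construction; the
circular-circular correlation is the sine-moment coefficient. Effects in
the factorial are measured by a likelihood-ratio statistic (LRTS) under a
von Mises likelihood with a common maximum-likelihood concentration: the
full model fits separate mean directions for the contrasted levels, the
null pools them. Interactions are built as main effects of within-subject
angular *differences* (difference of simple effects; the three-way uses a
second difference) — this matches the permutation schemes exactly, and
because all inference is by randomisation the parametric form only shapes
the statistic, never the validity. Permutations respect the
within-participant design: tested-factor labels shuffle within the levels
of the nontested factors; two-way interactions shuffle the four cells of
the two factors of interest within the third; the three-way shuffles all
eight cells. P-values are $(b+1)/(B+1)$ and never zero.

Time courses are corrected with maxsum cluster permutation: per-time
statistics above the permutation $1-\alpha$ quantile form temporally
contiguous clusters whose summed mass is referred to the permutation null
of the maximum mass (two-tailed for signed statistics, with clusters per
sign). The two-dimensional version on training x testing time matrices uses
4-connected components and sign-flip one-sample t statistics on Fisher
z-transformed accuracies. Calibration suites (200 null datasets x 500
permutations) verify the ~5% type-I/family-wise rates.

## Decoding and temporal generalisation

Trials are averaged in randomly partitioned groups of eight same-condition
trials into pseudo-trials (remainders dropped), then a linear support
vector regression (LIBSVM via `e1071`, $C = 1$, $\varepsilon = 0.001$)
learns the mapping from channel patterns to stimulus locations at every
time point, in 12-fold condition-stratified cross-validation. Channels are
standardised per time point with training-fold statistics — the SVR is
scale-sensitive and the choice is stated here because recordings do not
dictate it. Accuracy is the Pearson correlation between true and decoded
locations pooled over folds.

Temporal generalisation evaluates the model trained at one time at every
other time: cross-validated within a modality (the matrix diagonal equals
the plain decoding time course, a tested identity), and trained on all
pseudo-trials of one modality and tested on all of the other across
modalities (disjoint data, so no cross-validation is required — the chosen
reading where the procedure is underdetermined). Testing a decoder on its
own training trials is refused as a guarded leakage path.

For the audiovisual analysis the decoder is trained on the spatially
congruent conditions pooled over task and reliability, and decodes every
audiovisual pseudo-trial; congruent trials are decoded only by folds that
did not train on them. The decoded estimates feed the same weight-index and
model-fitting machinery as behaviour, after binning each estimate to the
nearest of the four true locations. Neural weight time courses are smoothed
with a 20-ms moving average applied to the regression weights (not to the
angles, which would misbehave at the wrap-around) before the angle is
recomputed.

## What the synthetic data emulate — and what they do not

`simulate_behavior()` draws internal samples per trial and applies the
observer's decision rule on the full 60-run, 7,680-trial schedule; its
response frequencies converge to the independently implemented
`predict_response_pmf()`, a cross-implementation agreement tested within
binomial error. Default generating parameters are the group-mean
behavioural estimates ($p_{\mathrm{common}} = 0.15$, $\sigma_P = 36.4$,
$\sigma_A = 4.4$, $\sigma_{V1} = 0.3$, $\sigma_{V2} = 3.5$ degrees); cohort
jitter is applied on the logit/log scales with defaults (0.3 on the logit
prior, 0.1–0.2 on log SDs) chosen once to mimic the reported
between-subject spread.

`simulate_eeg()` builds activity as a sum of stage-gated rank-one
encodings: an early visual stage (60–100 ms) encoding the true visual
location, a fusion stage (100–250 ms) encoding the reliability-weighted
estimate, and a causal-inference stage (350–700 ms) encoding the
task-relevant model-averaging estimate, each through its own orthonormal
seeded channel template, with raised-cosine 10-ms gate ramps (hard boxcars
would create degenerate single-sample clusters) and white channel noise.
The unisensory simulator adds a window (default 160–360 ms) in which both
modalities share one template, so cross-modal generalisation can succeed
only there. These timings are modelling devices for the qualitative staging
— early visual dominance, then reliability-weighted fusion, then causal
inference — not estimates of real latencies.

Two sizing choices in the bundled staging demonstration deserve
justification. First, the channel noise is set so that congruent decoding
accuracy lands near 0.9 rather than 1: binned decoded estimates then have a
dispersion comparable to the 6.6° button spacing, which is the regime in
which a multinomial fit can read distributional structure at all (with
near-noiseless decoding every condition collapses onto a single button and
the model comparison degenerates to the complexity penalty). Second, the
cohort driving the staging run uses a mid-range common-cause prior (0.5)
rather than the group-mean behavioural value (0.15): after 8-trial
pseudo-averaging and 4-button binning, the late-stage causal-inference
signature of a 0.15-prior observer is worth only a few nats of likelihood
per subject — below the evidence penalty of the extra parameter — so a
weak-prior observer's late stage is not identifiable at desk scale. The
staging run is a demonstration that the pipeline resolves stage-wise codes,
and uses an observer for whom each stage is decisively identifiable; it is
not a claim about the group-mean observer.

The generators deliberately omit volume conduction, 1/f noise, trial-order
and fatigue effects, reaction times and artifacts. Passing tests therefore
show that the *analysis chain* recovers the computational structure placed
in the data at realistic noise levels; they do not certify decoding onsets
or latencies in real recordings, which depend on unavailable raw data.

One behaviour of correlation-based decoding deserves note: with
near-deterministic synthetic encodings, a decoder tested on a modality
whose code it never saw produces $\pm 1$ correlations with
subject-specific random signs (any residual projection of the weights onto
the unseen template dominates the tiny noise). Group-level statistics
handle this correctly — the signs cancel across subjects — and the test
suite checks cross-modal confinement at the group level for exactly this
reason.

## Problem sizes and reproducibility

Every stochastic stage takes a seed, and sub-seeds are derived
deterministically from one master seed, so pipeline runs reproduce bit for
bit. The bundled study-scale runs use sizes chosen to keep a complete
analysis on a single CPU in minutes: parameter recovery simulates one
observer at 96 trials per audiovisual condition and fits with 2,000 draws
per condition (1,000 during the grid stage, 10,000 in the polish); the
13-subject cohort comparison uses a coarser four-point SD grid (0.5, 2, 8,
32 degrees) before simplex refinement; synthetic EEG runs use 16–32
channels on a 20-ms grid with model fits at representative time points per
stage window. These are the package's default study sizes, not limits of
the method; all of them are configuration fields.

## Known limitations

* $\sigma_{V1}$ is bounded, not point-identified, by button-discretised
  responses (see above).
* The recovered common-cause prior scatters along the
  $p_{\mathrm{common}}$–$\sigma_P$ ridge at single-session data volumes;
  group-level conclusions (model selection, weight-index effects) are
  robust to this, point estimates of the prior less so.
* The LRTS interaction construction differences one factor; the statistic
  is not symmetric in which factor is differenced (the permutation null is
  matched to the construction, so validity is unaffected).
* The evidence convention follows the printed half-scale criterion; compare
  absolute evidences across software with care.
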