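---
title: "Modelling choices, confidence and changes-of-mind under controllability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choices, confidence and changes-of-mind under controllability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volinfer)
```

# The task and its generative statistics

`volinfer` studies a two-alternative reversal task in which an observer
tracks a hidden binary state through sequences of oriented-bar stimuli. Two
conditions differ only in the degree of control over evidence sampling:

* **C- (uncontrollable)**: the hidden state is the category being drawn;
  the observer monitors it and reports it after each sequence.
* **C+ (controllable)**: the hidden state is the mapping from the agent's
  actions to drawn categories; the agent acts first and the next sequence
  is the outcome of that action passed through the hidden mapping.

The generator (`task_config()`, `generate_session()`) reproduces the
design's statistics: 8 blocks of 72 trials (576 total), hidden-state
episodes drawn from a truncated exponential on 4–24 trials, sequences of
2/4/6/8 stimuli drawn uniformly, and stimulus orientations drawn from one
of two von Mises categories with concentration $\kappa = 0.5$ whose means
are $\pi/2$ apart. Orientations are axial, so all circular computations
live on the doubled angle $2\theta$ (period $2\pi$); exposed values are in
$[0, \pi)$.

Two generator choices were open and fixed once:

* The truncation bounds are stated by the design but the exponential scale
  is not; the default scale of 5 trials yields a mean episode length of
  about 9 trials and a near-constant per-trial reversal hazard of
  $1 - e^{-1/5} \approx 0.18$ away from the truncation points, which is
  what a near-constant-hazard design requires.
* Block conditions alternate, with the starting condition set by the
  parity of the session seed, mirroring pseudo-random counterbalancing
  across participants.

## Canonical stimulus draws and the closed loop

A session stores each trial's stimuli as *canonical* draws from category
+1. Because the two category distributions are mirror images on the
doubled circle, a category $c$ realization is the canonical draw shifted
by the category gap, and the stimulus log-likelihood ratio (LLR) flips
sign: `realize_orientations()` applies the map exactly. The evidence a
trial carries about the hidden state is then

$$\mathrm{ev}_t = s_t \sum_i \ell_i,$$

with $s_t$ the hidden state and $\ell_i$ the canonical per-sample LLRs —
*in both conditions*. In C- the drawn category is $s_t$ directly. In C+
the category is $s_t \cdot a_{t-1}$, but the agent recodes evidence
relative to its own previous action $a_{t-1}$, and the two signs cancel.
This makes the inference engine literally shared between conditions and
makes closed-loop simulation on "the same stimuli" exact: any action
stream realizes its own categories from the same canonical noise.

# The observer

The observer (`model_params()`, `simulate_agent()`) is the normative
log-odds filter for a symmetric two-state world with reversal probability
$h$ per trial. Before each sequence the belief $L$ passes through the
reversal opportunity,

$$\psi(L) = L + \log\!\big(\tfrac{1-h}{h} + e^{-L}\big)
              - \log\!\big(\tfrac{1-h}{h} + e^{L}\big),$$

which is odd in $L$, strictly increasing for $h < 1/2$, and bounded by
$\log\frac{1-h}{h}$ — beliefs cannot grow without bound when reversals are
possible. Each stimulus contributes its LLR, which for orthogonal category
means reduces to $2\kappa\cos 2(\theta - \mu)$, corrupted by i.i.d.
Gaussian *inference noise* of SD $\sigma_\mathrm{inf}$ per sample, so the
accumulated noise variance grows linearly with sequence length. The choice
is the sign of the posterior belief — there is no selection noise — with
exact ties broken toward repetition.

Confidence is a thresholded readout of the same posterior belief:

$$\text{high} \iff |L_\mathrm{post}| \cdot g^{[\mathrm{switch}]} + \eta
   > \theta_c, \qquad \eta \sim \mathcal N(0, \sigma_\mathrm{meta}^2),$$

with a *confidence threshold* $\theta_c$, *metacognitive noise*
$\sigma_\mathrm{meta}$ corrupting only the readout, and a multiplicative
*confidence gain* $g$ applied to the absolute belief on switch trials
only. Whether the metacognitive noise enters before or after the absolute
value is not dictated by the model's verbal description; the default
applies it after the gain (`order = "gain-before-noise"`), and the
alternative order is available as an argument.

The five parameters and their fitting bounds: hazard
$h \in [10^{-6}, 1-10^{-6}]$, $\sigma_\mathrm{inf} \in [0, 10]$,
$\theta_c \in [-10, 10]$, $\sigma_\mathrm{meta} \in [0, 10]$,
$g \in [0, 10]$. Lower $h$ makes beliefs stickier: more inconsistent
evidence is needed to reverse them. This single mechanism yields the
qualitative signatures of control probed by the acceptance checks: a
larger-magnitude choice-PSE, a lower switch rate, and stronger absolute
prior beliefs.

# Psychometrics

`build_reversal_curve()` pools trials around reversals (default window
$-4$ to $+8$, clipped to the surrounding episodes). The choice curve is
fitted by `fit_reversal_exponential()` with the two-parameter recovery

$$p(k) = A - (2A - 1)\,e^{-k/\tau},$$

which starts at the mirrored pre-reversal level $1-A$ just after the
reversal and recovers to the asymptote $A$ with time constant $\tau$; the
functional form for this two-parameter (asymptote, time constant) family
was chosen here since only the parameterization, not the formula, is
conventionally reported. Confidence reversal curves use the
exponential-learning form $p(k) = p_\min + (p_\max - p_\min)(1 -
e^{-k/\tau})$, and the *confidence drop* is the gap between the upper
asymptote and the curve's value at the first post-reversal trial,

$$\mathrm{drop} = p_\max - \big[p_\min + (p_\max - p_\min)(1 -
e^{-1/\tau})\big] = (p_\max - p_\min)\,e^{-1/\tau}.$$

The time-constant-corrected drop admits a second parenthesization,
$(p_\max - p_\min) + (p_\max - p_\min)(1 - e^{-1/\tau})$; both are
implemented in `confidence_drop()` and the first is the default, because
it is the one that vanishes in both degenerate limits ($p_\max = p_\min$
and $\tau \to 0$, where trial 1 already sits at the asymptote).

Repetition analyses recode each trial's summed noiseless LLR by the
previous choice (`signed_evidence()`; positive = consistent with
repeating). `fit_repetition_logistic()` fits P(repeat) at the trial level;
the *choice-PSE* is the evidence level of indifference
($-\beta_0/\beta_1$) and the slope is the sensitivity. Complete separation
falls back to the Gaussian-prior MAP solver with a warning; single-class
subsamples return degenerate-flagged fits rather than errors so that
group-level pipelines keep running — mirroring the practice of excluding
noisy individual estimates and using rank tests at the group level.
`fit_confidence_dual_sigmoid()` fits separate confidence sigmoids for
repeat and switch trials; since both share the logistic link, their
crossing (the *confidence-PSE*) is solved exactly from the linear
predictors, with parallel or out-of-range crossings flagged instead of
fabricated. Evidence is binned into 8 equal-count bins for display and
for the simulation-based likelihood; the psychometric fits themselves are
trial-level.

# Change-of-mind statistics

`change_of_mind_metrics()` tabulates switch rates, the fraction of
switches confirmed on the next trial, and high-confidence fractions by
response type and by switch outcome. Group-level inference uses
`rm_anova_2x2()` (base `aov` with the within-participant error strata;
participants lacking any cell are dropped listwise, with a jackknife
alternative), `map_logistic_regression()` — a damped-Newton MAP solver
with independent $\mathcal N(0, 2^2)$ priors on every coefficient, which
keeps estimates finite when cells are sparse or separable — and
`group_level_tests()` (one-sample/paired t plus Wilcoxon signed-rank).
Factors use effects coding ($\pm 1$) and the evidence covariate is
standardized within participant so coefficients are comparable across
participants; both choices are conventions the verbal analysis description
leaves open.

# Model fitting

`fit_model()` maximizes a simulation-based likelihood
(`curve_neg_log_likelihood()`): the model's per-bin event probabilities
for four curve targets — choice and confidence reversal curves, the
choice repetition curve, and confidence repetition curves split by
repeat/switch (the split is what identifies the switch-specific gain) —
are estimated from 200 seeded simulations per evaluation and compared to
the observed bin counts under a binomial likelihood, floored at
$10^{-3}$. All targets carry equal weight; no weighting is dictated and
equal weighting is the neutral choice.

Numerical choices that matter:

* **Common random numbers**: all simulation noise is pre-drawn from the
  fit seed independently of the parameters, so the objective is a
  deterministic, nearly smooth function of the parameters and bounded
  derivative-free search is well posed.
* **Rao–Blackwellized confidence**: confidence feeds nothing downstream,
  so the metacognitive noise is marginalized analytically —
  $P(\text{high}) = \Phi\big((|L|g - \theta_c)/\sigma_\mathrm{meta}\big)$
  per simulated trial — rather than sampled, removing a large Monte-Carlo
  variance component from the confidence targets.
* **Bounded transforms + multi-start Nelder–Mead**: parameters are mapped
  to the real line by scaled logits of their bounds; a cheap random
  pre-screen selects the starting points, near-tied optima are re-ranked
  under 10-fold simulations, and the winner is briefly polished. A
  specialized noisy-objective optimizer would also satisfy this contract;
  the claim is the estimate, not the optimizer brand.

`validate_model()` re-simulates fitted parameters (50 simulations by
default) and rebuilds the same curves for overlay on the data.
`parameter_recovery()` samples generative parameters uniformly within
plausible sub-ranges of the fitting bounds (hazard 0.05–0.4, noises 0–3,
threshold 0–4, gain 0.5–2 — fixed plausible ranges, since
participant-derived ranges would require the behavioral dataset), then
simulates, refits, and reports the 5×5 Spearman matrix between generative
and recovered parameters.

## What recovery can and cannot show

With 288-trial single-condition sessions, hazard, inference noise,
confidence threshold and confidence gain recover sharply. Metacognitive
noise does not recover reliably under these sampling ranges, and the
failure is informative rather than numerical: in the low-hazard,
high-inference-noise corner of the box the absolute belief is almost
always far above threshold, confidence saturates, and the binned
confidence curves constrain only one function of
$(\theta_c, \sigma_\mathrm{meta})$ — two distant parameter pairs produce
curves differing by less than binomial noise at this data size. Pinning
the other parameters in a non-saturated regime restores sharp
$\sigma_\mathrm{meta}$ recovery, which localizes the limitation in the
data regime, not the estimator. Users fitting real sessions should check
that confidence usage is not saturated before interpreting
$\sigma_\mathrm{meta}$.

# Latent inference

`particle_filter()` runs sequential importance resampling over the noisy
belief path, conditioned on the observed responses: per trial, each
particle's weight is multiplied by the probability of the observed choice
(an indicator, since selection is noiseless) and, by default, of the
observed confidence (the Gaussian-CDF probability above). Systematic
resampling triggers when the effective sample size falls below half the
particle count; total weight collapse is rejuvenated with a warning. The
per-trial outputs are the conditioned posterior means of the two latents
used downstream: the absolute pre-sequence belief (*prior belief*) and
the trial's summed noisy evidence signed by the prior's direction
(*evidence direction*). A choices-only conditioning mode is available;
the default also uses confidence because both are model outputs. The
particle count (default 1000) and resampling scheme are implementation
choices verified against exhaustive grid integration on small problems.

# Problem sizes and limitations

The test suite and the bundled analysis script run entirely on synthetic
data at deliberately moderate sizes — e.g. recovery at 20 datasets of
288 trials, calibration checks at 1000 null replicates, filter/oracle
comparisons on 3-trial toys with 200k particles — chosen to exercise
every contract while keeping a full run in the minutes range.

What the synthetic generator does not emulate: response times and their
dependence on evidence; lapses, biases, and key-mapping confusions;
sequential effects outside the modelled belief dynamics (e.g. the
post-switch hypothesis-testing behavior that real agents show under
control beyond what a lower hazard predicts); and any neurophysiological
observables. Passing tests therefore certify the computational pipeline
and its statistical calibration, not the behavioral completeness of the
model.
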