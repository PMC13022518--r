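---
title: "Modelling reward learning under punishment contexts with rewpun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward learning under punishment contexts with rewpun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewpun)
```

# The scientific problem

Most reinforcement-learning experiments study rewards and punishments in
isolation, yet in natural environments they co-occur. `rewpun` implements a
complete analysis pipeline for asking whether the *presence* of punishments
changes how people learn from rewards: a probabilistic two-armed-bandit task
simulator with mixed- and single-valence blocks, a Q-learning model family
with valence-specific learning rates, maximum-likelihood and
maximum-a-posteriori fitting, random-effects Bayesian model selection,
behavioral statistics, event-related BOLD analyses keyed to punishment
history, and a coordinate-based meta-analysis (MKDA) with bootstrap
balancing. Because no participant-level data ship with the package, every
stage is validated against synthetic data with known ground truth; the
generators are first-class, tested code.

# The task

Six blocks of 40 trials (240 trials). Block types: reward-only (choices
yield +1 or nothing), punishment-only (-1 or nothing), and mixed (one
reward pair, one punishment pair), each type appearing twice in an
alternating, counterbalanced order. Each block has two stimulus pairs with
20 trials per pair; within a block, pair order is pseudorandomized so no
pair repeats more than four times consecutively (`make_schedule()` uses
rejection sampling of random interleavings -- the simplest sampler
satisfying the constraint). The "good" option of a reward pair wins with
probability 0.75 (behavioral version) or 0.70 (fMRI version); the "good"
option of a punishment pair is the one that loses with the complementary
low probability. Trials on which a (human) participant fails to respond are
marked invalid and excluded everywhere downstream; the simulator produces
them only on request (`miss_rate`, default 0, since model agents do not
time out). Response times carry a constant placeholder because no latency
model is part of the pipeline.

# The model

For the chosen option of the presented pair,

$$Q(t+1) = Q(t) + \alpha\,\delta(t), \qquad
  \delta(t) = \rho\, r(t) - Q(t),$$

with outcome coding $r \in \{1, 0\}$ for reward pairs and $\{0, -1\}$ for
punishment pairs, so positive prediction errors (PEs) correspond to reward
delivery or punishment omission and negative PEs to reward omission or
punishment delivery. The learning rate is $\alpha^+$ for $\delta > 0$ and
$\alpha^-$ for $\delta < 0$; at $\delta = 0$ the update is zero under
either branch, so the (formally undefined) tie costs nothing. Choices
follow a two-option softmax with inverse temperature $\beta$,

$$P(A) = \frac{1}{1 + e^{-\beta\,(Q_A - Q_B)}},$$

computed with the exponent clipped at $\pm 700$ and probabilities floored
at $10^{-12}$ inside logarithms -- numerical guards that cannot move optima
at realistic parameter values. Initial values default to the signed-half
scheme (+0.5 for reward pairs, -0.5 for punishment pairs), which reflects
the known outcome range in each valence; `zero` and `free` schemes are
available, and the free scheme estimates one starting value per valence
(configurable), since a single shared value cannot respect the sign
asymmetry of the two valences.

The optional sensitivity parameter $\rho$ rescales outcomes before the PE
($\rho = 1$ recovers the base model exactly, a tested identity). The
context-comparison variants (`null`, `alpha_only`, `beta_only`, `full`)
use a single learning rate and fit a valence's mixed + single-context
trials as one joint likelihood, sharing or splitting $\alpha$ and $\beta$
by context; the main dual-rate model is fit separately per condition
(reward-mixed, reward-only, punishment-mixed, punishment-only), so four
fits per subject.

# Fitting

`fit_condition()` minimizes the negative log-likelihood (MLE) or negative
log-posterior (MAP) with `nlminb` on the natural scale under box
constraints: $\alpha \in [0, 1]$, $\beta \in [0, 50]$,
$\rho \in [0, 3]$. The $\beta$ range covers essentially all prior mass and
the fixed-$\beta = 10$ robustness check; a best fit on the upper bound is
flagged (`converged = FALSE`) rather than silently accepted. Ten random
starts are drawn from the MAP priors -- Beta(1.1, 1.1) for learning rates
and Gamma(shape 15, scale 0.75) for $\beta$ (mean 11.25, mode 10.5; the
scale parameterization is recorded in `prior_spec()` and a rate form is
accepted). Multi-start optimization on the natural scale was chosen over a
logit/log transform because the box-constrained quasi-Newton search proved
as reliable as the unconstrained form against an exhaustive grid oracle
(`grid_oracle()`, up to $10^6$ evaluations), while keeping estimates and
bounds directly interpretable; the suite asserts the optimizer never loses
to the grid by more than $10^{-3}$ nats. MAP adds independent log-priors on
the learning rates and $\beta$ only; $\rho$ fits run MLE, mirroring its
role as a rejected extension. With an empty stream MAP returns the prior
modes ($\alpha = 0.5$, $\beta = 10.5$). Seeds fully determine starts, so
refits are bit-identical.

# Model selection

`bic()` uses $2\,\mathrm{nll} + k \ln n$ with $n$ the valid-trial count;
log model evidence is approximated as $-\mathrm{BIC}/2$ (natural logs).
`rfx_bms()` implements the variational Dirichlet–multinomial scheme for
random-effects group model comparison: Dirichlet prior $\alpha_0 = 1$ per
model, convergence at $10^{-6}$ on the counts, 500-iteration cap (flagged,
not fatal). Exceedance probabilities come from $10^5$ seeded Monte-Carlo
Dirichlet draws -- sampling generalizes uniformly to any number of models,
unlike the K = 2 closed form. The Bayes omnibus risk compares the
random-effects free energy with the equal-frequency null, and protected
exceedance probabilities are $\mathrm{EP}(1 - \mathrm{BOR}) +
\mathrm{BOR}/K$. Evidence can be aggregated per condition stream or summed
per subject (`compare_models(condition=)`), since either convention is
defensible for multi-condition designs.

# Behavioral statistics

`summarize_conditions()` computes per subject and condition: accuracy
(choices of the high-probability reward / low-probability punishment
option), stay-after-positive and switch-after-negative proportions over
consecutive presentations of the same pair (positive feedback = win or
avoided loss), their mean as a single stay/switch index (the raw
proportions are also kept because a "ratio" of the two is ambiguous when
the denominator is 0), mean response time, and a per-subject learning
slope (linear regression of correct on trial-in-pair by default; logistic
on request -- the linear form is the default because the 20-point curves
are far from the saturation regime where the two diverge).

`rm_anova_2x2()` implements the within-subject 2x2 ANOVA (context x
valence) from the classical sum-of-squares decomposition with
subject-by-effect error strata (df 1, n-1). Effect sizes are classical
$\eta^2 = SS_\mathrm{effect}/SS_\mathrm{total}$, with partial $\eta^2$
reported alongside: at n = 102 an F of 22.75 alongside $\eta^2 = 0.049$ is
only consistent with the classical definition, so that is the default.
Zero-variance error strata yield F = 0/p = 1 (no effect) or F = Inf/p = 0
(constant nonzero effect), flagged. Paired contrasts use
`paired_contrast()` with caller-supplied Bonferroni family size and
Cohen's $d = \bar{d}/s_d$; one-tailed contrasts (for directional
replication tests) are an argument, two-tailed the default.

The prespecified poor-learner screen (`filter_poor_learners()`) excludes
subjects below chance in every block or below 40% in the first 10 trials
of every block. Trial-level mixed-effects modelling of choice is exported
(`export_glme_table()`) rather than estimated -- the estimator belongs to
dedicated mixed-model software.

# Validation

`recovery_study()` repeats simulate-cohort / refit / correlate. Generating
parameters default to draws from the MAP priors because no participant
estimates ship with the package; a fixed table can be supplied.
`simulation_check()` re-simulates each subject from fitted parameters and
correlates the cohort-mean 20-point learning curves per condition.

`simulate_context_effect_cohort()` plants the pipeline's target effect: a
+0.15 increment on the reward-mixed learning rate with a shared $\beta$.
Its base learning rates are drawn from Beta(1.5, 8.5) (mean 0.15) rather
than the near-uniform fitting prior, for a substantive reason: accuracy
is non-monotone in the learning rate at task-typical inverse temperatures
(it peaks near $\alpha \approx 0.35$ and declines beyond), so an
increment planted on a near-uniform base straddles the peak and has no
net behavioral signature. The default base distribution is calibrated so
the planted increment reproduces the reported mixed-vs-only reward
accuracy effect size (Cohen's d about 0.4 at n = 102), placing the
cohorts in the regime the effect was observed in.

A caution on recovery of $\beta$: with 40 trials (mixed conditions) or 80
(single conditions) per stream and truths drawn from Gamma(15, 0.75)
(coefficient of variation 0.26), the inverse temperature is weakly
identified -- near-deterministic subjects are consistent with any large
$\beta$, so MLE estimates pile up at the upper bound and the Pearson
correlation against a narrow true spread is substantially lower than the
learning-rate correlations. This is a property of the stationary design,
not of the optimizer, which is verified consistent (long-stream fits
recover $\alpha$ within 0.01 and $\beta$ within 0.6) and never worse than
the grid oracle. Learning-rate recovery at cohort scale reaches r about
0.5-0.9; recovery against *empirically estimated* truths, whose spread
covers the whole admissible range, is the regime in which all-parameter
correlations clear 0.48.

A related caution applies to `compare_mle_map_pes()`: replayed prediction
errors depend on the learning-rate estimates but not on $\beta$ (which
cancels out of the PE given the observed choices), so MLE–MAP PE
agreement is driven entirely by how far the two estimators' learning
rates diverge. Prior-drawn cohorts include agents behaving near chance,
for whom the likelihood is flat in $\alpha$ and the two estimators
legitimately disagree; pooled correlations on unscreened synthetic
cohorts therefore sit slightly below the near-perfect agreement expected
for well-identified, pre-screened participants.

# BOLD time-series analyses

Epochs run from 2 volumes before to 8 after outcome onset at TR 2 s,
normalized to the pre-onset baseline (the two volumes in [-4, 0) s) and
expressed as percent signal change; the baseline mean of every normalized
epoch is exactly zero, a tested invariant. "6 s post-reward" is read as
the sample 3 TRs after onset and "0 s" as the onset volume -- exact grid
points at TR 2.

Punishment-history labels apply to valid reward trials in mixed blocks:
the count of punishment deliveries since the previous reward trial
(counter starting at 0 at block start and resetting after every reward
trial), binned 0 / 1 / 2+; and the recency of the most recent punishment,
measured in trials (the available proxy for time in simulated data),
reset after each reward and split into per-subject tertiles pooled across
a subject's mixed blocks (sizes within one trial, ties broken by trial
order). `bin_pe_tertiles()` applies the same deterministic tertile rule to
signed PEs. `history_slope_test()` fits a per-subject OLS slope of the
bin-mean measure (6 s peak, or the 0-to-6 s ramp) over occupied levels
1-3, excludes subjects with fewer than two occupied levels, and tests
slopes against zero with a one-tailed one-sample t test.

The synthetic generator (`simulate_bold()`) injects a double-gamma
hemodynamic response, rescaled so its 6 s sample is 1 and windowed to
(0, 32) s, at widely spaced onsets (40 s apart) on a flat baseline of 100,
with amplitude `amp_baseline + history_gain * (count level - 1)` percent
plus white Gaussian noise. It emulates amplitude modulation by punishment
history with exact, recoverable ground truth; it does not emulate
autocorrelated physiological noise, overlapping responses, drifts, or
motion, so passing tests certify the analysis code, not robustness to
real-scanner artifacts.

# MKDA meta-analysis

Studies are single units: each contributes a binary indicator map, 1
within 10 mm (the field's convention; the grid is 2 mm isotropic) of any
reported focus, clipped to a mask. The weighted density map averages
indicators with weights proportional to the square root of study sample
size (uniform weights available -- the original weighting is unstated).
Family-wise error control uses the max-statistic Monte-Carlo permutation
test: each permutation relocates every study's foci uniformly within the
mask, preserving per-study focus counts, and the critical density is the
(1 - alpha) quantile of the permuted maxima.

The category imbalance (16 reward-mixed vs 9 reward-only studies) is
addressed by bootstrap balancing: each of 500 iterations subsamples the
mixed category to 9, thresholds both categories' density maps separately
at FWE 0.05 (1,000 permutations), and marks voxels significant for mixed
but not only; the final map keeps voxels crossing a 5% consistency
frequency across iterations. Thresholding each map separately and
differencing was chosen because the per-iteration contrast statistic is
not further specified in the procedure being reproduced; a direct
density-difference permutation is a natural alternative and the building
blocks (`density_map()`, `permutation_threshold()`) expose it.
`overlap_fraction()` quantifies agreement with an empirical binary map as
the percentage of meta-analytic voxels inside a region mask that are also
empirically active. The packaged mask is a synthetic ellipsoid "brain"
(`ellipsoid_mask()`); any binary volume on the grid can be supplied, and
maps can be exported to NIfTI via `write_map_nifti()`.

`simulate_foci()` provides ground truth: uniform background foci within
the mask plus an optional planted convergence cluster (Gaussian jitter
around a center, exact at zero spread) carried by chosen categories.

# Problem sizes and reproducibility

All stochastic steps take explicit seeds and reproduce bitwise. The
package's own validation runs at desk scale, chosen to keep a full check
of the pipeline in the tens of minutes on one core while leaving the
statistics stable: 50 recovery simulations of 102-subject cohorts
(the original design used 500 simulations; the correlations stabilize well
before 50), 100 synthetic cohorts for the planted context-effect power
check with 20 cohorts for the BIC model-preference check, 100 null corpora
at 199 permutations on a 20-cubed grid for FWE calibration, and 100 null
generator runs for the slope-test size check. Each number is stated where
it is used in the test suite and can be scaled up by argument.

# Known limitations

* The pipeline fits subjects independently; hierarchical shrinkage and
  MCMC posteriors are out of scope.
* The two-option softmax does not extend to more than two options, and no
  choice-kernel/perseveration terms are modelled.
* The recency proxy is trial count; wall-clock recency requires onset
  times, which the simulator does not model.
* MKDA cluster-level (mass) inference is not implemented; thresholding is
  voxel-level max-statistic FWE.
* Synthetic BOLD and foci generators are deliberately simple ground-truth
  machines, not forward models of scanner physics or publication bias.
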