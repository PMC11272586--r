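---
title: "Modelling prosocial effort: discounting models, hierarchical fitting and lesion-symptom mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prosocial effort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`effortmap` implements the computational machinery for studying how people
decide whether physical effort is worth expending for a reward — for
themselves or for another person — and for relating individual differences
in those decisions to the location of focal brain damage. Everything runs
end to end on synthetic data: the package ships generators for choice
cohorts, grip-force traces and lesion-mask cohorts with planted structure.

## The task and its payoff rules

The modelled experiment is a grip-force decision task. On every trial the
participant chooses between resting, which always pays 1 credit, and a work
offer that pays `R` credits (2–10, in 2-credit steps) if a grip-force
criterion is met. The required force is one of five levels, 30–70% of the
participant's maximum voluntary contraction (MVC) in 10% steps; internally
effort is coded as the integer level `E` in 2–6, whose mapping to %MVC is
`10·E + 10`. A work trial succeeds when the force trace accumulates at least
one cumulative second at or above the required level within the 3 s response
window; failed work and missed trials pay nothing. Half of the trials pay
the participant (self), half an anonymous other person (prosocial
condition). `build_schedule()` constructs the balanced factorial schedule —
each (recipient, effort, reward) cell three times, 75 trials per recipient
in three blocks. The interleaving algorithm is a within-block uniform
shuffle with per-block recipient counts balanced; only the overall cell
balance is treated as a structural invariant.

## The discounting model space

Twelve models describe how effort devalues reward. Three cost families give
the subjective value of a work offer:

* linear: `V = R − K·E`
* hyperbolic: `V = R / (1 + K·E)`
* parabolic: `V = R − K·E²`

crossed with whether the discount weight `K` and the inverse stochasticity
`β` are shared across recipients or recipient-specific (`1K/2K × 1β/2β`).
Rest is worth its 1 credit undiscounted for either recipient. Choices follow
a two-option softmax on the value difference,

`P(work) = logistic(β · (V_work − V_rest))`,

the canonical rule for this family of tasks; β scales choice consistency
(per credit), with larger β giving more deterministic choices. Parameters
are bounded: `0 < K < 1.5` and `0 < β < 4`. Boundary values are rejected by
the validators; fitting works strictly inside the bounds through scaled
logistic transforms (`K = 1.5·logistic(x)`, `β = 4·logistic(y)`), so the
unconstrained space seen by the optimizer is unbounded.

## Hierarchical MAP fitting

`fit_map_em()` fits one model to a multi-subject dataset with an iterative
maximum a posteriori scheme, the standard empirical-Bayes
expectation-maximization used for behavioural models:

* **E-step.** Each subject's posterior mode is found by BFGS with analytic
  gradients under an independent Gaussian prior in the transformed space.
  The first E-step uses 5 starting points (prior mean plus seeded random
  prior draws); later E-steps warm-start from the subject's previous
  optimum, plus the prior mean and one fresh draw. Warm restarts track the
  optimum as the prior moves while keeping iterations cheap; the full
  multistart matters only before the prior has adapted.
* **M-step.** The prior mean is the average of the posterior modes; the
  prior variance averages the squared modes plus each subject's
  inverse-curvature (Laplace) correction, with a floor of `1e-4` against
  degenerate collapse. If a subject's Hessian is not positive-definite its
  correction is dropped, and the sample variance of the modes is used as a
  fallback.
* **Convergence.** Iterations stop when the summed per-subject log model
  evidence (Laplace approximation) improves by less than `1e-3`, with a cap
  of 100 iterations. If the objective ever dips, the previous (better)
  state is kept, so the reported evidence trace is monotone.

Per-subject evidence uses the Laplace approximation; when the curvature is
unusable the subject falls back to `−BIC/2` and is flagged. Missed trials
(NA choices) are dropped from all likelihoods.

Two fit-quality summaries accompany each fit. The integrated BIC,
`iBIC = −2 Σ_s log p̂(D_s | prior) + P·log N`, integrates each subject's
likelihood over the fitted group prior by Monte Carlo (2000 seeded draws
per subject by default; the draw count is configurable since published
analyses rarely state it) and penalizes the `P = 2 × (model parameters)`
prior hyperparameters. The pseudo-R² is the log-loss reduction against a
coin-flip baseline, `1 − Σ LL / (N·log 0.5)`; definitions of choice R² vary
across papers, and this package uses the chance-baseline form throughout
and labels it as such.

## Random-effects model selection

`bms_random_effects()` treats the model identity as a random effect across
subjects: a Dirichlet prior (uniform, `α₀ = 1`) over population model
frequencies is updated by the variational scheme, alternating subject-wise
model responsibilities with the Dirichlet concentration update until the
change in α is below `1e-6`. Estimated model frequencies (EF) are the
normalized concentrations; exceedance probabilities (XP) — the posterior
probability that each model is the most frequent — are estimated from 10⁶
seeded Dirichlet draws (exact Beta tails are used as a cross-check in the
tests, not as the estimator). `between_group_bms()` compares pooled versus
group-specific frequency vectors by their variational free energies with
equal prior odds, giving a posterior probability that groups share one
frequency vector.

## Validation by simulation

Two simulation studies validate the pipeline, mirroring standard practice:

* **Identifiability** (`run_identifiability()`): simulate cohorts from each
  candidate model with parameters drawn flat within the bounds, refit all
  candidates, and average XP into a generator-by-fitted confusion matrix.
  The full configuration (all 12 models, 10 datasets × 100 agents)
  sits behind `scale = "full"`; the default desk scale uses 4 well-spread
  models (linear/parabolic × fully-shared/fully-specific), 3 datasets × 30
  agents, chosen to exercise the same machinery at a few CPU-minutes.
* **Parameter recovery** (`run_parameter_recovery()`): simulate agents at
  the full crossing of `K ∈ {0, 0.3, 0.6, 0.9, 1.2, 1.5}` (self and other)
  and `β ∈ {0, 1, 2, 3, 4}` (self and other) — 900 agents — with additive
  `N(0,1)·0.05` jitter, refit the recipient-specific parabolic model, and
  correlate simulated with recovered values. Jittered values are clamped
  strictly inside the bounds; β is floored at 0.02 because a hard zero
  makes choices pure noise and the likelihood uninformative — recovery at
  the β floor necessarily degrades and is reported, not asserted. The test
  suite runs a 180-agent subsample; the acceptance script runs the full
  grid. Correlations are computed on the natural parameter scale, as
  recovery plots are conventionally drawn.

## What the synthetic cohorts emulate — and what they do not

`sample_agents()`, `simulate_choices()` and `simulate_force()` reproduce
the study conditions: the factorial schedule, Bernoulli choices from
softmax agents, and force traces modelled as `gain × required level` plus
Gaussian noise (fraction-of-MVC units), sampled at 50 Hz — the rate is a
package choice, configurable, since acquisition rates vary. Force gains
below 1 emulate under-exertion (for example, reduced force when another
person benefits). The traces have no rise time, fatigue, or serial
dependence, so passing tests say nothing about physiological grip
dynamics — only about the payoff and success logic downstream.

`simulate_lesion_cohort()` produces binary ellipsoidal masks on a common
40 × 48 × 40 grid at 4 mm spacing (desk-fast for permutation testing;
geometry configurable) with a planted spherical region and behaviour
`N(0,1) + d·overlap`. Lesion centres are drawn as a bimodal mixture: a
`target_fraction` (default 0.4) cluster tightly around the planted region
and the rest scatter widely. This mirrors how lesion cohorts are actually
composed — a target-territory group plus lesions elsewhere — and it is
what makes the planted association geometrically coherent: with a single
diffuse centre distribution, patients graze the planted region without
covering any voxel in common, and no voxelwise method can see the effect.
The masks are not meant to resemble vascular territories or real lesion
morphology.

## Behavioural metrics and the VLSM regressors

`credits_earned()`, `evaluate_success()` and `force_auc()` implement the
payoff, success and normalized-force statistics. The force AUC is the
trapezoidal integral of force/MVC over the window divided by its duration,
a dimensionless index equal to 1 for a constant squeeze at MVC; the
normalization is a package convention chosen for interpretability.

`subject_regressors()` produces the four per-subject variables mapped
against lesion location: the recipient effect on discounting
(`K_other − K_self`), the recipient effect on choices
(`acceptance_self − acceptance_other`; both signed so that "less prosocial"
is positive), and effort and reward sensitivity as per-subject logistic
slopes of choice on squared effort and on reward. This deliberately
replaces mixed-model participant-level random effects with per-subject
fitted parameters and slopes: the regressors keep their meaning while the
package avoids depending on a particular GLMM implementation; the
difference is that no partial pooling shrinks the per-subject values.
Subjects with separated regressions (all-work or all-rest) fall back to a
ridge-penalized fit and are flagged. `rank_z()` applies the rank-then-z
transform (ties averaged) used to de-skew regressors before mapping.

## Lesion-symptom mapping

`vlsm_map()` compares, at every included voxel, patients with damage there
to all other patients on the behavioural regressor with a pooled-variance
two-sample t test — the binary-regressor special case of the usual
design-matrix formulation. Voxels require at least 5 damaged patients
(`voxel_inclusion()`); masks can be symmetrized with `mirror_masks()`
(union with the left-right flip; the affine must encode an unambiguous
left-right axis on a midline-centred grid, otherwise the function refuses).
Voxels damaged in every patient carry no contrast and are excluded with a
flag.

Inference uses threshold-free cluster enhancement with the conventional
defaults `H = 2`, `E = 0.5`, 100 integration steps (`dh = max/100`) and
26-connectivity, all exposed as arguments. Family-wise error is controlled
by the permutation distribution of the map-wide maximum TFCE score under
unrestricted shuffling of the behaviour vector (5000 permutations by
default), with the add-one-corrected `p = (b + 1)/(m + 1)`; an
`exhaustive = TRUE` mode enumerates all `n!` relabelings for small cohorts,
making p values exact. Both one-sided maps (damage-higher and damage-lower
behaviour) are computed, since effects of either sign are of interest; the
default `alpha = 0.0125` is the Bonferroni level for four behavioural
regressors, applied by the caller's choice of `alpha`. Peaks are reported
in world coordinates through the affine.

One discretization caveat: because the TFCE step size is tied to the map
maximum, raising the global peak reshuffles the integration grid and can
perturb other voxels' scores by a fraction of one step; monotonicity holds
exactly for changes that leave the maximum in place.

## Numerical choices and degenerate inputs

* Optimizer: BFGS with analytic gradients; 300 iteration cap per subject.
* Hessians by finite differences of the analytic gradient; positive
  definiteness checked by Cholesky.
* Prior initialization mean 0, variance 4 (transformed space); variance
  floor `1e-4`.
* EM tolerance `1e-3` on summed evidence, 100 iteration cap,
  stop-and-revert on objective decrease.
* All-identical choice data drive estimates toward a transform extreme;
  the prior keeps them finite and the Laplace fallback flags the subject.
* Constant behaviour vectors, empty inclusion masks, mismatched grids,
  out-of-bounds parameters and empty trial sets all raise immediate errors
  rather than propagating NaNs.
* Every stochastic routine takes a seed and restores the caller's RNG
  state; outputs are pure functions of (inputs, seed).

## Problem sizes

The shipped test suite runs everything at reduced scale on one CPU: the
180-agent recovery subsample, the 4-model desk confusion matrix, five
100-agent cohorts for the 12-model iBIC comparison, 200 null lesion
cohorts at 500 permutations for the family-wise-error calibration, and 10
planted-effect cohorts. The acceptance script runs the full 900-agent
recovery grid. Full-scale identifiability (12 models × 10 datasets × 100
agents) is available via `scale = "full"` but takes hours rather than
minutes.

## Known limitations

* Only the three stated cost families are implemented — no exponential or
  sigmoidal discounting, loss aversion, or fatigue carry-over.
* Per-subject evidence is approximate (Laplace or −BIC/2); no MCMC.
* The between-group frequency comparison relies on variational free
  energies, which are lower bounds, not exact evidences.
* Protected exceedance probabilities and family-level model selection are
  out of scope.
* The lesion generator plants a single spherical region; multifocal or
  graded (lesion-load) ground truths are not modelled, and the VLSM
  statistic treats damage as binary "to any extent".
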