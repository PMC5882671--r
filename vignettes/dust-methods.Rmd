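---
title: "Methods: diffusion modelling of perceptual decisions under social norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion modelling of perceptual decisions under social norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the scientific question

`dustddm` analyses a two-alternative motion-discrimination task in which an
observer judges the direction of a random-dot stimulus while seeing the
choices of two other players (two arrows: *social information*) and, on
two-thirds of trials, a norm prompt that asks them to decide **with** the
other players (`same`) or **against** them (`only`); the remaining trials
carry no prompt (`none`). Congruent arrows are *valid* when they point in
the true motion direction and *invalid* otherwise; incongruent arrows carry
no directional information (the dots-only condition). Norm compliance has
monetary consequences for the *other* players only, in two variants:
compliance earns them a bonus (benefit-others, `bo`) or non-compliance
costs them money (harm-others, `ho`).

The modelling question is *where* in the decision process social
information and norms act: do they shift the **starting point** of evidence
accumulation (a prior bias needing less evidence for the cued response), or
do they change the **drift rate** (the quality of evidence accumulation
itself)?

## The diffusion model

Each trial is modelled as a Wiener diffusion with drift between two
absorbing boundaries: evidence accumulates from a relative starting point
`w` (fraction of the boundary separation `a`, measured from the lower/left
boundary) with drift `v` (positive toward the upper/right boundary) and
diffusion coefficient fixed at `s = 1` — all reported parameters are on
that scale. Observed RT is decision time plus a non-decision time `t0`;
across-trial drift variability is Normal with SD `sv`. The defective
first-passage density at the lower boundary is

```
f_lower(t) = (1 / a^2) * exp(-v a w - v^2 t / 2) * f1(t / a^2; w)
```

where `f1` is the zero-drift unit-scale density, computed by the small-time
or large-time series expansion — the term-count rules target an absolute
truncation error of `1e-7` and the cheaper expansion is selected
automatically (both expansions agree to better than `1e-6` around the
crossover; see `test-wiener.R`). With `sv > 0` the drift-dependent factor
is integrated in closed form, so no numerical quadrature enters the
likelihood. The upper-boundary density follows from the mirror identity
`upper(a, w, v) = lower(a, 1 - w, -v)`.

Starting points are parametrized as relative `w` rather than absolute `z`
so that `0 < z < a` holds automatically for any sampled `a`.

## The six model parametrizations

All models share `a`, `t0`, `sv` across trial contexts and differ in their
starting-point and drift maps (parameter counts in brackets):

| model | starting points | drifts |
|---|---|---|
| `reduced` (5) | one `w_base` | one magnitude `v_mag` |
| `sp_reduced` (7) | + `w_cong_left`, `w_cong_right`, shared across norms | `v_mag` |
| `sp` (11) | congruent pair per norm condition | `v_mag` |
| `drift_reduced` (6) | `w_base` | `v_incong`, `v_cong` |
| `drift` (8) | `w_base` | `v_incong` + `v_cong` per norm condition |
| `spdr` (14) | as `sp` | as `drift` |

Drift parameters are magnitudes, signed at resolution time by the true
stimulus direction (responses are coded left/right, not correct/error).
In starting-point models congruent cues act only on `w`; incongruent trials
always use `w_base`. Two genuinely open choices were resolved as the
simplest readings: `sp` carries a single incongruent baseline `w` (not one
per norm), and the incongruent drift in `drift`/`spdr` does not vary by
norm. The nesting structure is exact and is tested by equating the extra
parameters and comparing likelihoods.

## Priors and sampling

Priors are weakly informative truncated Normals spanning typical 2AFC
fits: `a ~ N(1.5, 1)` on (0.1, 5); starting points `~ N(0.5, 0.25)` on
(0.02, 0.98); drift magnitudes `~ N(1, 2)` on (0, 7); `t0 ~ N(0.3, 0.2)` s
on (0.05, 1); `sv ~ N(0.5, 0.5)` on (0, 3). All are overridable per fit.

Posteriors are sampled by differential-evolution MCMC: `3 p` chains
(`p` = parameter count), proposals `gamma (x_r1 - x_r2) + U(-0.001, 0.001)`
with `gamma = 2.38 / sqrt(2 p)` and a 5% chance of `gamma = 1` for mode
jumping. Chains are split into two fixed halves updated alternately, each
half drawing its difference vectors from the other half; this is a valid
composition of two conditional Metropolis sweeps and lets each sweep be a
single vectorised likelihood evaluation, which is what makes per-subject
fits take seconds rather than minutes on one CPU. During burn-in, every
20th iteration a random subset of chains proposes adopting a neighbour's
state in a ring (Metropolis-accepted), so stuck outlier chains are absorbed
early; migration is disabled after burn-in. Defaults are 500 burn-in and
1000 retained iterations per chain.

Convergence is monitored by split-chain R-hat; a fit with any R-hat above
1.1 is rerun once with doubled iterations and otherwise reported loudly
(error by default, a warning inside the batch pipeline). Trials whose RT is
at or below `t0`, or whose density underflows, contribute `-Inf` so the
sampler simply rejects — degenerate parameter regions are not exceptions.
No-response trials (deadline reached) are dropped before fitting: they are
rare by design (< 2% under default settings) and the model does not
describe them.

## Model comparison and averaging

Per subject and model, WAIC is computed from the pointwise posterior
log-likelihood matrix: `lppd` with log-sum-exp stabilisation, `p_waic` as
the summed per-trial variance over draws using the denominator-`n`
convention (duplicating draws must not change the estimate), and
`waic = -2 (lppd - p_waic)`. Akaike-style weights
`exp(-Δ/2) / Σ exp(-Δ/2)` are renormalized per subject over the six
models.

Condition-level summaries follow the reporting convention of averaging the
two cue sides into one "toward-the-cue" magnitude, corrected for any
incongruent-trial bias:

```
sp_bias  = mean(w_cong_right - w_base, w_base - w_cong_left)
drift_delta = v_cong(condition) - v_incong
```

computed from posterior means (means are linear, so they commute with the
weighting), with models lacking a parameter contributing their nested
value (0 bias / 0 delta). Final estimates are WAIC-weight averages over
all six models.

## The synthetic-data generator

No human data ship with the package; the generator emulates the task
design so every analysis can be exercised end to end:

* phase-two schedules of 360 trials, exactly 120 per norm condition, with
  at most 3 consecutive same-norm trials (constrained sequential sampling
  with bounded restarts);
* social cues stratified *within* each norm condition — 48 valid /
  36 invalid / 36 incongruent, i.e. 40/30/30% — with stimulus direction
  balanced left/right in every cell, so condition contrasts are balanced
  by construction (the stratification within norms is a design choice; only
  the overall proportions are fixed by the task description);
* a 2.5 s response deadline, 3 s inter-trial interval, and a norm prompt
  drawn uniformly from 0.5–1 s;
* base parameters `a = 1.2`, `v = 0.706`, `t0 = 0.3 s`, `sv = 0`,
  calibrated so dots-only accuracy is `1 / (1 + exp(-v a)) = 0.69998` —
  the task's 70% staircase target. Stimulus coherence is not modelled as a
  separate channel; difficulty is absorbed into the drift magnitude, and a
  phase-one familiarisation block is available as an option.

Condition effects are starting-point shifts toward the cued side
(`dw_none = +0.06`, `dw_same = +0.12`, `dw_only = +0.02` for `bo` /
`-0.04` for `ho`) and a congruent-drift change in the `only` condition
(`dv_only = -0.15` for `bo` / `-0.35` for `ho`). These encode the
qualitative pattern the two experiments are designed around — biases
ordered `same > none > only`, with the `only` effects more negative under
harm-others — at magnitudes typical of 2AFC starting-point effects; they
are the package's own design values, not estimates from any data set.
Subjects jitter around the presets with truncated-Normal noise at 25% of
each preset magnitude (zero-valued presets stay exact).

The trial simulator uses exact Gaussian increments on a 1 ms grid with
Brownian-bridge crossing probabilities between grid points, so absorption
probabilities are exact in law and only the RT is discretised (at 1 ms,
below any RT resolution of interest). Because the simulator shares no code
with the series density, simulator-vs-density agreement is a genuine
dual-route test, with the closed-form absorption probability as a third
route.

What the generator does **not** emulate: fast guesses and attention
lapses (no contaminant mixture), post-error slowing or other sequential
dependencies, stimulus-coherence psychophysics, and any group-level
(hierarchical) parameter structure. Tests passing on synthetic cohorts
therefore validate the machinery — schedule constraints, likelihood,
sampler, WAIC averaging, recovery — not the empirical adequacy of the
model family for any particular human data set.

## Validation studies

`run_recovery()` simulates subjects from known truths, refits, and scores
per-parameter coverage and cross-subject correlation. Truths default to
the generator presets (with the 25% jitter); a `"prior"` option draws
truths from the fitting priors instead, because the nominal-95%-coverage
property of central credible intervals holds exactly only under
prior-drawn truths. The preset `sv = 0` lies on the prior boundary, so
`sv` coverage is not meaningful under preset truths and the recovery gates
are placed on `a` and the drift magnitude.

`run_ppc()` draws parameter vectors from a fitted posterior, simulates the
subject's schedule under each, and compares observed accuracy and RT
quantiles (0.1/0.5/0.9) per norm-by-validity cell with central 95%
predictive intervals. A well-specified fit should cover the observed
statistics; a `reduced` fit to strongly biased starting-point data should
not — both directions are tested.

## Problem sizes and numerical choices

The shipped test suite exercises, among others: density normalization to
`1e-4` over both boundaries with and without `sv`; simulator agreement at
2-10 x 10^4 trials; a recovery study of the `reduced` model with 10
subjects x 360 trials on short chains (400 retained / 300 burn-in), gated
at correlation > 0.8 for `a` and `v`; and an end-to-end
simulate-fit-compare run of a 4-subject harm-others cohort across all six
models checking that the planted ordering
`sp_bias(same) > sp_bias(none) > sp_bias(only)` survives to the
cohort-mean, model-averaged estimates. These sizes keep the full suite
around six minutes on a single CPU while leaving every gate statistically
comfortable; larger runs (more subjects, default-length chains) use the
same code paths via `dust_config()`.

Other numerical conventions: series truncation error `1e-7`; simulator
step 1 ms; WAIC variance denominator `n`; R-hat split-chain with `Inf`
(plus a warning) for zero within-chain variance; ties in the norm-sequence
sampler broken by remaining-count-proportional sampling; the power
calculation defaults to one-tailed, which reproduces the design value of
27 participants (`d = 0.5`, `alpha = 0.05`, power 0.8) — the two-tailed
variant (n = 34) is available via `tails = 2`.

## Known limitations

* Fits are per-subject; there is no hierarchical shrinkage, so subjects
  with few usable trials get wide posteriors rather than partial pooling.
* The model family excludes starting-point and non-decision-time
  variability, collapsing bounds, and urgency; `sv` is the only
  across-trial variability.
* WAIC weights are Akaike-style normalized evidence, not stacking or
  LOO-CV weights; with highly correlated model predictions they can split
  weight across near-equivalent models.
* The DE-MCMC sampler is tuned for the 5-14 parameter models it ships
  with; much larger parameter spaces would need retuned population sizes.
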