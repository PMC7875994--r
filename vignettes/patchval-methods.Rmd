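---
title: "Methods: task simulation, value modelling and the E/I link analysis"
author: "patchval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task simulation, value modelling and the E/I link analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchval)
```

## Overview

`patchval` re-implements, as a tested pipeline, the computational core of a
study design that links cortical excitation/inhibition (E/I) balance —
glutamate-to-GABA concentration ratios measured by magnetic resonance
spectroscopy in five cortical voxels (dACC, vmPFC, dlPFC and bilateral
M1) — to two kinds of decisions made in a single two-stage task:
patch-leaving decisions (abandon a depleting resource at a travel cost) and
value-guided choices (pick the better of two risky options). Because the
human data are not bundled with the package, a synthetic-cohort generator
with planted individual-difference effects stands in for participants;
everything downstream of it — the model fits, the behavioural statistics
and the gated inference layer — is the analysis machinery itself.

## The task environment

Each of the 320 trials has two stages. At the patch stage, the agent sees a
travel cost and decides to stay or leave. The two patches carry latent
means that diffuse as a decaying Gaussian random walk,

$$\mu_{t+1} = \lambda \mu_t + (1-\lambda)\kappa + \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, 1.2^2),$$

with decay rate $\lambda = 0.96$ and decay centre $\kappa = 1$ for the
occupied patch (it depletes) and $\kappa = 100$ for the alternative (it
replenishes). Displayed patch values are Gaussian draws around these means
(variance 3.5), clamped into 10–90 points and rounded to integers. Travel
costs come from $\{5, 10, 15, 20\}$ and persist until the next leave. At
the value stage, the chosen patch's value is split between two options at a
random ratio (each option at least 10% of the total, never an exact 50/50
split) and each option independently receives a reward probability from
$\{0.1, \dots, 0.9\}$; outcomes are independent Bernoulli draws.

Two details deserve emphasis:

* **Clamping site.** The source design states only that values were
  controlled to fall in 10–90 points. We clamp the *sampled values*, never
  the latent mean recursion. This keeps the recursion an exact AR(1)
  process, so its fixed point ($\mu \to \kappa$ without noise) and its
  stationary spread ($\mathrm{SD} = 1.2/\sqrt{1-0.96^2} \approx 4.29$) are
  analytic properties the test suite verifies against simulation.
* **The flip-rule asymmetry.** When one option dominates on both magnitude
  and probability (a "no-brainer"), the original experiment intended to
  swap the two magnitudes in half of such trials, but a coding error
  applied the swap only to left-favouring no-brainers. `apply_flip_rule()`
  reproduces this by default (`replicate_side_bias_bug = TRUE`), which
  makes right-favouring no-brainers systematically more frequent — the
  asymmetry that motivates the no-brainer covariate in the analysis stage.
  Setting the flag to `FALSE` restores symmetric flipping.

No-brainer detection requires *strict* dominance on both attributes; ties
on probability do not count. Under this rule and the default generator the
empirical no-brainer share comes out near one third (a back-of-envelope
derivation gives 8/9 odds of unequal probabilities, half of those
congruent with the magnitudes, minus the half of left-favouring cases the
flip removes: 4/9 − 1/9 = 1/3); human cohorts on this task show a share a
few points higher, plausibly reflecting unrecorded details of the split
rule, so the simulator always reports its empirical fraction rather than
asserting a target.

## Synthetic agents and cohorts

The source study fits no generative model of patch choices or response
times, so the generator's behavioural policies are this package's own
design, built to be the *minimal* structure under which the analysis
stage's quantities are meaningful:

* **Leave policy.** $P(\text{leave}) = \text{logistic}\big((\mathrm{PLA} -
  \theta)/\sigma\big)$, where the patch-leaving advantage (PLA) is the
  previous trial's value difference (alternative − current) minus the
  displayed cost. A monotone stochastic threshold makes the mean PLA at
  leave trials an interpretable, recoverable per-agent quantity (it rises
  monotonically with $\theta$). Defaults $\theta = 30$, $\sigma = 8$ were
  chosen once so that a default cohort reproduces the observed behavioural
  regime (about 20 leaves per session at a mean PLA near 19 points).
* **Value policy.** Softmax over subjective values from the headline value
  model (below) with per-agent curvatures; magnitudes are mapped onto the
  `[1, 10]` fitting range using the fixed task-wide magnitude band so that
  generation and fitting share a scale.
* **Response times.** Log RT is linear in the same z-scored design
  variables the analysis stage uses, plus Gaussian noise (SD 0.3
  log-seconds). Default coefficients mirror the direction and order of
  magnitude of the group effects reported for this task (slower on leave
  trials, faster with practice and with larger value differences, etc.).
  This is a statistical emulation, not a process model — no
  drift-diffusion dynamics are implied, and recovery tests on real data
  would not inherit the log-linear form assumed here.

`generate_cohort()` draws a multivariate-normal latent vector per
participant over the five regional E/I values and any *planted targets*,
with a user-specified correlation structure (checked for positive
semi-definiteness). Planted targets may be agent parameters — then the
agents themselves carry the effect through the full pipeline — or bare
labels, in which case the latent variable is returned directly; the latter
is what the power and type-I calibration checks use, because it isolates
the inference layer from the (attenuating, and much slower) behavioural
simulation. Default planted effects mirror the magnitude of the reported
correlations: dACC↔`theta_leave` at $r = 0.5$ and vmPFC↔`alpha` at
$r = -0.46$.

Regional E/I means (4.5 in dACC down to 3.8 in M1, SDs ≈ 0.5) and the
metabolite constants (creatine ≈ 8 institutional units, grey-matter
fractions 0.55–0.70, creatine-normalized GABA ≈ 0.28) are fixed at values
a spectroscopist would call plausible for 7 T voxels; the generator
*solves* the absolute GABA and glutamate concentrations so that the latent
E/I re-emerges only after the full normalization chain, guaranteeing that
the arithmetic in `normalize_metabolites()` is exercised rather than
bypassed. Quality metrics are drawn inside the acceptance window, so
synthetic cohorts pass QC by construction; the QC gate itself is tested
with hand-corrupted measurements.

## The value-model family

Choices at the value stage are modelled with subjective option values
combining a power-law utility $u(m) = m^\alpha$ over magnitudes rescaled
to $[1, 10]$ and a probability weighting

$$w(p) = \frac{p^\gamma}{\big(p^\gamma + (1-p)^\gamma\big)^{1/\gamma}},$$

the classic inverse-S distortion for $\gamma < 1$. Three families combine
them: multiplicative ($V = \omega_{\text{mult}}\, u \cdot w$), additive
($V = \omega_m u + \omega_p w$), and a hybrid that mixes the normalized
additive and multiplicative values with weight
$\omega_{\text{mult}}/(\omega_m+\omega_p+\omega_{\text{mult}})$ and scales
by $\omega_m+\omega_p+\omega_{\text{mult}}$. Each family comes in four
distortion variants (EV, EU, EVPW, SU) fixing $\alpha$ and/or $\gamma$ at
1. The headline model is the SU-multiplicative family with
$\omega_{\text{mult}}$ fixed at 6.62 — the value used in the original
fits, where the scale parameter recovered poorly and was pinned at the
median of previously recovered parameters — leaving exactly two free
parameters, $\alpha$ and $\gamma$.

Choice probabilities are a unit-temperature logistic in the value
difference; the $\omega$ scale *is* the inverse temperature, so no
separate temperature parameter exists. The likelihood floors per-trial
probabilities at $10^{-12}$ to stay finite at extreme curvatures.

**Fitting.** `fit_value_model()` draws starting points uniformly within
box bounds ($\alpha, \gamma \in [0.05, 5]$, weights in $[0, 50]$ — bounds
are unstated in the source and were chosen to cover published estimates
with a wide margin; they are configurable) and runs a constrained
quasi-Newton (`L-BFGS-B`) minimisation from each, reporting the lowest-NLL
solution with all-start diagnostics. The default is 1000 starts, matching
the original procedure; the test suite and examples use 10–50 starts,
which for the two-parameter headline model reach the same optimum (the
suite asserts bit-identical results under a fixed seed, and the
nested-model NLL orderings hold at 20 starts). Model comparison uses
$\mathrm{BIC} = k \ln n + 2\,\mathrm{NLL}$ with ties broken toward fewer
parameters. `recover_parameters()` reruns the original recovery design:
random true parameters, choices simulated on a real trial template,
refit, per-parameter true-vs-recovered correlations (with 100 sets × 320
trials × 50 starts, $r \ge 0.88$ for $\alpha$ and $\ge 0.93$ for
$\gamma$ under the fixed acceptance seed).

## Behavioural statistics

All per-participant regressions z-score every design variable and add a
constant. The patch-stage RT model has six predictors (previous-trial
value difference, leave flag, cost, trial number, side change, previous
reward); the value-stage choice and RT models have ten, the RT variant
replacing the signed expected-value difference with its absolute value.
Log RTs are z-scored *within participant* — the source is ambiguous
between within-participant and sample-wide normalization, and the
within-participant reading keeps each regression self-contained (the
across-participant scale re-enters through the mean log RT decision
variable, which is z-scored at GLM entry). First trials are dropped
because previous-trial regressors are undefined there. Logistic fits use
Newton iterations with a tiny ridge on the slopes (1e-6, escalating to
1e-2) so complete separation — likely in near-deterministic agents —
yields finite estimates.

Group-level inference is the two-stage summary-statistics approach:
per-participant coefficients tested against zero with a two-tailed
one-sample t-test, 95% CI of the mean, and Cohen's U3 for one sample
reported as the proportion of participants *below* zero (so strongly
positive group effects give U3 ≈ 0). The cost-level analysis takes, per
participant and cost level, the median previous-trial value difference at
leaving, then runs a one-way repeated-measures ANOVA across the four
levels with listwise deletion of participants missing a level (a
participant can simply never be offered the highest cost). The effect
size is $\eta^2 = SS_{\text{condition}}/SS_{\text{total}}$ with the total
*including* the between-subject sum of squares — the variant classic
within-subject effect-size toolboxes produce, and markedly smaller than
partial $\eta^2$ whenever participants differ in overall level. The
linear trend regresses each participant's four medians on the cost values
plus a constant and t-tests the slopes.

Robust confirmation fits use iteratively reweighted least squares with a
Tukey bisquare weight function, tuning constant 4.685 (95% Gaussian
efficiency), with slope inference from the robust standard error at
$n - 2$ degrees of freedom.

## Metabolite normalization and the gated hierarchy

Only measurements with CRLB < 20%, FWHM < 25 Hz and SNR > 8 for both GABA
and glutamate enter; a participant failing QC in any of the five regions
is dropped listwise. GABA and glutamate are divided by the voxel's
grey-matter fraction (they reside predominantly in grey matter), total
creatine by the combined grey-plus-white fraction, and the reported
concentrations are the ratios of the two corrected values. E/I balance is
normalized glutamate over normalized GABA — algebraically the creatine
and grey-matter corrections cancel in the ratio, and the test suite
asserts exactly that invariance.

The inference layer enforces the source's hierarchy literally:

1. Only decision variables of a priori interest — and, when behavioural
   p-values are supplied, only those with a significant behavioural
   effect — are tested at all.
2. Each is regressed on the z-scored E/I balances of *all five regions
   simultaneously* (plus a constant; plus the no-brainer share as a
   covariate of no interest for value-phase variables).
3. If, and only if, a region is significant there (two-tailed $p < 0.05$;
   no correction across regions, matching the source's a-priori-hypothesis
   rationale), follow-ups run for that region: a partial correlation
   residualizing both the decision variable and the target E/I on the
   other four regions (always with a constant in the residualizing model),
   a robust bisquare refit of the residual pairs, transmitter-level
   partial correlations (residualizing on the other transmitter in the
   target region and both transmitters elsewhere — nine nuisance columns),
   and coefficient contrasts against the other regions computed from the
   GLM's coefficient covariance.
4. Mediation-style re-entry: for accuracy, the fitted $\alpha$ and
   $\gamma$ can be added to the design, reproducing the original check
   that the curvature parameters absorb the accuracy effect.

Every non-test carries a machine-readable reason, so a report never
silently omits a branch.

## Calibration, problem sizes and numerical choices

The package's own acceptance checks (in `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) run at sizes chosen to make the Monte-Carlo
error bands tight while keeping a full run in minutes on one core: a
$10^6$-step chain for the AR(1) stationary SD (2% tolerance), a
$10^4$-trial session for the clamp bound, 1000 null cohorts of $N = 29$
for per-region type-I rates (binomial 95% band around 5%), 500 cohorts
with a planted dACC correlation of 0.5 for power (> 60% detection with
the other four regions at their null rate), 100 recovery sets at 50
starts, and 50 synthetic participants for BIC model recovery. Degenerate
inputs are handled explicitly: constant magnitude vectors, zero-variance
design columns and rank-deficient GLMs are errors naming the offending
column; sessions without leave trials yield `NA` decision variables with a
warning and propagate as untested branches of the hierarchy.

## What passing tests do and do not show

The synthetic cohort reproduces the *statistical structure* the analyses
assume — log-normal RTs linear in the design variables, logistic leave
decisions, softmax value choices, multivariate-normal individual
differences — and therefore demonstrates that the pipeline recovers
planted effects at realistic sizes and keeps its nominal error rates. It
does not reproduce sequential dependencies beyond the design variables,
non-stationarity in strategy, lapses, or any neurochemical detail beyond
the planted correlations, so green tests here certify the machinery, not
any claim about new empirical data. The deposited behavioural data of the
original study can be ingested through `read_trials()` with a sidecar
column mapping and summarized with `behavioural_summary()`, which computes
the cohort descriptives (leave counts, mean PLA, no-brainer share,
cost-level ANOVA) that the original report prints.

## A worked micro-example

```{r example}
session <- simulate_session(agent_params(), patch_dynamics_params(),
                            seed = 7)
sum(session$switch)
compute_patch_leaving_advantage(session)$mean_pla

spec <- value_model_spec("multiplicative", "SU",
                         fixed = list(omega_mult = 6.62), n_starts = 25)
fit <- fit_value_model(session, spec, seed = 1)
fit

compute_decision_variables(session, fit)
```
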