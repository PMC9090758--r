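---
title: "Modelling evidence accumulation and prefrontal-amygdala connectivity in a face-matching task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evidence accumulation and prefrontal-amygdala connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`accumdcm` implements a two-stage generative analysis of a dynamic face-
and shape-matching experiment in adolescent depression: a hierarchical
linear ballistic accumulator (LBA) model of the choice response-time data,
and a four-region dynamic causal model (DCM) of the
FFA–LPFC–sgACC–amygdala network measured with fMRI. A synthetic cohort
generator reproduces the study design (33 controls and 30 patients, 80
trials per subject, 335 volumes at TR 1.6 s) so that the whole pipeline
can be exercised without access to patient data. This vignette documents
the models, the estimation machinery, the design choices that were
genuinely open, and what the synthetic validation does and does not show.

## 1. The behavioral model

Each trial presents a dynamic target face (or shape) and two probes; the
participant presses left or right as soon as they identify the match. The
LBA describes this as a race between two ballistic accumulators, one for
the matching and one for the mismatching probe. On every trial an
accumulator starts at a point drawn uniformly from `[0, A]` and rises
linearly with a drift sampled from a normal distribution; the first to
exceed the threshold `b = A + B` triggers the response, at time
`rt = t0 + (b - start) / drift`.

Parameters per subject:

* `v_true[c]`, `v_false[c]` — mean drifts of the matching and mismatching
  accumulator in condition `c` (positive, negative, neutral faces,
  shapes). The matching drift is the model's index of processing
  efficiency.
* `sv_true` — trial-to-trial SD of the matching drift; the mismatching
  SD is fixed at 1 to set the scale of the model.
* `A`, `B` — start-point range and threshold excursion (response
  caution).
* `t0` — non-decision time (encoding and motor preparation).

Accumulators are accuracy coded (match/mismatch); left/right is assigned
at simulation time from the design's correct-side column. Drifts are
truncated to positive values and the densities renormalized, so the race
always terminates and the defective densities of the two responses sum
to one. Numerical choices: a response faster than `t0` (or any density
underflow) contributes a floored log-density of `-1e10` rather than
`-Inf`, keeping Metropolis arithmetic finite; omissions are treated as
missing and excluded from the likelihood — the generator produces them
only by censoring responses slower than the 5 s response window.

Three variants express how the task conditions may act on the decision:
`M_v` lets both drift means vary by condition (12 subject parameters),
`M_B` lets the threshold vary (9), and `M_null` shares everything (6).

## 2. Hierarchical estimation by DE-MCMC

Subject parameters are sampled on a transformed scale (log for `A`, `B`,
`t0`, `sv_true`; natural for drifts) and modelled as independent normals
`x_sk ~ N(mu_k, sigma_k)` on that scale, i.e. log-normal group
distributions for the positivity-constrained parameters. Hyperpriors are
weakly informative: `mu` priors centred on plausible values (drifts
`N(1, 2)`; `log A`, `log B` centred at `log 0.5`; `log t0` at `log 0.3`;
`log sv` at 0) and `Exponential(1)` priors on every `sigma_k`. All of
these are arguments of `default_hyperpriors()` and can be replaced.

The sampler uses `3 x (subject parameters)` chains (36 for `M_v`), each
carrying the full state (all subjects plus the group level). A sweep
combines:

1. a differential-evolution (DE) crossover of every subject block,
   conditional on the chain's group state — proposals
   `x + gamma (x_j - x_k) + jitter` with distinct partner chains,
   Metropolis-accepted;
2. an exact Gibbs refresh of the group level given the subject draws
   (conjugate normal for `mu_k`; an independence Metropolis step for
   `sigma_k` proposed from the likelihood-conjugate inverse-gamma, with
   the exponential prior entering the acceptance ratio);
3. non-centered "interweaving" moves that hold the standardized subject
   deviations fixed and move `(mu_k, sigma_k)` — singly, and jointly for
   the whole group vector along DE directions. These are essential: the
   joint posterior has funnel geometry (small `sigma` pins the subjects
   to `mu`), which centered moves traverse extremely slowly;
4. a joint rescaling move along the LBA's soft scaling ridge
   (multiplying all drifts and shifting `log A`, `log B`, `log sv` by a
   common factor, `t0` fixed). With few error trials the fixed
   `sv_false = 1` constrains this direction only weakly, producing a
   long ridge that the move follows directly;
5. during burn-in only: whole-chain cyclic migration (5% per sweep by
   default) — a chain's subject and group states are mutually
   consistent, so rescue of a stuck chain must donate the complete
   state — and acceptance-targeted adaptation of the DE scales, frozen
   afterwards so the post-burn-in kernel is a fixed mixture.

Convergence is judged by the split-half potential scale reduction
factor: each chain is halved (doubling the chain count), univariate
statistics follow Gelman–Rubin and the multivariate statistic
Brooks–Gelman, with the conventional threshold `R-hat < 1.1`. Post
burn-in draws are thinned by 10. Starting values come from per-subject
penalized maximum-likelihood fits (Nelder–Mead on the sampling scale).

Model selection uses the expected log pointwise predictive density
estimated by WAIC from the stored draw-by-trial log-likelihood matrix —
the standard estimator computable from samples without refitting. Group
differences are assessed on the group-level posteriors of the two
separately fitted groups: paired differences (control minus patient) of
equal-length thinned samples, summarized by the 95% highest posterior
density interval (shortest window containing 95% of sorted draws); a
difference is called significant when the interval excludes zero.

## 3. The DCM forward model

Neural dynamics of the four regions follow the bilinear form

```
dz/dt = (A~ + u_pos B_pos + u_neg B_neg) z + C u
```

with `A~` equal to `A` off the diagonal and `-0.5 exp(A_ii)` on it: the
diagonal entries are unitless log-scalings of a -0.5 Hz self-decay, so a
lower value means a more excitable region, and the system cannot lose
self-inhibition entirely. The driving input (all face trials, mean-
centered over the session) enters the FFA only; the positive- and
negative-valence modulators are unit boxcars acting on the interregional
connections. Shapes trials drive no channel.

Hemodynamics follow the balloon–Windkessel model per region
(vasodilatory signal, inflow, venous volume `nu`, deoxyhemoglobin `q`)
with the observation `y = V0 (k1 (1 - q) + k2 (1 - q/nu) + k3 (1 - nu))`.
Constants are fixed at conventional values (`kappa = 0.64`,
`gamma = 0.32`, `tau = 2 s`, `alpha = 0.32`, `E0 = 0.4`, `V0 = 0.04`,
`k1 = 7 E0`, `k2 = 1.6`, `k3 = 1 - 1.5 E0`); the per-region transit time
is the only estimable hemodynamic quantity during inversion (as a log
scaling with a tight `N(0, 1/256)` prior), keeping the inversion
well-posed at this problem size. Integration uses a fixed-step RK4 at
micro-time `dt = TR/16` with inputs held constant within a step — chosen
for bit-reproducibility — and was validated against an adaptive
integrator at `rtol = 1e-10` and against the matrix-exponential solution
in the linear regime. BOLD is sampled at mid-volume times; measurement
noise is white Gaussian by default (an AR(1) option with configurable
lag-1 coefficient is available in `simulate_session()`; the AR(1)
whitening of the original GLM pipeline is out of scope).

## 4. Subject-level inversion

`variational_laplace()` fits a fixed-form Gaussian posterior by
Gauss–Newton ascent on the variational free energy, with: step
acceptance against a baseline recomputed at the current noise precision
(the precision anneals between iterations, so comparisons at stale
precisions are meaningless); Levenberg regularization that bends
rejected steps toward gradient ascent; a trust region of one prior SD
per coordinate per step (unbounded Gauss–Newton steps on this model
routinely jump into wrong basins); and a damped Newton update of the
noise log-precision under its `N(4, 1)` prior, initialized at the
residual-matched value so that a good warm start is not dragged back to
the prior while the assumed noise is still large. On linear-Gaussian
problems with fixed noise the converged free energy equals the exact log
evidence, which the test suite checks to `1e-4`.

The ascent is only locally convergent, and the DCM posterior is
multimodal (an approximate `(C, z) -> (-C, -z)` symmetry, plus
basin structure from the network gain). `invert_dcm()` therefore runs a
multistart: once from the prior mean and once from an empirical starting
point obtained by deconvolving each region's BOLD through the linearized
hemodynamic kernel (second-difference smoothness penalty, which
preserves amplitude) and regressing the neural derivative on the neural
states and the driving input. The higher-evidence solution is kept.
`fit_dcm_cohort()` adds two empirical-Bayes refinements across subjects:
re-inversion from the cohort-median warm start (kept only on free-energy
improvement), and a final pass under priors re-centered on the cohort
median, which counteracts shrinkage of weakly identified couplings
toward zero. Priors on the free parameters are `N(0, 1/64)` for the `A`
entries (off-diagonal and log-scaling diagonal) and `N(0, 1)` for `B`
and `C` entries.

## 5. Group level: PEB, reduction, classification

The Parametric Empirical Bayes model places a GLM over the subjects'
posterior means: `m_s = (x_s' ⊗ I) beta + e_s` with
`e_s ~ N(0, Sigma_s + exp(-gamma) Q)`, where `Sigma_s` is the subject's
posterior covariance, `Q` defaults to the first-level prior variances
divided by 16, and the random-effects log-precision `gamma` has a
`N(0, 1/16)` prior. Given `gamma` the model is linear-Gaussian, so the
`beta` posterior and the free energy are exact; `gamma` is optimized
numerically. The design matrix holds an intercept (commonality), the
group column, and SSRI, sex, age and handedness, all mean-centered
except the intercept; rank-deficient designs are rejected with the
collinear columns named. Intrinsic (`A`) and modulatory (`B`) parameters
are analysed in separate PEB runs sharing the design.

Bayesian model reduction computes the evidence and posterior of any
model that differs only in its (Gaussian) prior, analytically from the
full posterior. The greedy search switches off the second-level
parameter whose removal most increases the evidence and stops when every
single removal would decrease it; the nested models formed by toggling
the most evidence-ambiguous parameters around the final set (the
enumeration is capped, never exceeding 2^16 models) are scored, the best
256 retained, and estimates Bayesian-model-averaged with weights
proportional to model evidence. A parameter counts as present when its
summed weight exceeds 0.95.

Leave-one-out classification swaps the roles of the group predictor and
the connectivity estimates: for each held-out subject the PEB model is
fitted to the rest, and the posterior-predictive density of the
subject's connectivity is evaluated under either group label (with their
actual nuisance covariates); a flat label prior turns the ratio into a
probability of the patient class. Covariates are included as nuisance
columns in every fold (the alternative, residualizing them out first,
is not identifiable from the description of the original procedure).
The probability list yields the ROC curve and the Mann–Whitney AUC; its
confidence interval uses a stratified bootstrap of the probability list
(2000 resamples), since vertical averaging across cross-validation runs
is not reproducible from a single LOOCV pass. Folds that fail to fit are
excluded from the ROC rather than imputed.

## 6. The synthetic cohort

`cohort_config()` fixes the generating conditions:

* 33 controls, 30 patients; 4 blocks x 5 trials x 4 conditions per
  subject with randomized block order, 4 s stimuli and jittered 1.2–2.4 s
  inter-trial intervals inside a 335-volume, TR 1.6 s session (exact
  timings are not part of the published design, so they are
  configuration).
* Control group-level drift means `(2.2, 2.0, 1.4, 2.4)` for positive,
  negative, neutral, shapes — reproducing the empirical ordering
  (fastest for positive faces, slowest for neutral) — with the patient
  neutral drift lower by `neutral_gap` (default 0.14, the reported group
  difference); all other behavioral parameters shared between groups,
  matching the finding that only drift differed. Mismatch drift means
  `(0.6, 0.7, 1.0, 0.5)` make neutral the error-prone condition.
  Group-level SDs are 0.2 for drifts and 0.15 for the log-scale
  parameters.
* A mixed-sign base connectivity (excitatory feedforward, inhibitory
  feedback/top-down — the canonical cortical hierarchy; an
  all-excitatory network would sit near criticality and resembles no
  empirical effective-connectivity report), common valence modulations
  of the amygdala efferents, and patient-minus-control deltas
  `(-0.033, -0.085, +0.054, -0.036, -0.035)` Hz on the
  FFA↔LPFC, LPFC↔sgACC and sgACC→amygdala couplings — the pathway and
  magnitudes reported for the empirical group effect. SSRI intake
  (Bernoulli 0.6 among patients) lowers the sgACC self-connection
  log-scaling by 0.145.
* Between-subject SD of every free connectivity entry is 0.03, the
  scale implied by the conventional PEB assumption that random-effects
  variance is 1/16 of the prior variance (`sqrt(1/64/16) ≈ 0.03`).
* BOLD measurement noise SD 0.005, giving an effective SNR (signal SD /
  noise SD) of roughly 5–8 on the default network — the regime in which
  subject-level inversion is expected to work, and comparable to a
  well-behaved task-fMRI ROI time series.
* Covariates: sex (30%/33% male), age (normal, means 16.2/16.1, SDs
  1.9/1.4, clamped to the adolescent range), handedness (97%/93%
  right) — a matched design.

What the generator does **not** emulate: contaminant responses and
lapses, scanner drift and physiological (cardiac/respiratory) noise,
temporal autocorrelation, motion and its scrubbing, regional variation
of the hemodynamic response beyond transit time, dropout or missing
sessions, and any dependence between a subject's behavioral efficiency
and their connectivity (behavior and BOLD are generated independently
given group). Passing recovery tests on this cohort therefore shows the
estimators are correct and calibrated under the model's own
assumptions — not that those assumptions hold in patient data.

## 7. Validation scales and known limitations

The test-suite and acceptance computations run at deliberately reduced
problem sizes chosen as the package's own validation design: sampler
calibration uses 8–12 subjects per group with the full 80-trial
sessions; model-selection and group-difference calibration use 20 seeded
replicates each; the group-difference power arm injects a clearly
detectable neutral-drift gap of 0.5 (the reported 0.14 was estimated
from 63 subjects and is near the detection limit at 12 + 12 by design,
which would calibrate the decision rule against power rather than
against its error rates); DCM recovery uses 16 + 16 subjects and
sign/coverage criteria at SNR 5. The hierarchical sampler is run for a
few thousand sweeps in these checks; the convergence-targeted runs use
longer schedules, stated in `scripts/acceptance.R`.

Known limitations: the LBA hierarchy assumes independent normals across
parameters (no group-level correlations); WAIC is used as the ELPD
estimator rather than cross-validation; the DCM inversion is a local
ascent whose multistart and empirical-Bayes refinements mitigate but do
not eliminate multimodality (isolated subjects can converge to a wrong
basin, which inflates the PEB random-effects variance); and the
free-form noise model is a single white-noise precision shared across
regions.
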