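# accumdcm

Generative modelling of emotional face processing for computational
psychiatry: a hierarchical **linear ballistic accumulator** (LBA) analysis
of choice response times from a dynamic face- and shape-matching task, and
a four-region **dynamic causal model** (DCM) of the prefrontal–amygdala
network (fusiform face area, lateral prefrontal cortex, subgenual anterior
cingulate, amygdala) measured with fMRI. The package is aimed at
researchers who want to study group differences — here, adolescents with
major depressive disorder versus healthy controls — in both the cognitive
components of the decision process and the effective connectivity that
supports it, and at methodologists who want a self-contained, fully
synthetic testbed for this class of two-stage analyses.

## The models

**Behavior.** Each trial is a race between two ballistic accumulators
(match vs mismatch). An accumulator starts at `k ~ Uniform(0, A)`, rises
with drift `d ~ Normal(v, sv)` truncated to positive values, and responds
at `rt = t0 + (b - k)/d` with threshold `b = A + B`. The matching
accumulator's drift mean `v_true[condition]` indexes processing
efficiency; the mismatching accumulator has its drift SD fixed at 1 to set
the scale. Variants let the drifts (`M_v`), the threshold (`M_B`), or
nothing (`M_null`) vary over the four conditions (positive, negative,
neutral faces, shapes). Subjects are nested in a Bayesian hierarchy,
sampled with a differential-evolution MCMC scheme using `3 x` (subject
parameters) chains (36 for `M_v`), migration during burn-in, and thinning
by 10; convergence is checked with the split-half multivariate potential
scale reduction factor (threshold 1.1). Variants are compared by ELPD
(WAIC) and groups by the 95% highest posterior density interval of the
difference of group-level posteriors.

**Connectivity.** Neural dynamics follow the bilinear DCM
`dz/dt = (A~ + u_pos B_pos + u_neg B_neg) z + C u` with the all-faces
driving input entering the FFA and self-connections parameterized as
`-0.5 exp(a_ii)` Hz; BOLD arises from balloon–Windkessel hemodynamics and
is inverted per subject by variational Laplace. Group inference uses
Parametric Empirical Bayes over the subjects' posteriors (intercept,
group, SSRI, sex, age, handedness), Bayesian model reduction with a
greedy search and Bayesian model averaging over the best 256 nested
models, and a leave-one-out cross-validated classification of diagnosis
(ROC/AUC with bootstrap confidence bounds).

A synthetic cohort generator (`generate_cohort()`) reproduces the study
design — 33 controls and 30 patients, 80 trials per subject, 335 volumes
at TR = 1.6 s, matched covariates, a configurable neutral-drift group gap
(default 0.14) and connectivity group deltas on the
FFA–LPFC–sgACC–amygdala pathway — so every stage runs without any data
download. All generating parameters are stored as ground truth for
recovery testing.

## Worked example

```r
library(accumdcm)

# a small synthetic study: 8 controls + 8 patients, behavior only
cohort <- generate_cohort(
  cohort_config(n_controls = 8, n_patients = 8, neutral_gap = 0.5,
                seed = 42),
  simulate_bold = FALSE)

sc <- sampler_config(burnin = 500, samples = 1000, thin = 10, seed = 1)
fit_con <- run_hierarchical(
  subset(cohort$trials, group == "control"), "M_v", sc)
fit_mdd <- run_hierarchical(
  subset(cohort$trials, group == "MDD"), "M_v", sc)
fit_con
#> Hierarchical LBA fit (M_v): 8 subjects, 36 chains, 100 stored iterations (thin 10)
#>   multivariate split-half PSRF = 1.8149  [NOT converged]

compare_groups(fit_con, fit_mdd, "mu.v_true.neutral")
#> Delta(mu.v_true.neutral) = 0.724, 95% HPDI [0.212, 1.291]  *
```

The fit object reports its convergence diagnostic (short demonstration
runs like this one do not pass the 1.1 criterion; the acceptance script
below runs a convergence-length schedule). `compare_groups()` prints the
posterior mean difference of the neutral-condition matching drift
(control minus patient) with its 95% HPDI; the asterisk marks an interval
excluding zero — here recovering the injected gap of 0.5. The same
interface drives the DCM stage: `simulate_session()`,
`invert_dcm()`/`fit_dcm_cohort()`, `peb_fit()`,
`greedy_prune_and_average()` and `loocv_classify()`;
`run_pipeline(run_config(...))` chains all stages and writes a JSON
manifest.

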