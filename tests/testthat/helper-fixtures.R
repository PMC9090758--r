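# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small behavioral cohort (8 + 8 subjects) from the default generator.
fixture_behavioral_cohort <- function() {
  fixture("behavioral_cohort", function() {
    generate_cohort(cohort_config(n_controls = 8, n_patients = 8, seed = 301),
                    simulate_bold = FALSE)
  })
}

# Hierarchical M_v fits of the two groups of the small cohort.
fixture_group_fits <- function() {
  fixture("group_fits", function() {
    co <- fixture_behavioral_cohort()
    # the posterior-predictive checks need a reasonably converged fit,
    # so this fixture keeps the full move mix
    sc <- sampler_config(burnin = 400, samples = 600, thin = 10, seed = 11)
    tr <- co$trials
    list(control = run_hierarchical(tr[tr$group == "control", ], "M_v", sc),
         MDD = run_hierarchical(tr[tr$group == "MDD", ], "M_v", sc))
  })
}

# Full end-to-end DCM cohort fit (16 + 16 subjects with the documented
# group effects), shared between the recovery and classification checks.
fixture_endtoend <- function() {
  fixture("endtoend", function() {
    cc <- cohort_config(n_controls = 16, n_patients = 16, seed = 901,
                        ssri_rate = 0.5)
    co <- generate_cohort(cc)
    posts <- fit_dcm_cohort(co$sessions, co$events, max_iter = 12,
                            tol = 0.1)
    X <- cohort_design(co)
    a_pars <- grep("^A", names(dcm_priors()$mean), value = TRUE)
    fit <- peb_fit(posts, X, parameters = a_pars)
    pruned <- greedy_prune_and_average(fit)
    lc <- loocv_classify(posts, X, group_col = "group",
                         parameters = a_pars, n_boot = 200, seed = 902)
    list(config = cc, cohort = co, posteriors = posts, X = X,
         peb = fit, pruned = pruned, auc = lc$auc, loocv = lc)
  })
}

# Reference parameter set used across LBA unit tests.
fixture_lba_params <- function() {
  lba_params(A = 0.5, B = 0.5, t0 = 0.3, v_true = 1.2, v_false = 0.6,
             sv_true = 1)
}

# Monte-Carlo first-passage sample for one accumulator (the independent
# oracle for the closed-form density): start ~ U(0, A), drift ~ positive-
# truncated Normal(v, sv), first-passage time (b - start) / drift.
mc_first_passage <- function(n, A, b, v, sv, seed = 1) {
  set.seed(seed)
  k <- runif(n, 0, A)
  lo <- pnorm(0, v, sv)
  d <- qnorm(lo + runif(n) * (1 - lo), v, sv)
  (b - k) / d
}

# Simulate raw two-accumulator races (no censoring) for likelihood oracles.
mc_race <- function(n, params, condition = "neutral", seed = 1) {
  set.seed(seed)
  ci <- match(condition, task_conditions())
  b <- params$A + params$B[[ci]]
  k1 <- runif(n, 0, params$A); k2 <- runif(n, 0, params$A)
  lo1 <- pnorm(0, params$v_true[[ci]], params$sv_true)
  d1 <- qnorm(lo1 + runif(n) * (1 - lo1), params$v_true[[ci]], params$sv_true)
  lo2 <- pnorm(0, params$v_false[[ci]], 1)
  d2 <- qnorm(lo2 + runif(n) * (1 - lo2), params$v_false[[ci]], 1)
  t1 <- (b - k1) / d1; t2 <- (b - k2) / d2
  data.frame(rt = params$t0 + pmin(t1, t2), correct = t1 <= t2)
}

# Synthetic first-level posteriors for PEB/LOOCV calibration tests: true
# subject effects theta_s = beta0 + group_s * delta + noise, observed with
# a known posterior covariance.
synth_posteriors <- function(n_per_group, delta, beta0 = NULL, p = NULL,
                             subject_sd = 0.05, post_sd = 0.02, seed = 1) {
  set.seed(seed)
  p <- p %||% length(delta)
  beta0 <- beta0 %||% rep(0.1, p)
  n <- 2 * n_per_group
  group <- rep(c(0, 1), each = n_per_group)
  posts <- vector("list", n)
  for (s in seq_len(n)) {
    th <- beta0 + group[s] * delta + rnorm(p, 0, subject_sd)
    m <- th + rnorm(p, 0, post_sd)
    posts[[s]] <- subject_posterior(
      stats::setNames(m, paste0("par", seq_len(p))),
      diag(post_sd^2, p), F = 0,
      prior = list(mean = stats::setNames(numeric(p), paste0("par", seq_len(p))),
                   var = stats::setNames(rep(0.1, p), paste0("par", seq_len(p)))))
  }
  list(posteriors = posts, group = group)
}
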