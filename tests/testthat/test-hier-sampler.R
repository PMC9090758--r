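test_that("crossover proposals follow the DE rule and identity case accepts all", {
  set.seed(1)
  states <- matrix(rnorm(8), 4, 2)
  flat <- function(m) rep(0, nrow(m))
  st <- crossover_step(states, flat, gamma = 0, jitter_width = 0)
  expect_identical(st$states, states)
  expect_true(all(st$accepted))
  # with jitter off, every proposal must be theta_i + gamma (theta_j -
  # theta_k) for some distinct j, k != i
  states <- matrix(c(1, 2, 0.5, -1), 4, 1)
  prop <- accumdcm:::de_propose(states, gamma = 0.5, jitter_width = 0)
  for (i in 1:4) {
    others <- setdiff(1:4, i)
    pairs <- expand.grid(j = others, k = others)
    pairs <- pairs[pairs$j != pairs$k, ]
    cand <- states[i, 1] + 0.5 * (states[pairs$j, 1] - states[pairs$k, 1])
    expect_true(any(abs(prop[i, 1] - cand) < 1e-12))
  }
  expect_error(crossover_step(matrix(0, 3, 1), flat), "4 chains")
})

test_that("migration with zero probability or singleton subsets is the identity", {
  set.seed(2)
  states <- matrix(rnorm(10), 5, 2)
  flat <- function(m) rep(1, nrow(m))
  st <- migration_step(states, flat, migration_prob = 0)
  expect_identical(st$states, states)
  expect_false(st$migrated)
  # on a flat target every migration proposal is accepted, so the
  # multiset of chain states is preserved (states only move between
  # chains)
  for (r in 1:20) {
    st <- migration_step(states, flat, migration_prob = 1)
    expect_equal(sort(st$states[, 1]), sort(states[, 1]))
    states <- st$states
  }
})

test_that("DE-MCMC recovers the moments of a Gaussian target", {
  Sig <- matrix(c(1, 0.6, 0.6, 0.5), 2)
  Sinv <- solve(Sig)
  mu <- c(1, -2)
  logpost <- function(m) {
    d <- sweep(m, 2, mu)
    -0.5 * rowSums((d %*% Sinv) * d)
  }
  set.seed(3)
  init <- matrix(rnorm(20 * 2, 0, 2), 20, 2)
  draws <- de_mcmc_sample(logpost, init, n_iter = 3000, burnin = 500, seed = 4)
  flat <- apply(draws, 3, as.vector)
  # MC standard error from per-chain means (chains are near-independent)
  ch_mean <- apply(draws, c(2, 3), mean)
  se <- apply(ch_mean, 2, sd) / sqrt(nrow(ch_mean))
  expect_lt(abs(mean(flat[, 1]) - mu[1]), 3 * se[1])
  expect_lt(abs(mean(flat[, 2]) - mu[2]), 3 * se[2])
  expect_equal(unname(cov(flat)), Sig, tolerance = 0.15)
})

test_that("split-half PSRF matches a direct evaluation and handles degenerate chains", {
  # degenerate: identical constant chains
  draws <- array(1, c(8, 3, 2))
  expect_warning(rep <- psrf(draws), "zero within-chain")
  expect_equal(unname(rep$univariate), c(1, 1))
  expect_true(rep$pass)
  # hand-evaluated Gelman-Rubin on two chains of 4 values (split into 4
  # chains of 2)
  c1 <- c(1, 2, 1, 2); c2 <- c(1.5, 2.5, 1.5, 2.5)
  draws <- array(c(c1, c2), c(4, 2, 1))
  rep <- psrf(draws)
  halves <- list(c1[1:2], c1[3:4], c2[1:2], c2[3:4])
  n <- 2; m <- 4
  W <- mean(vapply(halves, var, numeric(1)))
  B_n <- var(vapply(halves, mean, numeric(1)))
  sig2 <- (n - 1) / n * W + B_n
  R_direct <- sqrt((m + 1) / m * sig2 / W - (n - 1) / (m * n))
  expect_equal(unname(rep$univariate[1]), R_direct, tolerance = 1e-12)
  # iid Gaussian chains are diagnosed as converged
  set.seed(5)
  draws <- array(rnorm(5000 * 4 * 3), c(5000, 4, 3))
  rep <- psrf(draws)
  expect_lt(rep$multivariate, 1.1)
  expect_true(rep$pass)
})

test_that("HPDI is the shortest window over sorted draws", {
  expect_equal(hpdi(rep(3.2, 10)), c(3.2, 3.2))
  expect_error(hpdi(1), "2 finite")
  expect_error(hpdi(rnorm(10), mass = 1.2), "mass")
  # brute-force oracle over all windows of 20 explicit values
  set.seed(6)
  x <- sort(c(rnorm(15), rnorm(5, 4)))
  w <- ceiling(0.9 * 20)
  widths <- x[(w + 1):20] - x[1:(20 - w)]
  i <- which.min(widths)
  expect_equal(hpdi(x, 0.9), c(x[i], x[i + w]))
  # large-sample Gaussian check
  set.seed(7)
  ci <- hpdi(rnorm(1e5), 0.95)
  expect_equal(ci, c(-1.96, 1.96), tolerance = 0.03)
})

test_that("group comparison pairs draws, applies the sign convention and flags zero-exclusion", {
  set.seed(8)
  base <- matrix(rnorm(4000, 1, 0.3), ncol = 2,
                 dimnames = list(NULL, c("mu.a", "mu.b")))
  same <- compare_groups(base, base, "mu.a")
  expect_false(same$significant)
  expect_equal(same$mean, 0)
  shifted <- base; shifted[, "mu.a"] <- shifted[, "mu.a"] - 0.5
  gd <- compare_groups(base, shifted, "mu.a")
  expect_true(gd$significant)
  expect_equal(gd$mean, 0.5, tolerance = 1e-12)   # paired in stored order
  expect_true(all(gd$delta > 0))                  # controls uniformly larger
  expect_lte(gd$hpdi[1], 0.5); expect_gte(gd$hpdi[2], 0.5)
  expect_error(compare_groups(base, base, "mu.zzz"), "not found")
})

test_that("fixed-effects initialization is order-invariant and recovers drifts at large n", {
  v <- model_variant("M_v")
  truth <- lba_params(A = 0.5, B = 0.7, t0 = 0.3,
                      v_true = c(2.2, 2.0, 1.4, 2.4),
                      v_false = c(0.6, 0.7, 1.0, 0.5), sv_true = 0.6)
  des <- session_design(blocks_per_condition = 25, seed = 10)  # 500 trials
  tr <- simulate_trials(truth, des, seed = 11, response_window = Inf)
  est <- fixed_effects_init(tr, v)
  expect_equal(dim(est), c(1L, 12L))
  p_est <- accumdcm:::variant_to_params(est[1, ], v)
  rel <- abs(p_est$v_true - truth$v_true) / truth$v_true
  expect_true(all(rel < 0.15))
  # permuting trial order leaves the estimate unchanged
  set.seed(12)
  est2 <- fixed_effects_init(tr[sample(nrow(tr)), ], v)
  expect_equal(est, est2, tolerance = 1e-6)
})

test_that("hierarchical sampler bookkeeping is exact", {
  co <- fixture_behavioral_cohort()
  fits <- fixture_group_fits()
  fit <- fits$control
  expect_equal(dim(fit$group_draws)[2], 36)            # 3 x 12 chains
  expect_equal(dim(fit$group_draws)[1], 600 %/% 10)    # floor(samples/thin)
  expect_equal(dim(fit$subject_draws)[3], 8)
  expect_equal(ncol(fit$pointwise),
               sum(co$trials$group == "control" &
                   co$trials$response != "omission"))
  expect_s3_class(fit$convergence, "convergence_report")
})

test_that("hierarchical fit recovers generating group-level locations", {
  v <- model_variant("M_v")
  mu_true <- c(2.2, 2.0, 1.4, 2.4, 0.6, 0.7, 1.0, 0.5,
               log(0.5), log(0.7), log(0.3), log(0.6))
  set.seed(13)
  dat <- do.call(rbind, lapply(1:20, function(s) {
    x <- rnorm(12, mu_true, 0.15)
    simulate_trials(accumdcm:::variant_to_params(x, v),
                    session_design(seed = 100 + s), seed = 200 + s,
                    subject_id = sprintf("s%02d", s))
  }))
  fit <- run_hierarchical(dat, v,
                          sampler_config(burnin = 500, samples = 700,
                                         thin = 10, seed = 14,
                                         n_interweave = 1, n_full = 2,
                                         n_scale = 2,
                                         store_loglik = FALSE))
  gm <- accumdcm:::group_draw_matrix(fit)
  covered <- vapply(seq_len(12), function(k) {
    ci <- hpdi(gm[, k], 0.95)
    mu_true[k] >= ci[1] && mu_true[k] <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 10)
})

test_that("WAIC comparison is zero for identical fits and errors on mismatched trials", {
  fits <- fixture_group_fits()
  cmp <- elpd_compare(list(a = fits$control, b = fits$control))
  expect_equal(cmp$table$delta_elpd, c(0, 0), tolerance = 1e-10)
  expect_equal(cmp$table$delta_se[2], 0, tolerance = 1e-10)
  truncated <- fits$control
  truncated$pointwise <- truncated$pointwise[, -1]
  expect_error(elpd_compare(list(a = fits$control, b = truncated)),
               "identical trial")
})

test_that("posterior-predictive cohorts have the validation design", {
  fits <- fixture_group_fits()
  pp <- posterior_predictive_cohort(fits, n_per_group = 40,
                                    trials_per_condition = 20, seed = 15)
  expect_equal(length(unique(pp$subject_id)), 80)
  expect_equal(sum(table(pp$subject_id, pp$group)[, "control"] > 0), 40)
  one <- pp[pp$subject_id == pp$subject_id[1], ]
  expect_equal(as.vector(table(one$condition)), rep(20, 4))
  sub <- subsample_cohort(pp, n_controls = 33, n_patients = 30, seed = 16)
  expect_equal(length(unique(sub$subject_id[sub$group == "control"])), 33)
  expect_equal(length(unique(sub$subject_id[sub$group == "MDD"])), 30)
  # RT distribution of synthetic controls close to the training data
  co <- fixture_behavioral_cohort()
  train <- co$trials[co$trials$group == "control" &
                     co$trials$response != "omission", "rt"]
  synth <- pp[pp$group == "control" & pp$response != "omission", "rt"]
  ks <- suppressWarnings(ks.test(synth, train)$statistic)
  expect_lt(unname(ks), 0.05)
})
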