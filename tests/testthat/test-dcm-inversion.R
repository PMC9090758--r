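# Conjugate linear-Gaussian toy shared by the variational-Laplace and BMR
# oracles.
linear_toy <- function(n = 40, p = 3, lambda = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  theta <- c(0.5, -1, 2)[seq_len(p)]
  y <- as.numeric(X %*% theta) + rnorm(n, 0, exp(-lambda / 2))
  list(X = X, y = y, theta = theta, lambda = lambda,
       prior_var = rep(4, p))
}

# Exact log evidence of y ~ N(X theta, e^-lambda I), theta ~ N(0, diag(pv)).
linear_evidence <- function(X, y, pv, lambda) {
  n <- length(y)
  Sy <- X %*% diag(pv, ncol(X)) %*% t(X) + diag(exp(-lambda), n)
  ch <- chol(Sy)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
}

test_that("variational Laplace equals the conjugate closed form on linear models", {
  toy <- linear_toy()
  fit <- variational_laplace(toy$y, function(th) as.numeric(toy$X %*% th),
                             rep(0, 3), toy$prior_var,
                             lambda0 = toy$lambda, fix_lambda = TRUE,
                             tol = 1e-8)
  P <- exp(toy$lambda) * crossprod(toy$X) + diag(1 / toy$prior_var)
  S <- solve(P)
  m <- as.numeric(S %*% (exp(toy$lambda) * crossprod(toy$X, toy$y)))
  expect_equal(unname(fit$mean), m, tolerance = 1e-6)
  expect_equal(unname(fit$cov), S, tolerance = 1e-6)
  le <- linear_evidence(toy$X, toy$y, toy$prior_var, toy$lambda)
  expect_equal(fit$F, le, tolerance = 1e-4)
  expect_true(fit$F <= le + 1e-6)     # free energy is a lower bound
})

test_that("uninformative data leave the posterior at the prior", {
  toy <- linear_toy()
  fit <- variational_laplace(toy$y, function(th) as.numeric(toy$X %*% th),
                             rep(0, 3), toy$prior_var,
                             lambda0 = -15, fix_lambda = TRUE, tol = 1e-8)
  expect_equal(unname(fit$mean), rep(0, 3), tolerance = 1e-4)
  expect_equal(unname(diag(fit$cov)), toy$prior_var, tolerance = 1e-3)
})

test_that("DCM inversion recovers coupling signs at SNR 5", {
  base <- accumdcm:::default_dcm_base()
  spec <- dcm_spec(A = base$A, B_pos = base$B_pos, B_neg = base$B_neg,
                   C = base$C)
  truth <- accumdcm:::pack_dcm_theta(spec)
  off <- grep("^A\\.", names(truth), value = TRUE)
  des <- session_design(seed = 3)
  ev <- data.frame(onset = des$onset, duration = des$duration,
                   condition = des$condition)
  s0 <- simulate_session(spec, events = ev, noise_sd = 0)
  noise <- sd(s0$bold) / 5
  ok <- logical(0)
  for (noise_seed in 1:3) {
    ses <- simulate_session(spec, events = ev, noise_sd = noise,
                            seed = noise_seed)
    post <- invert_dcm(ses, ev, max_iter = 48, tol = 0.02)
    sgn <- sign(truth[off]) == sign(post$mean[off])
    cov90 <- abs(truth[off] - post$mean[off]) <
      1.645 * sqrt(diag(post$cov))[match(off, names(post$mean))]
    ok <- c(ok, sgn & cov90)
  }
  expect_gte(mean(ok), 0.8)
})

test_that("Bayesian model reduction is exact on conjugate toys", {
  toy <- linear_toy()
  fit <- variational_laplace(toy$y, function(th) as.numeric(toy$X %*% th),
                             rep(0, 3), toy$prior_var,
                             lambda0 = toy$lambda, fix_lambda = TRUE,
                             tol = 1e-10)
  full_prior <- list(mean = rep(0, 3), cov = diag(toy$prior_var))
  # identical priors: no change
  same <- bayesian_model_reduction(fit, full_prior, full_prior)
  expect_equal(same$delta_F, 0, tolerance = 1e-10)
  expect_equal(unname(same$posterior$mean), unname(fit$mean),
               tolerance = 1e-8)
  # shrink one parameter to zero; compare with the directly computed
  # evidence of the reduced model
  rv <- c(4, 1e-8, 4)
  red <- bayesian_model_reduction(fit, full_prior,
                                  list(mean = rep(0, 3), cov = diag(rv)))
  dF_direct <- linear_evidence(toy$X, toy$y, rv, toy$lambda) -
    linear_evidence(toy$X, toy$y, toy$prior_var, toy$lambda)
  expect_equal(red$delta_F, dF_direct, tolerance = 1e-8)
  # reduced posterior equals direct inversion under the reduced prior
  fit_red <- variational_laplace(toy$y, function(th) as.numeric(toy$X %*% th),
                                 rep(0, 3), rv, lambda0 = toy$lambda,
                                 fix_lambda = TRUE, tol = 1e-10)
  expect_equal(unname(red$posterior$mean), unname(fit_red$mean),
               tolerance = 1e-6)
})

test_that("shrinking a truly null parameter does not hurt the evidence", {
  set.seed(31)
  dFs <- vapply(1:20, function(r) {
    toy <- linear_toy(seed = 100 + r)
    # regenerate data with the middle coefficient truly zero
    y <- as.numeric(toy$X %*% c(0.5, 0, 2)) + rnorm(40, 0, exp(-1))
    fit <- variational_laplace(y, function(th) as.numeric(toy$X %*% th),
                               rep(0, 3), toy$prior_var, lambda0 = 2,
                               fix_lambda = TRUE, tol = 1e-8)
    bayesian_model_reduction(fit,
      list(mean = rep(0, 3), cov = diag(toy$prior_var)),
      list(mean = rep(0, 3), cov = diag(c(4, 1e-8, 4))))$delta_F
  }, numeric(1))
  expect_gt(mean(dFs), 0)
})

test_that("PEB reduces to the precision-weighted average for intercept-only designs", {
  set.seed(32)
  p <- 4
  Sig <- diag(0.05, p)
  posts <- lapply(1:6, function(s)
    subject_posterior(stats::setNames(rnorm(p, 0.3, 0.2), paste0("b", 1:p)),
                      Sig))
  X <- peb_design(n = 6)
  fit <- peb_fit(posts, X, beta_var = rep(1e6, p), Q = diag(1e-12, p))
  pw <- rowMeans(vapply(posts, `[[`, numeric(p), "mean"))
  expect_equal(unname(fit$beta_mean), unname(pw), tolerance = 1e-6)
})

test_that("duplicating subjects preserves the PEB mean and tightens it", {
  set.seed(33)
  p <- 3
  posts <- lapply(1:8, function(s)
    subject_posterior(stats::setNames(rnorm(p, 0.2, 0.1), paste0("b", 1:p)),
                      diag(0.03, p)))
  X <- peb_design(n = 8)
  f1 <- peb_fit(posts, X, Q = diag(1e-3, p))
  f2 <- peb_fit(c(posts, posts), peb_design(n = 16), Q = diag(1e-3, p))
  expect_equal(unname(f2$beta_mean), unname(f1$beta_mean), tolerance = 0.02)
  expect_true(all(diag(f2$beta_cov) < diag(f1$beta_cov)))
})

test_that("PEB centers covariates and rejects collinear designs", {
  set.seed(34)
  posts <- lapply(1:6, function(s)
    subject_posterior(c(b = rnorm(1)), matrix(0.01)))
  X <- cbind(intercept = 1, age = c(10, 12, 14, 16, 18, 20))
  expect_warning(fit <- peb_fit(posts, X), "mean-centered")
  expect_lt(abs(mean(fit$X[, 2])), 1e-12)
  Xbad <- cbind(intercept = 1, a = c(1, 0, 1, 0, 1, 0), b = c(2, 0, 2, 0, 2, 0))
  expect_error(peb_fit(posts, Xbad), "rank deficient")
  expect_error(peb_design(a = 1:6, b = 2 * (1:6)), "collinear")
})

test_that("greedy pruning keeps strong effects and prunes true zeros", {
  # strong effects on every parameter: nothing pruned
  sp <- synth_posteriors(10, delta = rep(0, 4), beta0 = rep(0.5, 4),
                         subject_sd = 0.02, post_sd = 0.01, seed = 35)
  fit <- peb_fit(sp$posteriors, peb_design(n = 20))
  pruned <- greedy_prune_and_average(fit)
  expect_true(all(pruned$pp[grep("intercept", names(pruned$pp))] > 0.95))
  expect_equal(length(pruned$pruned), 0)
  expect_lte(pruned$n_models, 256)
  expect_equal(sum(pruned$model_weights), 1, tolerance = 1e-12)
  # true zeros are pruned in most replicates
  hits <- vapply(1:20, function(r) {
    sp <- synth_posteriors(20, delta = c(0.3, 0, 0), beta0 = c(0.4, 0, 0),
                           subject_sd = 0.03, post_sd = 0.02,
                           seed = 400 + r)
    X <- peb_design(group = sp$group)
    fit <- peb_fit(sp$posteriors, X)
    pr <- greedy_prune_and_average(fit)
    zero_pars <- c("intercept:par2", "intercept:par3",
                   "group:par2", "group:par3")
    all(pr$pp[zero_pars] < 0.95)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("AUC is the pairwise concordance and LOOCV is calibrated under the null", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.7, 0.6, 0.4),
                                c(1, 1, 1, 0, 0)), 1)
  # brute-force oracle over all 6 pairs
  expect_equal(auc_mann_whitney(c(0.9, 0.5, 0.7, 0.6, 0.4),
                                c(1, 1, 1, 0, 0)), 5 / 6)
  skip_if_not_installed("pROC")
  set.seed(36)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(auc_mann_whitney(sc, lb),
               as.numeric(suppressMessages(
                 pROC::auc(lb, sc, direction = "<", levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("LOOCV classification separates groups with effects and not without", {
  # informative group effect
  sp <- synth_posteriors(10, delta = c(0.15, -0.12, 0.1), seed = 37,
                         subject_sd = 0.03, post_sd = 0.02)
  X <- peb_design(group = sp$group)
  res <- loocv_classify(sp$posteriors, X, group_col = "group",
                        n_boot = 200, seed = 38)
  expect_gt(res$auc, 0.8)
  expect_true(res$ci[1] <= res$auc && res$ci[2] >= res$auc)
  expect_equal(length(res$prob), 20)
  # null calibration over 20 replicates
  aucs <- vapply(1:20, function(r) {
    sp <- synth_posteriors(8, delta = rep(0, 3), seed = 500 + r,
                           subject_sd = 0.05, post_sd = 0.02)
    loocv_classify(sp$posteriors, peb_design(group = sp$group),
                   group_col = "group", n_boot = 50, seed = r)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("group effects on the affected pathway are recovered end to end", {
  # one full pipeline replicate: generate a cohort with the documented
  # connectivity deltas, invert every subject (with empirical-Bayes
  # refinement), and test the PEB group effects and LOOCV discrimination
  e2e <- fixture_endtoend()
  injected <- paste0("group:", names(e2e$config$dcm_group_delta))
  est <- e2e$peb$beta_mean[injected]
  sign_ok <- sign(est) == sign(e2e$config$dcm_group_delta)
  expect_gte(sum(sign_ok), 4)          # effect directions recovered
  pp_ok <- e2e$pruned$pp[injected] > 0.95
  expect_gte(sum(sign_ok & pp_ok), 3)  # and most survive the reduction
  expect_gt(e2e$auc, 0.6)              # above the null calibration band
})
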