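test_that("accumulator CDF has the right limits and matches a Monte-Carlo oracle", {
  expect_equal(accumulator_cdf(0, 0.5, 1, 1, 1), 0)
  expect_equal(accumulator_cdf(1e5, 0.5, 1, 1, 1), 1, tolerance = 1e-3)
  # nondecreasing, bounded
  tt <- seq(0.01, 10, length.out = 200)
  Fv <- accumulator_cdf(tt, 0.5, 1, 1, 1)
  expect_true(all(diff(Fv) >= -1e-12))
  expect_true(all(Fv >= 0 & Fv <= 1))
  # 10^6-draw first-passage simulation at t = 1
  n <- 1e6
  fp <- mc_first_passage(n, A = 0.5, b = 1, v = 1, sv = 1, seed = 42)
  p_hat <- mean(fp <= 1)
  se <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(accumulator_cdf(1, 0.5, 1, 1, 1) - p_hat), 3 * se)
})

test_that("accumulator CDF/PDF reject invalid parameter domains by name", {
  expect_error(accumulator_cdf(1, -0.1, 1, 1, 1), "'A'")
  expect_error(accumulator_cdf(1, 0.5, 0.4, 1, 1), "'b'")
  expect_error(accumulator_pdf(1, 0.5, 1, 1, -1), "'sv'")
})

test_that("accumulator PDF is the derivative of the CDF and normalizes", {
  expect_equal(accumulator_pdf(c(-1, 0), 0.5, 1, 1, 1), c(0, 0))
  h <- 1e-5
  nd <- (accumulator_cdf(1 + h, 0.5, 1, 1, 1) -
         accumulator_cdf(1 - h, 0.5, 1, 1, 1)) / (2 * h)
  expect_equal(accumulator_pdf(1, 0.5, 1, 1, 1), nd, tolerance = 1e-6)
  # derivative consistency on a grid
  tg <- seq(0.2, 5, by = 0.2)
  ndg <- (accumulator_cdf(tg + h, 0.5, 1, 1, 1) -
          accumulator_cdf(tg - h, 0.5, 1, 1, 1)) / (2 * h)
  expect_equal(accumulator_pdf(tg, 0.5, 1, 1, 1), ndg, tolerance = 1e-6)
  # the positive-truncation tail is heavy (drifts near zero give very
  # long first-passage times), so the normalization check integrates to
  # infinity rather than truncating the domain
  total <- integrate(function(t) accumulator_pdf(t, 0.5, 1, 1, 1),
                     0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("defective densities of the race sum to one", {
  for (p in list(fixture_lba_params(),
                 lba_params(A = 0.2, B = 0.9, t0 = 0.2, v_true = 2.5,
                            v_false = 1.2, sv_true = 0.5),
                 lba_params(A = 0.8, B = 0.3, t0 = 0.4, v_true = 0.8,
                            v_false = 0.7, sv_true = 1.5))) {
    mass <- integrate(function(t)
      accumdcm:::defective_density(t, p, "neutral", TRUE), 0, 100)$value +
      integrate(function(t)
        accumdcm:::defective_density(t, p, "neutral", FALSE), 0, 100)$value
    expect_equal(mass, 1, tolerance = 1e-3)
  }
})

test_that("trial log-likelihood floors impossible RTs and matches a simulation oracle", {
  p <- fixture_lba_params()
  expect_equal(trial_loglik(p$t0 - 0.01, "neutral", TRUE, p), -1e10)
  # symmetry: identical accumulators split the response probability
  ps <- lba_params(A = 0.5, B = 0.5, t0 = 0.3, v_true = 1, v_false = 1,
                   sv_true = 1)
  p_correct <- integrate(function(t)
    accumdcm:::defective_density(t, ps, "neutral", TRUE), 0, 100)$value
  expect_equal(p_correct, 0.5, tolerance = 1e-3)
  # kernel-density oracle from 10^6 simulated races at rt = 1.2
  sim <- mc_race(1e6, p, seed = 7)
  p_corr <- mean(sim$correct)
  dens <- density(sim$rt[sim$correct], n = 2048, from = 0.9, to = 1.5)
  f_at <- approx(dens$x, dens$y, xout = 1.2)$y * p_corr
  expect_equal(trial_loglik(1.2, "neutral", TRUE, p), log(f_at),
               tolerance = 0.02)
})

test_that("simulated sessions have the designed layout", {
  p <- fixture_lba_params()
  tr <- simulate_trials(p, seed = 2)
  expect_equal(nrow(tr), 80)
  expect_equal(sort(unique(tr$condition)), sort(task_conditions()))
  expect_equal(as.vector(table(tr$condition)), rep(20, 4))
  expect_equal(length(unique(tr$block)), 16)
  # determinism
  expect_identical(tr, simulate_trials(p, seed = 2))
  # omission iff missing rt
  expect_true(all(is.na(tr$rt) == (tr$response == "omission")))
})

test_that("a deterministic race produces exact RTs", {
  # mismatch drift sv is fixed at 1, so the mismatching accumulator is
  # parked at a strongly negative drift to keep it out of the race; the
  # matching accumulator is then a deterministic linear rise to threshold
  p <- lba_params(A = 0, B = 1, t0 = 0.3, v_true = 2, v_false = -3,
                  sv_true = 1e-9)
  tr <- simulate_trials(p, seed = 5)
  expect_true(all(abs(tr$rt - 0.8) < 1e-6))
  expect_true(all(tr$correct))
})

test_that("simulated choice proportions agree with the defective-density integral", {
  p <- fixture_lba_params()
  n <- 1e5
  des <- data.frame(block = 1, condition = "neutral", onset = 0,
                    correct_side = "left")
  des <- des[rep(1, n), ]
  tr <- simulate_trials(p, des, seed = 3, response_window = Inf)
  p_sim <- mean(tr$correct)
  p_th <- integrate(function(t)
    accumdcm:::defective_density(t, p, "neutral", TRUE), 0, 200)$value
  se <- sqrt(p_th * (1 - p_th) / n)
  expect_lt(abs(p_sim - p_th), 3 * se)
})

test_that("simulation and likelihood imply the same RT distribution (KS)", {
  p <- fixture_lba_params()
  n <- 1e5
  des <- data.frame(block = 1, condition = "neutral", onset = 0,
                    correct_side = "left")[rep(1, n), ]
  tr <- simulate_trials(p, des, seed = 9, response_window = Inf)
  rts <- sort(tr$rt)
  # marginal RT CDF implied by the defective densities
  Fmix <- vapply(seq(0.35, 6, by = 0.05), function(u) {
    integrate(function(t) accumdcm:::defective_density(t, p, "neutral", TRUE),
              0, max(u - p$t0, 1e-9))$value +
    integrate(function(t) accumdcm:::defective_density(t, p, "neutral", FALSE),
              0, max(u - p$t0, 1e-9))$value
  }, numeric(1))
  ecdf_v <- ecdf(rts)(seq(0.35, 6, by = 0.05))
  expect_lt(max(abs(ecdf_v - Fmix)), 0.01)
})

test_that("increasing matching drift increases accuracy monotonically", {
  acc <- vapply(seq(0.5, 3, by = 0.5), function(v) {
    p <- lba_params(A = 0.5, B = 0.5, t0 = 0.3, v_true = v, v_false = 0.8,
                    sv_true = 1)
    integrate(function(t)
      accumdcm:::defective_density(t, p, "neutral", TRUE), 0, 200)$value
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("model variants enumerate the documented parameter structures", {
  mv <- model_variant("M_v")
  expect_equal(mv$n_subject_params, 12)
  expect_equal(mv$n_chains, 36)
  expect_setequal(mv$varies, c("v_true", "v_false"))
  expect_equal(model_variant("M_B")$n_subject_params, 9)
  expect_equal(model_variant("M_null")$n_subject_params, 6)
  expect_error(model_variant("M_x"))
  # round trip between parameter vector and structured parameters
  p <- lba_params(A = 0.4, B = 0.6, t0 = 0.25, v_true = c(2, 1.8, 1.2, 2.2),
                  v_false = c(0.5, 0.6, 0.9, 0.4), sv_true = 0.7)
  x <- accumdcm:::params_to_variant(p, mv)
  p2 <- accumdcm:::variant_to_params(x, mv)
  expect_equal(p2$v_true, p$v_true)
  expect_equal(p2$B, p$B)
  expect_equal(p2$t0, p$t0, tolerance = 1e-12)
})

test_that("R and C++ density implementations agree", {
  tg <- seq(0.05, 4, by = 0.05)
  p <- fixture_lba_params()
  # C++ kernel evaluated through the trial likelihood vs the exported
  # closed form assembled in R
  ll <- vapply(tg, function(t) trial_loglik(t + p$t0, "neutral", TRUE, p),
               numeric(1))
  direct <- pmax(log(accumdcm:::defective_density(tg, p, "neutral", TRUE)),
                 -1e10)   # the likelihood kernel floors underflows
  expect_equal(ll, direct, tolerance = 1e-10)
})
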