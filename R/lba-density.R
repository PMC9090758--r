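check_acc_args <- function(A, b, v, sv) {
  if (!is.finite(A) || A < 0) stop("invalid accumulator parameter 'A': must be >= 0", call. = FALSE)
  if (!is.finite(b) || b <= A) stop("invalid accumulator parameter 'b': must exceed A", call. = FALSE)
  if (!is.finite(v)) stop("invalid accumulator parameter 'v': must be finite", call. = FALSE)
  if (!is.finite(sv) || sv <= 0) stop("invalid accumulator parameter 'sv': must be > 0", call. = FALSE)
}

#' First-passage CDF of a single linear ballistic accumulator
#'
#' Probability that an accumulator with start point `~ Uniform(0, A)`
#' and drift `~ Normal(v, sv)` truncated to positive values has crossed
#' the threshold `b` by decision time `t`. Under the positive-drift
#' truncation the accumulator finishes almost surely, so the CDF tends
#' to 1 as `t` grows.
#'
#' @param t Decision time(s) in seconds (non-decision time already
#'   subtracted); vectorized.
#' @param A Start-point range, `>= 0`.
#' @param b Threshold, `> A`.
#' @param v Mean drift.
#' @param sv Between-trial drift SD, `> 0`.
#' @return Vector of probabilities in `[0, 1]`, nondecreasing in `t`.
#' @seealso [accumulator_pdf()], [trial_loglik()]
#' @export
accumulator_cdf <- function(t, A, b, v, sv) {
  check_acc_args(A, b, v, sv)
  cpp_acc_cdf(as.numeric(t), A, b, v, sv)
}

#' First-passage density of a single linear ballistic accumulator
#'
#' Derivative of [accumulator_cdf()]; integrates to 1 over positive
#' decision times under the positive-drift truncation convention.
#'
#' @inheritParams accumulator_cdf
#' @return Vector of densities (1/s), zero for `t <= 0`.
#' @export
accumulator_pdf <- function(t, A, b, v, sv) {
  check_acc_args(A, b, v, sv)
  cpp_acc_pdf(as.numeric(t), A, b, v, sv)
}

#' Log defective density of one observed trial
#'
#' Log-likelihood of observing the given response at the given response
#' time under the two-accumulator race: the density of the winning
#' accumulator finishing at `rt - t0` times the survivor function of
#' the losing one. The matching (correct-response) accumulator carries
#' drift `v_true[condition]` and SD `sv_true`; the mismatching one
#' `v_false[condition]` with SD 1. Responses faster than the
#' non-decision time are impossible and return the floor value `-1e10`
#' (used instead of `-Inf` to keep MCMC arithmetic finite).
#'
#' @param rt Response time in seconds.
#' @param condition Condition label, one of [task_conditions()].
#' @param correct Logical: did the matching accumulator win?
#' @param params An [lba_params()] object.
#' @return Scalar log-density.
#' @export
trial_loglik <- function(rt, condition, correct, params) {
  stopifnot(inherits(params, "lba_params"))
  condition <- match.arg(condition, .cond_levels)
  ci <- match(condition, .cond_levels) - 1L
  b4 <- matrix(params$A + params$B, nrow = 1)
  as.numeric(cpp_lba_loglik(params$A, b4, params$t0, params$sv_true,
                            matrix(params$v_true, 1), matrix(params$v_false, 1),
                            rt, ci, as.integer(isTRUE(correct))))
}

# Vectorized subject log-likelihood used by the sampler: theta is a matrix of
# sampling-scale parameter vectors (rows = chains); trials is a prepared list
# with rt, cond (0-based int), correct (int).
subject_loglik_chains <- function(theta, variant, trials) {
  p <- expand_chain_params(theta, variant)
  cpp_lba_loglik(p$A, p$b, p$t0, p$sv, p$vt, p$vf,
                 trials$rt, trials$cond, trials$correct)
}

subject_pointwise_chains <- function(theta, variant, trials) {
  p <- expand_chain_params(theta, variant)
  cpp_lba_pointwise(p$A, p$b, p$t0, p$sv, p$vt, p$vf,
                    trials$rt, trials$cond, trials$correct)
}

# Draw from Normal(v, sv) truncated to (0, Inf) by inverse CDF.
rtnorm_pos <- function(n, v, sv) {
  lo <- pnorm(0, v, sv)
  qnorm(lo + runif(n) * (1 - lo), v, sv)
}

#' Default session design of the face-matching task
#'
#' Sixteen blocks (four per condition, randomized order) of five trials
#' each, 80 trials in total. Each trial has a fixed stimulus duration
#' and a jittered inter-trial interval so the session fits within the
#' scan (335 volumes at TR 1.6 s).
#'
#' @param blocks_per_condition Number of blocks per condition.
#' @param trials_per_block Trials per block.
#' @param trial_duration Stimulus duration in seconds.
#' @param iti_range Inter-trial interval range in seconds (uniform
#'   jitter).
#' @param lead_in Rest before the first trial, seconds.
#' @param seed Integer seed for block order and jitter.
#' @return Data frame with columns `block`, `condition`, `onset`,
#'   `duration`, `correct_side` (`left`/`right`, counterbalanced).
#' @export
session_design <- function(blocks_per_condition = 4, trials_per_block = 5,
                           trial_duration = 4, iti_range = c(1.2, 2.4),
                           lead_in = 8, seed = 1) {
  n_blocks <- 4L * blocks_per_condition
  n_trials <- n_blocks * trials_per_block
  rs <- local_rng(seed)
  cond <- rep(sample(rep(.cond_levels, blocks_per_condition)),
              each = trials_per_block)
  iti <- runif(n_trials, iti_range[1], iti_range[2])
  onset <- lead_in + cumsum(c(0, (trial_duration + iti)[-n_trials]))
  side <- sample(rep(c("left", "right"), length.out = n_trials))
  data.frame(block = rep(seq_len(n_blocks), each = trials_per_block),
             condition = cond, onset = onset, duration = trial_duration,
             correct_side = side, stringsAsFactors = FALSE)
}

#' Simulate trials from the LBA race
#'
#' Draws one trial per design row: both accumulators receive a uniform
#' start point and a positive-truncated normal drift; the response is
#' the accumulator that reaches threshold first and
#' `rt = t0 + (b - start) / drift` of the winner. Responses slower than
#' the response window are censored to omissions.
#'
#' @param params An [lba_params()] object.
#' @param design Data frame as returned by [session_design()] (columns
#'   `block`, `condition`, `onset`, `correct_side`).
#' @param seed Integer seed; simulation is deterministic given the
#'   seed.
#' @param response_window Censoring limit in seconds; slower responses
#'   are recorded as omissions with missing RT.
#' @param subject_id,group Labels copied into the output.
#' @return A trial table: data frame with columns `subject_id`,
#'   `group`, `condition`, `block`, `onset`, `response`, `rt`,
#'   `correct`.
#' @export
simulate_trials <- function(params, design = session_design(), seed = 1,
                            response_window = 5, subject_id = "sub-01",
                            group = "control") {
  stopifnot(inherits(params, "lba_params"))
  rs <- local_rng(seed)
  n <- nrow(design)
  ci <- match(design$condition, .cond_levels)
  b <- unname(params$A + params$B[ci])
  k_match <- runif(n, 0, params$A)
  k_mis <- runif(n, 0, params$A)
  d_match <- rtnorm_pos(n, params$v_true[ci], params$sv_true)
  d_mis <- rtnorm_pos(n, params$v_false[ci], 1)
  t_match <- (b - k_match) / d_match
  t_mis <- (b - k_mis) / d_mis
  match_wins <- t_match <= t_mis
  rt <- params$t0 + pmin(t_match, t_mis)
  response <- ifelse(match_wins, design$correct_side,
                     ifelse(design$correct_side == "left", "right", "left"))
  omit <- rt > response_window
  response[omit] <- "omission"
  rt[omit] <- NA_real_
  data.frame(subject_id = subject_id, group = group,
             condition = design$condition, block = design$block,
             onset = design$onset, response = response, rt = rt,
             correct = ifelse(omit, NA, match_wins),
             stringsAsFactors = FALSE)
}

# Prepare a subject's trial table for the likelihood kernels: drop omissions,
# 0-based condition codes.
prepare_trials <- function(trials) {
  keep <- trials$response != "omission" & !is.na(trials$rt)
  tr <- trials[keep, , drop = FALSE]
  list(rt = as.numeric(tr$rt),
       cond = as.integer(match(tr$condition, .cond_levels) - 1L),
       correct = as.integer(tr$correct),
       n = nrow(tr))
}

# Defective density of (response = match-wins if correct, rt) marginalized:
# used by tests and posterior-predictive summaries.
defective_density <- function(t, params, condition, correct = TRUE) {
  ci <- match(condition, .cond_levels)
  b <- params$A + params$B[[ci]]
  if (correct) {
    accumulator_pdf(t, params$A, b, params$v_true[[ci]], params$sv_true) *
      (1 - accumulator_cdf(t, params$A, b, params$v_false[[ci]], 1))
  } else {
    accumulator_pdf(t, params$A, b, params$v_false[[ci]], 1) *
      (1 - accumulator_cdf(t, params$A, b, params$v_true[[ci]], params$sv_true))
  }
}
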