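# Differential-evolution MCMC primitives. Proposals for chain i are
# theta_i + gamma * (theta_j - theta_k) + Uniform(-jitter, jitter) noise with
# distinct j, k != i, accepted by Metropolis; migration occasionally cycles
# states among a random subset of chains to free stuck chains.

# Distinct partner indices j, k != i for every chain, vectorized.
de_partners <- function(nc) {
  i <- seq_len(nc)
  j <- sample.int(nc - 1L, nc, replace = TRUE)
  j <- j + (j >= i)
  k <- sample.int(nc - 2L, nc, replace = TRUE)
  a <- pmin(i, j); b <- pmax(i, j)
  k <- k + (k >= a)
  k <- k + (k >= b)
  cbind(j, k)
}

de_propose <- function(states, gamma, jitter_width) {
  nc <- nrow(states)
  jk <- de_partners(nc)
  prop <- states + gamma * (states[jk[, 1], , drop = FALSE] -
                            states[jk[, 2], , drop = FALSE])
  if (jitter_width > 0)
    prop <- prop + matrix(runif(length(prop), -jitter_width, jitter_width),
                          nrow = nc)
  prop
}

#' One DE-MCMC crossover step
#'
#' Updates every chain with a differential-evolution proposal
#' `theta_i + gamma * (theta_j - theta_k) + e`, where `j, k` are
#' distinct chains other than `i` and `e` is uniform jitter, followed
#' by a Metropolis accept/reject against `target_logpost`. The proposal
#' is symmetric, so detailed balance holds.
#'
#' @param chain_states Numeric matrix, one row per chain (at least 4
#'   chains), one column per parameter.
#' @param target_logpost Function taking a state matrix (rows = chains)
#'   and returning the vector of log posterior densities.
#' @param gamma Scale of the difference vector; defaults to
#'   `2.38 / sqrt(2 d)`.
#' @param jitter_width Half-width of the uniform jitter added to
#'   proposals.
#' @param current_logpost Optional cached log posterior of
#'   `chain_states`, to avoid re-evaluation.
#' @return List with `states` (updated matrix), `logpost` (vector) and
#'   `accepted` (logical vector).
#' @export
crossover_step <- function(chain_states, target_logpost, gamma = NULL,
                           jitter_width = 1e-3, current_logpost = NULL) {
  if (!is.matrix(chain_states)) chain_states <- as.matrix(chain_states)
  nc <- nrow(chain_states)
  if (nc < 4) stop("DE-MCMC requires at least 4 chains", call. = FALSE)
  d <- ncol(chain_states)
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (is.null(current_logpost)) current_logpost <- target_logpost(chain_states)
  prop <- de_propose(chain_states, gamma, jitter_width)
  lp_prop <- target_logpost(prop)
  acc <- log(runif(nc)) < (lp_prop - current_logpost)
  acc[!is.finite(lp_prop)] <- FALSE
  chain_states[acc, ] <- prop[acc, , drop = FALSE]
  current_logpost[acc] <- lp_prop[acc]
  list(states = chain_states, logpost = current_logpost, accepted = acc)
}

#' One DE-MCMC migration step
#'
#' With probability `migration_prob` a random subset of chains is
#' selected and each selected chain is proposed the state of its
#' predecessor in the (randomly ordered) cycle, accepted chainwise by
#' Metropolis. Used during burn-in only; a subset of size one leaves
#' the states unchanged.
#'
#' @inheritParams crossover_step
#' @param migration_prob Probability in `[0, 1]` that migration happens
#'   at all on this invocation.
#' @return List with `states`, `logpost` and `migrated` (logical
#'   scalar).
#' @export
migration_step <- function(chain_states, target_logpost,
                           migration_prob = 0.05, current_logpost = NULL) {
  if (!is.matrix(chain_states)) chain_states <- as.matrix(chain_states)
  if (migration_prob < 0 || migration_prob > 1)
    stop("migration_prob must be in [0, 1]", call. = FALSE)
  nc <- nrow(chain_states)
  if (is.null(current_logpost)) current_logpost <- target_logpost(chain_states)
  if (runif(1) >= migration_prob)
    return(list(states = chain_states, logpost = current_logpost,
                migrated = FALSE))
  m <- sample.int(nc, 1)
  sel <- sample.int(nc, m)
  if (m > 1) {
    donor <- sel[c(m, seq_len(m - 1))]   # chain sel[t] receives state of donor[t]
    prop <- chain_states[donor, , drop = FALSE]
    lp_prop <- current_logpost[donor]
    acc <- log(runif(m)) < (lp_prop - current_logpost[sel])
    chain_states[sel[acc], ] <- prop[acc, , drop = FALSE]
    current_logpost[sel[acc]] <- lp_prop[acc]
  }
  list(states = chain_states, logpost = current_logpost, migrated = TRUE)
}

#' Sample an arbitrary target with DE-MCMC
#'
#' Convenience driver looping [crossover_step()] (with optional
#' burn-in [migration_step()]) on a user-supplied log density;
#' used to validate the sampler against known posteriors.
#'
#' @param logpost Function from a state matrix (rows = chains) to a
#'   vector of log densities.
#' @param init Matrix of initial chain states.
#' @param n_iter Total sweeps.
#' @param burnin Sweeps discarded; migration is active only here.
#' @param migration_prob Migration probability during burn-in.
#' @param gamma,jitter_width See [crossover_step()].
#' @param seed Integer seed.
#' @return Array of retained draws, `(n_iter - burnin) x chains x d`.
#' @export
de_mcmc_sample <- function(logpost, init, n_iter = 1000, burnin = 200,
                           migration_prob = 0.05, gamma = NULL,
                           jitter_width = 1e-3, seed = 1) {
  local_rng(seed)
  states <- as.matrix(init)
  lp <- logpost(states)
  keep <- array(NA_real_, c(n_iter - burnin, nrow(states), ncol(states)))
  for (it in seq_len(n_iter)) {
    if (it <= burnin && runif(1) < migration_prob) {
      st <- migration_step(states, logpost, migration_prob = 1,
                           current_logpost = lp)
    } else {
      st <- crossover_step(states, logpost, gamma = gamma,
                           jitter_width = jitter_width, current_logpost = lp)
    }
    states <- st$states; lp <- st$logpost
    if (it > burnin) keep[it - burnin, , ] <- states
  }
  keep
}
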