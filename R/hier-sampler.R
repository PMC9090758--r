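# Hierarchical LBA: subject parameter vectors live on the sampling scale
# (log for A, B, t0, sv_true; natural for drifts) and are modelled as
# Normal(mu_k, sigma_k) per parameter k at the group level. Chains carry the
# full state (all subjects + group); updates alternate subject-level and
# group-level DE-MCMC crossovers (blocked Gibbs-within-DE), with migration
# during burn-in only.

#' Weakly-informative hyperpriors for the hierarchical LBA
#'
#' Group-level locations `mu_k` get normal priors centred on plausible
#' accumulator values (drifts near 1; `A`, `B` near 0.5; `t0` near
#' 0.3 s; `sv_true` near 1, all positivity-constrained parameters on
#' the log scale); group-level scales `sigma_k` get Exponential(1)
#' priors.
#'
#' @param variant An [model_variant()] descriptor.
#' @return List with vectors `mu_mean`, `mu_sd` (length
#'   `n_subject_params`) and scalar `sigma_rate`.
#' @export
default_hyperpriors <- function(variant) {
  nm <- variant$par_names
  mu_mean <- numeric(length(nm))
  mu_sd <- numeric(length(nm))
  for (i in seq_along(nm)) {
    p <- nm[i]
    if (grepl("^v_", p)) { mu_mean[i] <- 1; mu_sd[i] <- 2 }
    else if (grepl("^log_A", p)) { mu_mean[i] <- log(0.5); mu_sd[i] <- 1 }
    else if (grepl("^log_B", p)) { mu_mean[i] <- log(0.5); mu_sd[i] <- 1 }
    else if (p == "log_t0") { mu_mean[i] <- log(0.3); mu_sd[i] <- 0.5 }
    else { mu_mean[i] <- 0; mu_sd[i] <- 1 }   # log_sv_true
  }
  list(mu_mean = stats::setNames(mu_mean, nm),
       mu_sd = stats::setNames(mu_sd, nm), sigma_rate = 1)
}

#' Hierarchical LBA model descriptor
#'
#' @param variant An [model_variant()] descriptor or a variant name.
#' @param hyper Hyperpriors, see [default_hyperpriors()].
#' @return Object of class `hier_model`.
#' @export
hier_model <- function(variant, hyper = NULL) {
  if (is.character(variant)) variant <- model_variant(variant)
  hyper <- hyper %||% default_hyperpriors(variant)
  stopifnot(length(hyper$mu_mean) == variant$n_subject_params,
            all(hyper$mu_sd > 0), hyper$sigma_rate > 0)
  structure(list(variant = variant, hyper = hyper), class = "hier_model")
}

#' Sampler configuration
#'
#' @param burnin Burn-in sweeps (migration active here only).
#' @param samples Post-burn-in sweeps before thinning.
#' @param thin Keep every `thin`-th post-burn-in sweep (stored
#'   iterations = `floor(samples / thin)`).
#' @param migration_prob Migration probability during burn-in, applied
#'   at both the subject and the group level.
#' @param jitter_width Uniform jitter half-width of DE proposals.
#' @param seed Integer master seed.
#' @param store_loglik Keep the draw-by-trial pointwise log-likelihood
#'   matrix (needed for ELPD model comparison).
#' @param n_interweave Interweaved non-centered rescaling moves per
#'   sweep (each picks one random group parameter).
#' @param n_full Full-vector non-centered DE moves per sweep.
#' @param n_scale Joint drift/threshold rescaling moves per sweep.
#' @param init_maxit Nelder-Mead iteration cap of the fixed-effects
#'   starting-value fits.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(burnin = 300, samples = 1000, thin = 10,
                           migration_prob = 0.05, jitter_width = 1e-3,
                           seed = 1, store_loglik = TRUE, n_interweave = 2,
                           n_full = 3, n_scale = 3, init_maxit = 2000) {
  stopifnot(burnin >= 1, samples >= thin, thin >= 1,
            migration_prob >= 0, migration_prob <= 1, n_interweave >= 0)
  structure(list(burnin = as.integer(burnin), samples = as.integer(samples),
                 thin = as.integer(thin), migration_prob = migration_prob,
                 jitter_width = jitter_width, seed = as.integer(seed),
                 store_loglik = isTRUE(store_loglik),
                 n_interweave = as.integer(n_interweave),
                 n_full = as.integer(n_full), n_scale = as.integer(n_scale),
                 init_maxit = as.integer(init_maxit)),
            class = "sampler_config")
}

split_trials <- function(data) {
  stopifnot(all(c("subject_id", "condition", "response", "rt") %in% names(data)))
  ids <- unique(data$subject_id)
  trials <- lapply(ids, function(s)
    prepare_trials(data[data$subject_id == s, , drop = FALSE]))
  names(trials) <- ids
  trials
}

#' Per-subject fixed-effects starting values
#'
#' Penalized maximum-likelihood fit of the LBA to each subject
#' separately (Nelder-Mead on the sampling scale, started from the
#' hyperprior means with a weak shrinkage penalty). Used to initialize
#' the hierarchical chains. Deterministic given the data.
#'
#' @param data Trial table covering one or more subjects.
#' @param variant An [model_variant()] descriptor or name.
#' @param hyper Hyperpriors used for the shrinkage penalty.
#' @return Matrix `n_subjects x n_subject_params` of sampling-scale
#'   estimates, rownames = subject ids.
#' @export
fixed_effects_init <- function(data, variant, hyper = NULL, maxit = 2000) {
  if (is.character(variant)) variant <- model_variant(variant)
  hyper <- hyper %||% default_hyperpriors(variant)
  trials <- split_trials(data)
  d <- variant$n_subject_params
  start <- hyper$mu_mean
  out <- matrix(NA_real_, length(trials), d,
                dimnames = list(names(trials), variant$par_names))
  pmap <- variant_parmap(variant)
  mu0 <- unname(hyper$mu_mean)
  sd0 <- 2 * unname(hyper$mu_sd)
  for (s in seq_along(trials)) {
    tr <- trials[[s]]
    negpen <- function(x) {
      ll <- cpp_subj_loglik_one(x, pmap, tr$rt, tr$cond, tr$correct)
      -(ll + sum(dnorm(x, mu0, sd0, log = TRUE)))
    }
    fit <- tryCatch(
      optim(start, negpen, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) {
      warning("fixed-effects fit failed for subject '", names(trials)[s],
              "'; using hyperprior means", call. = FALSE)
      out[s, ] <- hyper$mu_mean
    } else {
      out[s, ] <- fit$par
    }
  }
  out
}

#' Fit the hierarchical LBA by DE-MCMC
#'
#' Samples the joint posterior of all subject-level parameter vectors
#' and their group-level means/SDs with `3 x n_subject_params` chains
#' (36 for the drift-varying variant `M_v`). Each sweep performs a
#' DE crossover of every subject block conditional on the chain's
#' group-level state, then of every group-level `(mu_k, sigma_k)` pair
#' conditional on the subject draws; during burn-in each block instead
#' migrates with the configured probability. Post-burn-in sweeps are
#' thinned and stored together with the pointwise log-likelihoods
#' needed for ELPD model comparison.
#'
#' @param data Trial table (omissions are excluded from the
#'   likelihood).
#' @param variant An [model_variant()] descriptor or name.
#' @param config A [sampler_config()].
#' @param hyper Optional hyperpriors ([default_hyperpriors()]).
#' @param init Optional matrix of subject starting values; defaults to
#'   [fixed_effects_init()].
#' @return Object of class `lba_hierfit` with elements `group_draws`
#'   (`stored x chains x 2 d` array of `mu`/`log_sigma` draws),
#'   `subject_draws` (`stored x chains x subjects x d`), `pointwise`
#'   (draws x trials log-likelihood matrix or `NULL`),
#'   `convergence` (a [psrf()] report over group-level parameters),
#'   plus bookkeeping (`variant`, `config`, `group_names`,
#'   `subject_ids`, `trial_index`).
#' @export
run_hierarchical <- function(data, variant, config = sampler_config(),
                             hyper = NULL, init = NULL) {
  if (is.character(variant)) variant <- model_variant(variant)
  hyper <- hyper %||% default_hyperpriors(variant)
  trials <- split_trials(data)
  S <- length(trials)
  d <- variant$n_subject_params
  nc <- variant$n_chains

  if (is.null(init))
    init <- fixed_effects_init(data, variant, hyper,
                               maxit = config$init_maxit %||% 2000)
  stopifnot(nrow(init) == S, ncol(init) == d)

  local_rng(config$seed)
  res <- cpp_hier_sampler(
    unname(trials), init, variant_parmap(variant),
    unname(hyper$mu_mean), unname(hyper$mu_sd), hyper$sigma_rate,
    nc, config$burnin, config$samples, config$thin,
    config$migration_prob, config$jitter_width, config$n_interweave,
    config$store_loglik, 0.1, config$n_full, config$n_scale)

  n_store <- config$samples %/% config$thin
  group_names <- c(paste0("mu.", variant$par_names),
                   paste0("sigma.", variant$par_names))
  G_draws <- res$group
  dimnames(G_draws) <- list(NULL, NULL, group_names)
  S_draws <- array(res$subjects, c(n_store, nc, S, d))
  n_tr <- vapply(trials, `[[`, integer(1), "n")
  trial_index <- data.frame(
    subject_id = rep(names(trials), n_tr),
    trial = unlist(lapply(n_tr, seq_len), use.names = FALSE))
  fit <- structure(list(
    variant = variant, config = config, hyper = hyper,
    group_draws = G_draws, subject_draws = S_draws,
    group_names = group_names, subject_ids = names(trials),
    pointwise = if (config$store_loglik) res$pointwise else NULL,
    trial_index = trial_index, init = init,
    acceptance = res$acceptance),
    class = "lba_hierfit")
  fit$convergence <- psrf(fit)
  fit
}

# 0-based column indices mapping the sampling-scale vector onto the
# condition-expanded parameter blocks of the C++ likelihood kernel.
variant_parmap <- function(variant) {
  nm <- variant$par_names
  idx <- function(field, log_scale = FALSE) {
    pref <- if (log_scale) paste0("log_", field) else field
    if (field %in% variant$varies) {
      match(paste0(pref, ".", .cond_levels), nm) - 1L
    } else {
      rep(match(pref, nm) - 1L, 4L)
    }
  }
  list(vt = idx("v_true"), vf = idx("v_false"), b = idx("B", TRUE),
       a = match("log_A", nm) - 1L, t0 = match("log_t0", nm) - 1L,
       sv = match("log_sv_true", nm) - 1L)
}

#' @export
print.lba_hierfit <- function(x, ...) {
  cat("Hierarchical LBA fit (", x$variant$name, "): ",
      length(x$subject_ids), " subjects, ",
      dim(x$group_draws)[2], " chains, ",
      dim(x$group_draws)[1], " stored iterations (thin ",
      x$config$thin, ")\n", sep = "")
  cat("  multivariate split-half PSRF = ",
      round(x$convergence$multivariate, 4),
      if (x$convergence$pass) "  [converged]" else "  [NOT converged]",
      "\n", sep = "")
  invisible(x)
}

# Flatten group-level draws to a (draws x parameter) matrix, sigma on the
# natural scale.
group_draw_matrix <- function(fit) {
  g <- fit$group_draws
  m <- matrix(g, dim(g)[1] * dim(g)[2], dim(g)[3])
  colnames(m) <- fit$group_names
  sig <- grepl("^sigma\\.", colnames(m))
  m[, sig] <- exp(m[, sig])
  m
}
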