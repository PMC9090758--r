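# Subject-level model inversion: fixed-form Gaussian variational inference
# (variational Laplace) with Gauss-Newton ascent on the free energy, plus the
# DCM-specific parameter packing and shrinkage priors.

#' Shrinkage priors of the DCM free parameters
#'
#' Free parameters and their independent Gaussian priors: the 12
#' off-diagonal and 4 diagonal (log-scaling) entries of `A`
#' (`N(0, 1/64)`), the off-diagonal entries of `B_pos` and `B_neg`
#' (`N(0, 1)`), the driving weight `C` (`N(0, 1)`), and the per-region
#' log transit-time scaling (`N(0, 1/256)`), the only estimable
#' hemodynamic quantity. Naming follows `A.to.from` (`A.LPFC.FFA` is
#' the connection from FFA to LPFC).
#'
#' @param a_var,aself_var,b_var,c_var,tau_var Prior variances per
#'   block.
#' @return List with named vectors `mean` and `var`.
#' @export
dcm_priors <- function(a_var = 1 / 64, aself_var = 1 / 64, b_var = 1,
                       c_var = 1, tau_var = 1 / 256) {
  rg <- .dcm_regions
  off <- expand.grid(to = rg, from = rg, stringsAsFactors = FALSE)
  off <- off[off$to != off$from, ]
  nm <- c(paste0("A.", off$to, ".", off$from),
          paste0("Aself.", rg),
          paste0("Bpos.", off$to, ".", off$from),
          paste0("Bneg.", off$to, ".", off$from),
          "C.faces",
          paste0("log_tau.", rg))
  v <- c(rep(a_var, 12), rep(aself_var, 4), rep(b_var, 12), rep(b_var, 12),
         c_var, rep(tau_var, 4))
  list(mean = stats::setNames(numeric(length(nm)), nm),
       var = stats::setNames(v, nm))
}

# theta vector (dcm_priors naming) -> dcm_spec + per-region transit scaling
unpack_dcm_theta <- function(theta, names = NULL) {
  if (!is.null(names)) names(theta) <- names
  rg <- .dcm_regions
  A <- matrix(0, 4, 4, dimnames = list(rg, rg))
  Bp <- A; Bn <- A
  for (to in rg) for (from in rg) {
    if (to == from) next
    A[to, from] <- theta[[paste0("A.", to, ".", from)]]
    Bp[to, from] <- theta[[paste0("Bpos.", to, ".", from)]]
    Bn[to, from] <- theta[[paste0("Bneg.", to, ".", from)]]
  }
  diag(A) <- theta[paste0("Aself.", rg)]
  list(spec = dcm_spec(A = A, B_pos = Bp, B_neg = Bn,
                       C = theta[["C.faces"]]),
       tau_scale = exp(unname(theta[paste0("log_tau.", rg)])))
}

# dcm_spec (+ tau scaling) -> theta vector
pack_dcm_theta <- function(spec, tau_scale = rep(1, 4)) {
  pr <- dcm_priors()
  th <- pr$mean
  rg <- .dcm_regions
  for (to in rg) for (from in rg) {
    if (to == from) next
    th[paste0("A.", to, ".", from)] <- spec$A[to, from]
    th[paste0("Bpos.", to, ".", from)] <- spec$B_pos[to, from]
    th[paste0("Bneg.", to, ".", from)] <- spec$B_neg[to, from]
  }
  th[paste0("Aself.", rg)] <- diag(spec$A)
  th["C.faces"] <- spec$C[1, 1]
  th[paste0("log_tau.", rg)] <- log(tau_scale)
  th
}

#' Construct a subject posterior
#'
#' Gaussian posterior over a subject's model parameters together with
#' its negative free energy (model-evidence bound); the container
#' passed between subject-level inversion and group-level (PEB)
#' analysis.
#'
#' @param mean Named numeric vector.
#' @param cov Covariance matrix (symmetric positive definite).
#' @param F Free energy value.
#' @param prior Optional list with `mean` and `var` of the
#'   subject-level prior (used by PEB to scale random effects).
#' @return Object of class `subject_posterior`.
#' @export
subject_posterior <- function(mean, cov, F = NA_real_, prior = NULL) {
  cov <- as.matrix(cov)
  stopifnot(length(mean) == nrow(cov), nrow(cov) == ncol(cov))
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("posterior covariance must be symmetric", call. = FALSE)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2, F = F, prior = prior),
            class = "subject_posterior")
}

logdet_pd <- function(M) 2 * sum(log(diag(chol(M))))

#' Variational-Laplace inversion
#'
#' Fits a fixed-form Gaussian posterior `q(theta) = N(m, S)` to a
#' nonlinear Gaussian observation model `y = g(theta) + e`,
#' `e ~ N(0, exp(-lambda) I)`, by Gauss-Newton ascent on the
#' variational free energy. Accepted steps never decrease F
#' (step-halving otherwise); non-positive-definite curvature is
#' Levenberg-regularized. The noise log-precision `lambda` is updated
#' by Newton steps under its Gaussian prior unless fixed. For a linear
#' `g` and fixed `lambda` the converged F equals the exact log model
#' evidence.
#'
#' @param y Numeric data vector.
#' @param forward Function `theta -> predicted y` (may return `NULL`
#'   or non-finite values for unstable parameters, which are treated
#'   as rejected proposals).
#' @param prior_mean,prior_var Gaussian prior (variances, independent)
#'   or `prior_cov` for a full matrix.
#' @param lambda0,lambda_var Prior mean/variance of the noise
#'   log-precision.
#' @param fix_lambda Fix `lambda` at `lambda0` (then no lambda prior
#'   term enters F).
#' @param max_iter,tol Stop after `max_iter` Gauss-Newton iterations
#'   or when the F improvement falls below `tol`.
#' @param fd_step Forward finite-difference step for the Jacobian.
#' @param init Optional starting value of the posterior mean
#'   (defaults to the prior mean).
#' @param trust Trust region: the largest move per coordinate per
#'   Gauss-Newton step, in units of the prior SD.
#' @return A [subject_posterior()] with extra fields `lambda`,
#'   `iterations`, `converged`, `trace` (F per iteration).
#' @export
variational_laplace <- function(y, forward, prior_mean, prior_var = NULL,
                                prior_cov = NULL, lambda0 = 4,
                                lambda_var = 1, fix_lambda = FALSE,
                                max_iter = 32, tol = 1e-3, fd_step = 1e-4,
                                init = NULL, trust = 1) {
  y <- as.numeric(y)
  N <- length(y)
  p <- length(prior_mean)
  m0 <- as.numeric(prior_mean)
  if (is.null(prior_cov)) {
    stopifnot(length(prior_var) == p, all(prior_var > 0))
    P0 <- diag(1 / prior_var, p)
    ld_S0 <- sum(log(prior_var))
  } else {
    P0 <- solve(prior_cov)
    ld_S0 <- logdet_pd(as.matrix(prior_cov))
  }

  eval_forward <- function(th) {
    g <- tryCatch(forward(th), error = function(e) NULL)
    if (is.null(g) || length(g) != N || any(!is.finite(g))) NULL else g
  }

  prior_sd <- sqrt(if (is.null(prior_cov)) prior_var else diag(prior_cov))
  m <- if (is.null(init)) m0 else as.numeric(init)
  g <- eval_forward(m)
  if (is.null(g))
    stop("forward model failed at the prior mean; cannot start inversion",
         call. = FALSE)
  # start the noise log-precision at its residual-matched value: a
  # mismatched initial precision either drags a good starting point back
  # into the prior (precision too low) or freezes a poor one (too high)
  lambda <- if (fix_lambda) lambda0 else
    max(lambda0, min(log(N / sum((y - g)^2)), lambda0 + 12))

  jacobian <- function(m, g) {
    J <- matrix(0, N, p)
    for (i in seq_len(p)) {
      mi <- m
      h <- fd_step * max(1, abs(m[i]))
      mi[i] <- mi[i] + h
      gi <- eval_forward(mi)
      if (is.null(gi)) {           # one-sided fallback
        mi[i] <- m[i] - h
        gi <- eval_forward(mi)
        if (is.null(gi)) gi <- g
        h <- -h
      }
      J[, i] <- (gi - g) / h
    }
    J
  }

  free_energy <- function(e, JtJ, S, m, lambda) {
    acc <- -0.5 * exp(lambda) * (sum(e^2) + sum(JtJ * S)) +
      0.5 * N * lambda - 0.5 * N * log(2 * pi)
    dm <- m - m0
    kl <- 0.5 * (sum(P0 * S) + sum(dm * (P0 %*% dm)) - p +
                 ld_S0 - logdet_pd(S))
    Fv <- acc - kl
    if (!fix_lambda)
      Fv <- Fv + dnorm(lambda, lambda0, sqrt(lambda_var), log = TRUE)
    Fv
  }

  S <- diag(1e-6, p)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    J <- jacobian(m, g)
    JtJ <- crossprod(J)
    e <- y - g

    # noise precision: one damped Newton step per iteration (a cautious
    # annealing of the assumed precision keeps the early ascent on a soft
    # likelihood surface and avoids shallow local optima)
    if (!fix_lambda) {
      H <- JtJ * exp(lambda) + P0
      Sl <- tryCatch(chol2inv(chol(H)), error = function(err) NULL)
      tr_term <- sum(e^2) + if (is.null(Sl)) 0 else sum(JtJ * Sl)
      g1 <- 0.5 * N - 0.5 * exp(lambda) * tr_term -
        (lambda - lambda0) / lambda_var
      g2 <- -0.5 * exp(lambda) * tr_term - 1 / lambda_var
      lambda <- lambda + max(-0.5, min(0.5, -g1 / g2))
    }

    lam <- exp(lambda)
    grad <- lam * crossprod(J, e) - P0 %*% (m - m0)
    H0 <- lam * JtJ + P0
    scale_r <- mean(diag(H0))
    chol_H <- function(ridge) {
      tryCatch(chol(H0 + diag(ridge * scale_r, p)),
               error = function(err) NULL)
    }
    ch <- chol_H(0)
    if (is.null(ch)) ch <- chol_H(1e-6)
    if (is.null(ch)) stop("inversion failure: curvature not positive ",
                          "definite despite regularization", call. = FALSE)
    S_new <- chol2inv(ch)

    # baseline F of staying at m, under the current lambda and S: the
    # lambda annealing changes F between iterations, so step acceptance
    # must compare candidates against a baseline at the same lambda.
    # Rejected steps raise the Levenberg ridge, bending the proposal from
    # the Gauss-Newton direction toward (short) gradient ascent.
    F_base <- free_energy(e, JtJ, S_new, m, lambda)
    ridge <- 0
    accepted <- FALSE
    for (lm_try in 1:10) {
      chr <- chol_H(ridge)
      if (!is.null(chr)) {
        dm <- as.numeric(backsolve(chr, backsolve(chr, grad,
                                                  transpose = TRUE)))
        # trust region: at most `trust` prior SDs per coordinate per step
        over <- max(abs(dm) / prior_sd)
        if (over > trust) dm <- dm * (trust / over)
        m_try <- m + dm
        g_try <- eval_forward(m_try)
        if (!is.null(g_try)) {
          F_try <- free_energy(y - g_try, JtJ, S_new, m_try, lambda)
          if (F_try > F_base) {
            m <- m_try; g <- g_try; S <- S_new
            F_new <- F_try
            accepted <- TRUE
            break
          }
        }
      }
      ridge <- if (ridge == 0) 1e-3 else ridge * 8
    }
    if (!accepted) {
      F_new <- F_base
      S <- S_new
    }
    trace <- c(trace, F_new)
    lam_settled <- fix_lambda ||
      abs(0.5 * N - 0.5 * exp(lambda) * (sum(e^2) + sum(JtJ * S)) -
          (lambda - lambda0) / lambda_var) * lambda_var < 0.05
    if ((F_new - F_base) < tol && lam_settled) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  F_old <- trace[length(trace)]

  out <- subject_posterior(stats::setNames(m, names(prior_mean)), S,
                           F = F_old)
  out$lambda <- lambda
  out$iterations <- it
  out$converged <- converged
  out$trace <- trace
  out
}

#' Empirical starting point for DCM inversion
#'
#' System-identification initializer: each region's neural time course
#' is recovered by deconvolving the BOLD signal through the linearized
#' hemodynamic impulse response (with a second-difference smoothness
#' penalty, which preserves amplitude), and the couplings are then
#' estimated by regressing the neural derivative on the neural states
#' and the driving input, with the self-decay fixed at its prior. Used
#' as a warm start; the free-energy comparison across starts decides
#' which basin the final posterior comes from.
#'
#' @param bold 4 x n BOLD matrix.
#' @param events Task events.
#' @param TR Repetition time (s).
#' @param hemo Hemodynamic constants.
#' @param priors See [dcm_priors()].
#' @param micro_dt Kernel integration step.
#' @return Named parameter vector on the [dcm_priors()] layout.
#' @export
dcm_empirical_init <- function(bold, events, TR = 1.6,
                               hemo = hemo_params(), priors = dcm_priors(),
                               micro_dt = TR / 16) {
  nv <- ncol(bold)
  lags <- min(22L, nv)
  # impulse response to a 1-TR unit neural pulse, sampled at TR
  nmic <- ceiling((lags + 1) * TR / micro_dt) + 1L
  z <- c(rep(0.01, round(TR / micro_dt)), rep(0, nmic))
  st <- c(0, 1, 1, 1); yk <- numeric(nmic)
  for (i in seq_len(nmic)) {
    stepfun <- function(stt, zz) {
      fout <- stt[3]^(1 / hemo$alpha)
      Ef <- 1 - (1 - hemo$E0)^(1 / stt[2])
      c(zz - hemo$kappa * stt[1] - hemo$gamma_h * (stt[2] - 1), stt[1],
        (stt[2] - fout) / hemo$tau[1],
        (stt[2] * Ef / hemo$E0 - fout * stt[4] / stt[3]) / hemo$tau[1])
    }
    k1 <- stepfun(st, z[i]); k2 <- stepfun(st + micro_dt / 2 * k1, z[i])
    k3 <- stepfun(st + micro_dt / 2 * k2, z[i])
    k4 <- stepfun(st + micro_dt * k3, z[i])
    st <- st + micro_dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    yk[i] <- hemo$V0 * (hemo$k1 * (1 - st[4]) + hemo$k2 * (1 - st[4] / st[3]) +
                        hemo$k3 * (1 - st[3]))
  }
  kern <- yk[pmax(round((seq_len(lags) - 0.5) * TR / micro_dt), 1)] / (0.01 * TR)
  K <- matrix(0, nv, nv)
  for (l in seq_along(kern)) {
    idx <- seq_len(nv - l + 1)
    K[cbind(idx + l - 1, idx)] <- kern[l] * TR
  }
  D2 <- diff(diag(nv), differences = 2)
  KtK <- crossprod(K)
  Z <- solve(KtK + 1e-4 * mean(diag(KtK)) * crossprod(D2),
             crossprod(K, t(bold)))
  U <- build_task_inputs(events, micro_dt, nv * TR)
  uTR <- U[pmax(round((seq_len(nv) - 0.5) * TR / micro_dt), 1), 1]
  dZ <- (Z[-1, , drop = FALSE] - Z[-nv, , drop = FALSE]) / TR
  Zm <- (Z[-1, , drop = FALSE] + Z[-nv, , drop = FALSE]) / 2
  um <- (uTR[-1] + uTR[-nv]) / 2
  Aini <- matrix(0, 4, 4)
  Cini <- 0.3
  for (r in 1:4) {
    yy <- dZ[, r] + 0.5 * Zm[, r]
    Xr <- cbind(Zm[, -r, drop = FALSE], if (r == 1) um else NULL)
    bb <- solve(crossprod(Xr) + 1e-8 * diag(ncol(Xr)), crossprod(Xr, yy))
    Aini[r, setdiff(1:4, r)] <- bb[1:3]
    if (r == 1) Cini <- bb[4]
  }
  th0 <- priors$mean
  rg <- .dcm_regions
  for (to in 1:4) for (from in 1:4) {
    if (to == from) next
    th0[paste0("A.", rg[to], ".", rg[from])] <-
      min(max(Aini[to, from], -0.4), 0.4)
  }
  th0["C.faces"] <- min(max(Cini, 0.1), 1)
  th0
}

#' Invert a BOLD session under the four-region DCM
#'
#' Wraps [variational_laplace()] around the DCM forward model: free
#' parameters are the A/B/C entries and per-region transit scaling
#' (see [dcm_priors()]); the observation noise log-precision is
#' estimated alongside. By default the ascent is run twice — once from
#' the prior mean and once from the empirical starting point of
#' [dcm_empirical_init()] — and the solution with the higher free
#' energy is returned (the ascent is only locally convergent).
#'
#' @param session A [simulate_session()] result or a 4 x n matrix.
#' @param events Task events used to rebuild the input channels.
#' @param priors See [dcm_priors()].
#' @param hemo Hemodynamic constants.
#' @param micro_dt Integration step.
#' @param multistart Also run from the empirical starting point and
#'   keep the higher-evidence solution.
#' @param ... Passed to [variational_laplace()].
#' @return A [subject_posterior()] carrying the DCM prior in `$prior`.
#' @export
invert_dcm <- function(session, events, priors = dcm_priors(),
                       hemo = hemo_params(), micro_dt = NULL,
                       multistart = TRUE, ...) {
  if (inherits(session, "bold_session")) {
    Y <- session$bold; TR <- session$TR; n_vol <- session$n_volumes
    micro_dt <- micro_dt %||% session$micro_dt
  } else {
    Y <- as.matrix(session); TR <- 1.6; n_vol <- ncol(Y)
    micro_dt <- micro_dt %||% (TR / 16)
  }
  U <- build_task_inputs(events, micro_dt, n_vol * TR)
  nms <- names(priors$mean)
  forward <- function(theta) {
    up <- unpack_dcm_theta(theta, nms)
    sim <- cpp_dcm_simulate(up$spec$A, up$spec$B_pos, up$spec$B_neg,
                            up$spec$C, U, micro_dt, as.integer(n_vol), TR,
                            hemo$kappa, hemo$gamma_h,
                            hemo$tau * up$tau_scale, hemo$alpha, hemo$E0,
                            hemo$V0, hemo$k1, hemo$k2, hemo$k3, FALSE)
    if (!isTRUE(sim$ok)) return(NULL)
    as.numeric(sim$bold)
  }
  post <- variational_laplace(as.numeric(Y), forward, priors$mean,
                              prior_var = priors$var, ...)
  if (multistart) {
    init2 <- tryCatch(
      dcm_empirical_init(Y, events, TR = TR, hemo = hemo, priors = priors,
                         micro_dt = micro_dt),
      error = function(e) NULL)
    if (!is.null(init2)) {
      post2 <- tryCatch(
        variational_laplace(as.numeric(Y), forward, priors$mean,
                            prior_var = priors$var, init = init2, ...),
        error = function(e) NULL)
      if (!is.null(post2) && is.finite(post2$F) && post2$F > post$F)
        post <- post2
    }
  }
  post$prior <- priors
  post
}
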