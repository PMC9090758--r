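# Parametric Empirical Bayes: a Gaussian GLM over subjects' posterior
# connectivity estimates. Writing m_s for subject s's posterior mean over
# the selected parameters and Sigma_s for its covariance, the second-level
# model is
#   m_s = (x_s' kron I_p) beta + eps_s,   eps_s ~ N(0, Sigma_s + exp(-gamma) Q)
# with beta ~ N(0, S_beta0) and gamma (log random-effects precision) given a
# Gaussian prior. Given gamma the model is linear-Gaussian, so beta's
# posterior and the free energy are exact; gamma is optimized numerically.

#' Build a PEB design matrix
#'
#' Column 1 is the intercept (commonality); all further columns are
#' mean-centered. Rejects rank-deficient designs, naming the collinear
#' columns.
#'
#' @param ... Named covariate vectors (e.g. `group = `, `ssri = `).
#' @param n Number of subjects (checked against the covariates).
#' @return Design matrix with zero-mean covariate columns.
#' @export
peb_design <- function(..., n = NULL) {
  cov <- list(...)
  stopifnot(length(cov) == 0 || !is.null(names(cov)))
  n <- n %||% length(cov[[1]])
  X <- cbind(intercept = rep(1, n))
  for (nm in names(cov)) {
    v <- as.numeric(cov[[nm]])
    stopifnot(length(v) == n)
    X <- cbind(X, v - mean(v))
    colnames(X)[ncol(X)] <- nm
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

# Extract the (sub)vector/matrix over `parameters` from a subject posterior.
subset_posterior <- function(post, parameters) {
  idx <- match(parameters, names(post$mean))
  if (anyNA(idx))
    stop("parameter(s) missing from subject posterior: ",
         paste(parameters[is.na(idx)], collapse = ", "), call. = FALSE)
  list(mean = as.numeric(post$mean[idx]),
       cov = as.matrix(post$cov)[idx, idx, drop = FALSE])
}

#' Fit the PEB model
#'
#' Empirical-Bayes estimation of second-level effects `beta` and the
#' random-effects log-precision `gamma` by maximizing the (exact,
#' given gamma) free energy of the hierarchical Gaussian model; the
#' subject-level posterior covariances propagate into the fit.
#'
#' @param posteriors List of [subject_posterior()] objects sharing a
#'   parameter space.
#' @param X Design matrix from [peb_design()] (rows = subjects;
#'   column 1 = intercept, further columns mean-centered — small
#'   deviations are re-centered with a warning).
#' @param parameters Which first-level parameters to take to the
#'   second level (default: all).
#' @param beta_var Prior variance of each `beta` entry; defaults to
#'   the first-level prior variances (every design column), read from
#'   the posteriors' `$prior` or 1 if absent.
#' @param Q Between-subject covariance pattern; defaults to
#'   first-level prior variances / 16.
#' @param gamma0,gamma_var Gaussian prior on `gamma`.
#' @return Object of class `peb_result`: `beta_mean`, `beta_cov`
#'   (named `column:parameter`), `gamma`, `F`, plus the ingredients
#'   needed for reduction and LOOCV.
#' @export
peb_fit <- function(posteriors, X, parameters = NULL, beta_var = NULL,
                    Q = NULL, gamma0 = 0, gamma_var = 1 / 16) {
  stopifnot(length(posteriors) >= 2)
  X <- as.matrix(X)
  n <- length(posteriors)
  if (nrow(X) != n) stop("rows of X must match subjects", call. = FALSE)
  if (ncol(X) >= 2) {
    cm <- colMeans(X[, -1, drop = FALSE])
    if (any(abs(cm) > 1e-8)) {
      warning("covariate columns were not mean-centered; centering them",
              call. = FALSE)
      X[, -1] <- sweep(X[, -1, drop = FALSE], 2, cm)
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X) %||% seq_len(ncol(X)), collapse = ", "),
         call. = FALSE)
  parameters <- parameters %||% names(posteriors[[1]]$mean)
  p <- length(parameters)
  c_ <- ncol(X)
  sub <- lapply(posteriors, subset_posterior, parameters = parameters)

  pv <- posteriors[[1]]$prior
  prior_var_1l <- if (!is.null(pv))
    pv$var[match(parameters, names(pv$mean))] else rep(1, p)
  if (is.null(Q)) Q <- diag(as.numeric(prior_var_1l) / 16, p)
  Q <- as.matrix(Q)
  if (is.null(beta_var)) beta_var <- rep(as.numeric(prior_var_1l), c_)
  stopifnot(length(beta_var) == c_ * p)

  M <- unlist(lapply(sub, `[[`, "mean"))               # stacked, subject-major
  Pb0 <- diag(1 / beta_var, c_ * p)
  ld_Sb0 <- sum(log(beta_var))

  # Free energy and beta posterior for a given gamma, via the Woodbury /
  # determinant-lemma decomposition over the block-diagonal V.
  fit_gamma <- function(gamma, want_beta = FALSE) {
    Vre <- exp(-gamma) * Q
    A_ <- Pb0                    # S_beta0^{-1} + Z' V^{-1} Z, accumulated
    bvec <- numeric(c_ * p)
    quad <- 0; ld_V <- 0
    for (s in seq_len(n)) {
      Vs <- sub[[s]]$cov + Vre
      ch <- tryCatch(chol(Vs), error = function(e) NULL)
      if (is.null(ch)) return(list(F = -Inf))
      ld_V <- ld_V + 2 * sum(log(diag(ch)))
      Vi <- chol2inv(ch)
      ms <- sub[[s]]$mean
      quad <- quad + sum(ms * (Vi %*% ms))
      xs <- X[s, ]
      A_ <- A_ + kronecker(tcrossprod(xs), Vi)
      bvec <- bvec + as.numeric(kronecker(xs, Vi %*% ms))
    }
    chA <- tryCatch(chol(A_), error = function(e) NULL)
    if (is.null(chA)) return(list(F = -Inf))
    Sb <- chol2inv(chA)
    mb <- as.numeric(Sb %*% bvec)
    # log evidence of M | gamma (beta integrated out)
    Fv <- -0.5 * (n * p) * log(2 * pi) - 0.5 * ld_V - 0.5 * ld_Sb0 -
      sum(log(diag(chA))) - 0.5 * (quad - sum(bvec * mb)) +
      dnorm(gamma, gamma0, sqrt(gamma_var), log = TRUE)
    if (!want_beta) return(list(F = Fv))
    list(F = Fv, beta_mean = mb, beta_cov = Sb)
  }

  opt <- stats::optimize(function(g) -fit_gamma(g)$F, interval = c(-6, 10))
  gamma <- opt$minimum
  res <- fit_gamma(gamma, want_beta = TRUE)
  bn <- as.vector(outer(parameters, colnames(X) %||% paste0("x", 1:c_),
                        function(a, b) paste0(b, ":", a)))
  structure(list(beta_mean = stats::setNames(res$beta_mean, bn),
                 beta_cov = res$beta_cov, gamma = gamma, F = res$F,
                 X = X, parameters = parameters, beta_names = bn,
                 beta_prior_mean = stats::setNames(numeric(c_ * p), bn),
                 beta_prior_var = stats::setNames(beta_var, bn),
                 Q = Q, gamma0 = gamma0, gamma_var = gamma_var,
                 subjects = sub),
            class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat("PEB fit:", length(x$subjects), "subjects,", length(x$parameters),
      "parameters,", ncol(x$X), "design columns; F =", round(x$F, 2),
      " gamma =", round(x$gamma, 2), "\n")
  invisible(x)
}

#' Bayesian model reduction
#'
#' Analytic evidence change and posterior of a reduced model that
#' differs from the full one only in its (Gaussian) prior — no
#' refitting. With posterior precision `P`, prior precision `P0` and
#' reduced-prior precision `P0r`, the reduced posterior precision is
#' `P + P0r - P0` and the log evidence difference follows from the
#' Gaussian evidence-ratio formula.
#'
#' @param full_posterior,full_prior,reduced_prior Lists with `mean`
#'   and `cov` (or a [subject_posterior()]).
#' @return List with `delta_F` (log evidence of reduced minus full)
#'   and `posterior` (list `mean`, `cov` of the reduced posterior).
#' @export
bayesian_model_reduction <- function(full_posterior, full_prior,
                                     reduced_prior) {
  getmc <- function(x) list(m = as.numeric(x$mean), C = as.matrix(x$cov))
  q <- getmc(full_posterior); p0 <- getmc(full_prior)
  pr <- getmc(reduced_prior)
  inv_pd <- function(C) {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) {
      warning("singular covariance in BMR; adding jitter", call. = FALSE)
      ch <- chol(C + diag(1e-10 * max(diag(C)), nrow(C)))
    }
    chol2inv(ch)
  }
  P <- inv_pd(q$C); P0 <- inv_pd(p0$C); Pr0 <- inv_pd(pr$C)
  Pr <- P + Pr0 - P0
  chr <- tryCatch(chol(Pr), error = function(e) NULL)
  if (is.null(chr)) {
    warning("reduced posterior precision not positive definite; ",
            "stabilized with jitter", call. = FALSE)
    Pr <- Pr + diag(1e-8 * max(diag(Pr)), nrow(Pr))
    chr <- chol(Pr)
  }
  br <- P %*% q$m + Pr0 %*% pr$m - P0 %*% p0$m
  Sr <- chol2inv(chr)
  mr <- as.numeric(Sr %*% br)
  ld <- function(M) 2 * sum(log(diag(chol(M))))
  dF <- 0.5 * (ld(P) + ld(Pr0) - ld(P0) - ld(Pr)) -
    0.5 * (sum(q$m * (P %*% q$m)) + sum(pr$m * (Pr0 %*% pr$m)) -
           sum(p0$m * (P0 %*% p0$m)) - sum(mr * (Pr %*% mr)))
  list(delta_F = as.numeric(dF),
       posterior = list(mean = stats::setNames(mr, names(full_posterior$mean)),
                        cov = Sr))
}

# Reduced prior with the given entries switched off (shrunk to ~zero).
reduced_prior_off <- function(prior_mean, prior_var, off,
                              off_var = 1e-8) {
  v <- prior_var
  m <- prior_mean
  v[off] <- off_var
  m[off] <- 0
  list(mean = m, cov = diag(v, length(v)))
}

#' Greedy Bayesian model reduction with model averaging
#'
#' Iteratively switches off the second-level parameter whose removal
#' most increases the model evidence (via [bayesian_model_reduction()];
#' no refitting), stopping when every single removal would decrease
#' the evidence. The nested models formed by toggling the most
#' evidence-ambiguous parameters around the final set (capped at
#' `2^16` models) are then scored, the best `max_models` retained, and
#' parameters Bayesian-model-averaged over them weighted by posterior
#' model probability. A parameter is flagged present when its summed
#' weight exceeds `pp_threshold`.
#'
#' @param peb A [peb_fit()] result.
#' @param max_models Models retained for averaging.
#' @param pp_threshold Posterior probability above which a parameter
#'   counts as present.
#' @param enumerate_limit Cap on the enumerated model space (log2;
#'   the search never enumerates more than 2^16 models).
#' @return The `peb_result` augmented with `bma_mean`, `pp` (posterior
#'   probability of being present), `pruned` (switched-off parameter
#'   names), `model_F`, `model_weights` and `n_models`.
#' @export
greedy_prune_and_average <- function(peb, max_models = 256,
                                     pp_threshold = 0.95,
                                     enumerate_limit = 12L) {
  stopifnot(inherits(peb, "peb_result"))
  k <- length(peb$beta_mean)
  full_post <- list(mean = peb$beta_mean, cov = peb$beta_cov)
  full_prior <- list(mean = peb$beta_prior_mean,
                     cov = diag(peb$beta_prior_var, k))
  F_of <- function(off) {
    if (length(off) == 0) return(list(delta_F = 0,
      posterior = list(mean = peb$beta_mean, cov = peb$beta_cov)))
    bayesian_model_reduction(full_post, full_prior,
      reduced_prior_off(peb$beta_prior_mean, peb$beta_prior_var, off))
  }
  off <- integer(0)
  F_cur <- 0
  repeat {
    cand <- setdiff(seq_len(k), off)
    if (length(cand) == 0) break
    dF <- vapply(cand, function(j) F_of(c(off, j))$delta_F - F_cur,
                 numeric(1))
    best <- which.max(dF)
    if (dF[best] <= 0) break
    off <- c(off, cand[best])
    F_cur <- F_cur + dF[best]
  }

  # enumerate on/off combinations of the most ambiguous parameters
  dF_toggle <- vapply(seq_len(k), function(j) {
    off_j <- if (j %in% off) setdiff(off, j) else c(off, j)
    abs(F_of(off_j)$delta_F - F_cur)
  }, numeric(1))
  n_enum <- min(k, enumerate_limit, 16L)
  enum <- order(dF_toggle)[seq_len(n_enum)]
  fixed_off <- setdiff(off, enum)
  n_models <- 2^n_enum
  Fs <- numeric(n_models)
  model_off <- vector("list", n_models)
  for (mdl in seq_len(n_models)) {
    bits <- as.logical(bitwAnd(mdl - 1L, bitwShiftL(1L, seq_len(n_enum) - 1L)))
    model_off[[mdl]] <- c(fixed_off, enum[bits])
    Fs[mdl] <- F_of(model_off[[mdl]])$delta_F
  }
  keep <- order(Fs, decreasing = TRUE)[seq_len(min(max_models, n_models))]
  w <- exp(Fs[keep] - max(Fs[keep]))
  w <- w / sum(w)
  bma <- numeric(k)
  pp <- numeric(k)
  for (i in seq_along(keep)) {
    red <- F_of(model_off[[keep[i]]])
    mu <- red$posterior$mean
    mu[model_off[[keep[i]]]] <- 0
    bma <- bma + w[i] * mu
    on <- setdiff(seq_len(k), model_off[[keep[i]]])
    pp[on] <- pp[on] + w[i]
  }
  peb$bma_mean <- stats::setNames(bma, peb$beta_names)
  peb$pp <- stats::setNames(pp, peb$beta_names)
  peb$pruned <- peb$beta_names[off]
  peb$model_F <- Fs[keep]
  peb$model_weights <- w
  peb$n_models <- length(keep)
  peb$pp_threshold <- pp_threshold
  peb$present <- peb$pp > pp_threshold
  peb
}
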