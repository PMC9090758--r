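#' Split-half potential scale reduction factor
#'
#' Gelman-Rubin univariate PSRF per parameter and the Brooks-Gelman
#' multivariate PSRF, computed after splitting every chain into halves
#' (doubling the chain count), so that non-stationarity within chains
#' inflates the diagnostic. For a hierarchical fit the diagnostic is
#' computed over the group-level parameters. Convergence is declared
#' when the multivariate R-hat is below 1.1.
#'
#' @param samples Either an `lba_hierfit` or a 3-d array of draws with
#'   dimensions iterations x chains x parameters.
#' @param threshold Pass threshold for the multivariate PSRF.
#' @return Object of class `convergence_report`: list with
#'   `univariate` (named vector), `multivariate` (scalar R-hat),
#'   `pass`, `n` (half-chain length) and `m` (split chain count).
#' @export
psrf <- function(samples, threshold = 1.1) {
  if (inherits(samples, "lba_hierfit")) {
    draws <- samples$group_draws
  } else draws <- samples
  stopifnot(length(dim(draws)) == 3)
  n_it <- dim(draws)[1]; n_ch <- dim(draws)[2]; d <- dim(draws)[3]
  if (n_ch < 2 || n_it < 4)
    stop("psrf needs >= 2 chains and >= 4 stored iterations", call. = FALSE)
  pnames <- dimnames(draws)[[3]] %||% paste0("par", seq_len(d))

  n <- n_it %/% 2L
  m <- 2L * n_ch
  # split chains: (n, m, d)
  sp <- array(NA_real_, c(n, m, d))
  sp[, seq_len(n_ch), ] <- draws[seq_len(n), , , drop = FALSE]
  sp[, n_ch + seq_len(n_ch), ] <- draws[n_it - n + seq_len(n), , , drop = FALSE]

  ch_mean <- apply(sp, c(2, 3), mean)                  # m x d
  grand <- colMeans(ch_mean)
  W_uni <- apply(sp, c(2, 3), var)                     # m x d within variances
  W_bar <- colMeans(W_uni)
  B_n <- apply(ch_mean, 2, var)                        # = B/n
  degenerate <- W_bar <= .Machine$double.eps * pmax(1, abs(grand))^2
  if (any(degenerate))
    warning("zero within-chain variance for: ",
            paste(pnames[degenerate], collapse = ", "),
            "; reporting R-hat = 1 for these", call. = FALSE)
  sig2 <- (n - 1) / n * W_bar + B_n
  R_uni <- sqrt(pmax((m + 1) / m * sig2 / W_bar - (n - 1) / (m * n), 0))
  R_uni[degenerate] <- 1
  names(R_uni) <- pnames

  keep <- !degenerate
  if (sum(keep) == 0) {
    R_mv <- 1
  } else if (sum(keep) == 1) {
    R_mv <- unname(R_uni[keep])
  } else {
    cent <- sweep(ch_mean[, keep, drop = FALSE], 2, grand[keep])
    Bn <- crossprod(cent) / (m - 1)                    # B/n
    W <- matrix(0, sum(keep), sum(keep))
    for (j in seq_len(m)) W <- W + cov(sp[, j, keep, drop = TRUE])
    W <- W / m
    lam <- tryCatch(
      max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
      error = function(e) NA_real_)
    if (!is.finite(lam)) {
      warning("singular within-chain covariance; multivariate R-hat from ",
              "univariate maximum", call. = FALSE)
      R_mv <- max(R_uni)
    } else {
      R_mv <- sqrt((n - 1) / n + (m + 1) / m * lam)
    }
  }
  structure(list(univariate = R_uni, multivariate = R_mv,
                 pass = R_mv < threshold, n = n, m = m,
                 threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Split-half PSRF over", length(x$univariate), "parameters (",
      x$m, "split chains x", x$n, "iterations )\n")
  cat("  multivariate R-hat =", round(x$multivariate, 4),
      if (x$pass) paste0("< ", x$threshold, " [pass]")
      else paste0(">= ", x$threshold, " [fail]"), "\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws Numeric vector of posterior draws (`>= 2`).
#' @param mass Probability mass, in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 2) stop("hpdi needs at least 2 finite draws", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  w <- ceiling(mass * n)
  if (w >= n) return(c(x[1], x[n]))
  widths <- x[(w + 1):n] - x[1:(n - w)]
  i <- which.min(widths)
  c(x[i], x[i + w])
}

#' Group difference of a group-level parameter
#'
#' Pairs the thinned posterior draws of the two separately fitted
#' groups (truncated to the shorter sample, paired in stored order),
#' forms the difference `control - patient`, and summarizes it by its
#' 95% highest posterior density interval. The difference is flagged
#' significant when the interval excludes zero.
#'
#' @param post_controls,post_patients `lba_hierfit` objects (or
#'   matrices of group-level draws with named columns).
#' @param parameter Group-level parameter name, e.g.
#'   `"mu.v_true.neutral"`.
#' @param mass HPDI mass.
#' @return List of class `group_difference`: `parameter`, `delta`
#'   (paired difference draws), `mean`, `hpdi`, `significant`.
#' @export
compare_groups <- function(post_controls, post_patients, parameter,
                           mass = 0.95) {
  getdraws <- function(x) {
    m <- if (inherits(x, "lba_hierfit")) group_draw_matrix(x) else as.matrix(x)
    if (!parameter %in% colnames(m))
      stop("parameter '", parameter, "' not found in posterior", call. = FALSE)
    m[, parameter]
  }
  a <- getdraws(post_controls)
  b <- getdraws(post_patients)
  n <- min(length(a), length(b))
  delta <- a[seq_len(n)] - b[seq_len(n)]
  ci <- hpdi(delta, mass)
  structure(list(parameter = parameter, delta = delta, mean = mean(delta),
                 hpdi = ci, mass = mass,
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "group_difference")
}

#' @export
print.group_difference <- function(x, ...) {
  cat(sprintf("Delta(%s) = %.3f, %d%% HPDI [%.3f, %.3f]%s\n", x$parameter,
              x$mean, round(100 * x$mass), x$hpdi[1], x$hpdi[2],
              if (x$significant) "  *" else ""))
  invisible(x)
}

# WAIC from a draws x trials pointwise log-likelihood matrix.
waic_from_pointwise <- function(ll) {
  n <- ncol(ll); ns <- nrow(ll)
  lppd_i <- apply(ll, 2, log_sum_exp) - log(ns)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  list(elpd = sum(elpd_i), se = sqrt(n * var(elpd_i)), pointwise = elpd_i,
       p_waic = sum(p_i))
}

#' ELPD model comparison (WAIC)
#'
#' Estimates the expected log pointwise predictive density of each
#' fitted variant by WAIC from the stored pointwise log-likelihoods
#' and ranks the variants; the winner has the maximal ELPD. Pairwise
#' differences against the winner are reported with the standard error
#' of the paired pointwise differences.
#'
#' @param fits Named list of `lba_hierfit` objects fitted to the same
#'   trials.
#' @return Object of class `model_comparison`: data frame `table` with
#'   columns `model`, `elpd`, `se`, `delta_elpd`, `delta_se`, plus
#'   `winner` and `ranking`.
#' @export
elpd_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$variant$name, character(1))
  pw <- lapply(fits, function(f) {
    if (is.null(f$pointwise))
      stop("fit has no stored pointwise log-likelihood; rerun with ",
           "store_loglik = TRUE", call. = FALSE)
    f$pointwise
  })
  ntr <- vapply(pw, ncol, integer(1))
  if (length(unique(ntr)) != 1)
    stop("fits were not computed on identical trial sets", call. = FALSE)
  w <- lapply(pw, waic_from_pointwise)
  elpd <- vapply(w, `[[`, numeric(1), "elpd")
  se <- vapply(w, `[[`, numeric(1), "se")
  ord <- order(elpd, decreasing = TRUE)
  winner <- names(fits)[ord[1]]
  dse <- delpd <- numeric(length(fits))
  for (i in seq_along(fits)) {
    di <- w[[ord[1]]]$pointwise - w[[i]]$pointwise
    delpd[i] <- elpd[i] - elpd[ord[1]]
    dse[i] <- sqrt(length(di) * var(di))
  }
  tab <- data.frame(model = names(fits), elpd = elpd, se = se,
                    delta_elpd = delpd, delta_se = dse,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, winner = winner, ranking = tab$model),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("ELPD (WAIC) model comparison; winner:", x$winner, "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Posterior-predictive cohort simulation
#'
#' Simulates a large synthetic cohort from the fitted group-level
#' posteriors: for each synthetic subject one stored group-level draw
#' is selected, subject parameters are drawn from the group
#' distribution, and a session is simulated. Defaults follow the
#' validation design: 1000 subjects per group with 20 trials per
#' condition.
#'
#' @param group_fits Named list with `lba_hierfit` elements `control`
#'   and `MDD`.
#' @param n_per_group Synthetic subjects per group.
#' @param trials_per_condition Trials per condition per subject.
#' @param seed Integer seed; subject-level seeds derive
#'   deterministically from it.
#' @return Trial table for the full cohort (class `data.frame`), with
#'   attribute `"generating_draw"` recording the group-level draw index
#'   per subject.
#' @export
posterior_predictive_cohort <- function(group_fits, n_per_group = 1000,
                                        trials_per_condition = 20, seed = 1) {
  stopifnot(all(c("control", "MDD") %in% names(group_fits)))
  local_rng(seed)
  out <- vector("list", 2 * n_per_group)
  idx <- integer(2 * n_per_group)
  i <- 0L
  for (grp in c("control", "MDD")) {
    fit <- group_fits[[grp]]
    gm <- group_draw_matrix(fit)
    d <- fit$variant$n_subject_params
    design <- session_design(
      blocks_per_condition = max(1L, trials_per_condition %/% 5L),
      trials_per_block = if (trials_per_condition %% 5L == 0L) 5L
                         else trials_per_condition,
      seed = derive_seed(seed, 7))
    for (s in seq_len(n_per_group)) {
      i <- i + 1L
      idx[i] <- sample.int(nrow(gm), 1)
      mu <- gm[idx[i], seq_len(d)]
      sig <- gm[idx[i], d + seq_len(d)]
      x <- rnorm(d, mu, sig)
      pars <- variant_to_params(x, fit$variant)
      out[[i]] <- simulate_trials(
        pars, design, seed = derive_seed(seed, i),
        subject_id = sprintf("ppc-%s-%03d", grp, s), group = grp)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "generating_draw") <- idx
  res
}

#' Subsample a posterior-predictive cohort to the study size
#'
#' Randomly selects 33 synthetic controls and 30 synthetic patients
#' (the empirical group sizes) from a posterior-predictive cohort for
#' the mixed-model check.
#'
#' @param trials Trial table from [posterior_predictive_cohort()].
#' @param n_controls,n_patients Subjects to keep per group.
#' @param seed Integer seed.
#' @return Trial table restricted to the sampled subjects.
#' @export
subsample_cohort <- function(trials, n_controls = 33, n_patients = 30,
                             seed = 1) {
  local_rng(seed)
  pick <- function(grp, n) {
    ids <- unique(trials$subject_id[trials$group == grp])
    if (length(ids) < n) stop("not enough ", grp, " subjects", call. = FALSE)
    sample(ids, n)
  }
  keep <- c(pick("control", n_controls), pick("MDD", n_patients))
  trials[trials$subject_id %in% keep, , drop = FALSE]
}
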