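# Leave-one-out cross-validated diagnosis classification: the roles of the
# second-level group predictor and the first-level connectivity estimates
# are swapped — the PEB model fitted to all other subjects yields a
# posterior-predictive density of the held-out subject's connectivity under
# either group label, from which the posterior belief about the label
# follows by Bayes' rule with a flat label prior.

#' Area under the ROC curve (Mann-Whitney)
#'
#' Pairwise-concordance AUC: the proportion of (positive, negative)
#' score pairs ranked correctly, ties counting one half.
#'
#' @param scores Numeric classification scores.
#' @param labels Logical or 0/1 vector; `TRUE`/1 = positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

# Stratified bootstrap CI of the AUC.
auc_boot_ci <- function(scores, labels, level = 0.95, n_boot = 2000,
                        seed = 1) {
  local_rng(seed)
  labels <- as.logical(labels)
  i1 <- which(labels); i0 <- which(!labels)
  reps <- vapply(seq_len(n_boot), function(b) {
    j <- c(sample(i1, length(i1), replace = TRUE),
           sample(i0, length(i0), replace = TRUE))
    auc_mann_whitney(scores[j], labels[j])
  }, numeric(1))
  unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Leave-one-out cross-validated group classification
#'
#' For each subject in turn, fits the PEB model (including the group
#' column and all nuisance covariates) to the remaining subjects and
#' evaluates the posterior-predictive probability of the held-out
#' subject's group label from their connectivity estimates. The
#' probability list yields the ROC curve and the Mann-Whitney AUC with
#' a stratified-bootstrap confidence interval.
#'
#' @param posteriors List of [subject_posterior()] objects.
#' @param X Design matrix containing the group column (see
#'   [peb_design()]).
#' @param group_col Name or index of the group column of `X`.
#' @param parameters First-level parameters used for prediction
#'   (default all).
#' @param level Confidence level of the AUC interval.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @param ... Passed to [peb_fit()] for each fold.
#' @return Object of class `loocv_result`: `prob` (per-subject
#'   probability of the patient class), `truth`, `auc`, `ci`, `roc`,
#'   `failed` (subjects skipped because a fold did not fit).
#' @export
loocv_classify <- function(posteriors, X, group_col = "group",
                           parameters = NULL, level = 0.95, n_boot = 2000,
                           seed = 1, ...) {
  X <- as.matrix(X)
  n <- length(posteriors)
  stopifnot(nrow(X) == n)
  gi <- if (is.character(group_col)) match(group_col, colnames(X))
        else as.integer(group_col)
  if (is.na(gi)) stop("group column not found in X", call. = FALSE)
  gvals <- sort(unique(X[, gi]))
  if (length(gvals) != 2)
    stop("group column must have exactly 2 levels", call. = FALSE)
  if (min(table(X[, gi])) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  parameters <- parameters %||% names(posteriors[[1]]$mean)
  p <- length(parameters)

  prob <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    # re-center the fold's covariates and shift the held-out row (and
    # the candidate group codes) by the same fold means
    foldX <- X[-i, , drop = FALSE]
    cm <- if (ncol(X) >= 2) colMeans(foldX[, -1, drop = FALSE]) else numeric(0)
    if (length(cm)) foldX[, -1] <- sweep(foldX[, -1, drop = FALSE], 2, cm)
    xtest <- X[i, ]
    if (length(cm)) xtest[-1] <- xtest[-1] - cm
    gshift <- if (gi > 1) cm[gi - 1] else 0
    fold <- tryCatch(
      peb_fit(posteriors[-i], foldX, parameters = parameters, ...),
      error = function(e) NULL)
    if (is.null(fold)) { failed <- c(failed, i); next }
    test <- subset_posterior(posteriors[[i]], parameters)
    Vre <- exp(-fold$gamma) * fold$Q
    loglik_g <- vapply(gvals - gshift, function(g) {
      xs <- xtest
      xs[gi] <- g
      mu <- as.numeric(kronecker(t(xs), diag(1, p)) %*% fold$beta_mean)
      Zt <- kronecker(t(xs), diag(1, p))
      Vt <- test$cov + Vre + Zt %*% fold$beta_cov %*% t(Zt)
      ch <- chol((Vt + t(Vt)) / 2)
      d <- test$mean - mu
      z <- backsolve(ch, d, transpose = TRUE)
      -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
    }, numeric(1))
    # flat prior over the two labels; gvals[2] is the higher (patient) code
    prob[i] <- 1 / (1 + exp(loglik_g[1] - loglik_g[2]))
  }
  ok <- !is.na(prob)
  truth <- X[, gi] == gvals[2]
  auc <- auc_mann_whitney(prob[ok], truth[ok])
  ci <- auc_boot_ci(prob[ok], truth[ok], level = level, n_boot = n_boot,
                    seed = seed)
  structure(list(prob = prob, truth = truth, auc = auc, ci = ci,
                 roc = roc_curve(prob[ok], truth[ok]),
                 failed = failed, level = level),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV classification: AUC = %.3f, %d%% CI [%.3f, %.3f]",
              x$auc, round(100 * x$level), x$ci[1], x$ci[2]))
  if (length(x$failed)) cat(" (", length(x$failed), "folds failed )")
  cat("\n")
  invisible(x)
}
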