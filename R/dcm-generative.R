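# Four-region bilinear DCM of the prefrontal-amygdala face-processing
# network, regions fixed as (FFA, LPFC, sgACC, AMY). Neural dynamics
#   dz/dt = (A~ + u_pos B_pos + u_neg B_neg) z + C u
# where A~ equals A off the diagonal and -0.5 * exp(A_ii) on it (the
# log-scaling self-connection convention: lower diagonal parameter =
# weaker self-decay = more excitable region). BOLD arises from the
# balloon-Windkessel hemodynamics per region.

.dcm_regions <- c("FFA", "LPFC", "sgACC", "AMY")

#' Region labels of the prefrontal-amygdala DCM
#' @return Character vector `c("FFA", "LPFC", "sgACC", "AMY")`.
#' @export
dcm_regions <- function() .dcm_regions

#' DCM specification (A/B/C matrices)
#'
#' @param A 4x4 intrinsic coupling matrix: off-diagonal entries in Hz,
#'   diagonal entries unitless log-scaling parameters of the -0.5 Hz
#'   self-decay (effective self-connection `-0.5 * exp(A_ii)`).
#' @param B_pos,B_neg 4x4 modulatory matrices (Hz) for positive and
#'   negative valence; diagonals must be zero (modulation acts on
#'   interregional connections only).
#' @param C 4x3 driving-input weights; only the (FFA, all-faces) entry
#'   may be nonzero. A scalar is accepted as that entry.
#' @return Object of class `dcm_spec`.
#' @export
dcm_spec <- function(A = matrix(0, 4, 4), B_pos = matrix(0, 4, 4),
                     B_neg = matrix(0, 4, 4), C = 0.3) {
  as4 <- function(M, nm) {
    M <- as.matrix(M)
    if (!all(dim(M) == c(4, 4)))
      stop("'", nm, "' must be a 4x4 matrix", call. = FALSE)
    dimnames(M) <- list(.dcm_regions, .dcm_regions)
    M
  }
  A <- as4(A, "A"); B_pos <- as4(B_pos, "B_pos"); B_neg <- as4(B_neg, "B_neg")
  if (any(diag(B_pos) != 0) || any(diag(B_neg) != 0))
    stop("modulatory matrices must have zero diagonals", call. = FALSE)
  if (length(C) == 1) {
    Cm <- matrix(0, 4, 3)
    Cm[1, 1] <- C
  } else {
    Cm <- as.matrix(C)
    if (!all(dim(Cm) == c(4, 3)))
      stop("'C' must be 4x3 (regions x input channels)", call. = FALSE)
    if (any(Cm[-1, ] != 0) || any(Cm[1, -1] != 0))
      stop("only the (FFA, all-faces) entry of 'C' may be nonzero",
           call. = FALSE)
  }
  dimnames(Cm) <- list(.dcm_regions, c("faces", "positive", "negative"))
  structure(list(A = A, B_pos = B_pos, B_neg = B_neg, C = Cm),
            class = "dcm_spec")
}

# Effective coupling matrix: A off the diagonal, -0.5*exp(a_ii) on it.
effective_A <- function(A) {
  At <- A
  diag(At) <- -0.5 * exp(diag(A))
  At
}

#' Neural drift of the bilinear model
#'
#' `dz/dt = (A~ + u_pos B_pos + u_neg B_neg) z + C u` with the
#' self-connection convention described in [dcm_spec()].
#'
#' @param z Neural state, length 4.
#' @param u Input vector, length 3 (all-faces drive, positive
#'   modulator, negative modulator).
#' @param spec A [dcm_spec()].
#' @return Length-4 derivative (Hz).
#' @export
neural_drift <- function(z, u, spec) {
  stopifnot(inherits(spec, "dcm_spec"), length(z) == 4, length(u) == 3,
            all(is.finite(z)), all(is.finite(u)))
  J <- effective_A(spec$A) + u[2] * spec$B_pos + u[3] * spec$B_neg
  as.numeric(J %*% z + spec$C %*% u)
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Standard constants of the hemodynamic forward model: vasodilatory
#' signal decay `kappa`, flow feedback `gamma_h`, transit time `tau`,
#' Grubb exponent `alpha`, resting oxygen extraction `E0`, resting
#' venous volume fraction `V0`, and BOLD observation constants
#' `k1 = 7 E0`, `k2`, `k3`.
#'
#' @param kappa,gamma_h Rates (1/s).
#' @param tau Mean transit time (s); scalar or one per region.
#' @param alpha Grubb exponent, in (0, 1).
#' @param E0 Resting oxygen extraction fraction, in (0, 1).
#' @param V0,k1,k2,k3 Observation constants.
#' @return Object of class `hemo_params`.
#' @export
hemo_params <- function(kappa = 0.64, gamma_h = 0.32, tau = 2.0,
                        alpha = 0.32, E0 = 0.4, V0 = 0.04,
                        k1 = 7 * E0, k2 = 1.6, k3 = 1 - 1.5 * E0) {
  vals <- c(kappa = kappa, gamma_h = gamma_h, alpha = alpha, E0 = E0,
            V0 = V0, k1 = k1, k2 = k2, k3 = k3)
  if (any(!is.finite(c(vals, tau))) || any(c(kappa, gamma_h, tau, V0) <= 0))
    stop("hemodynamic constants must be positive and finite", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (E0 <= 0 || E0 >= 1) stop("E0 must be in (0, 1)", call. = FALSE)
  tau <- rep(as.numeric(tau), length.out = 4)
  structure(list(kappa = kappa, gamma_h = gamma_h, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0, k1 = k1, k2 = k2, k3 = k3),
            class = "hemo_params")
}

#' Hemodynamic state derivatives
#'
#' Balloon-Windkessel equations for one region: vasodilatory signal
#' `s`, blood inflow `f`, venous volume `nu`, deoxyhemoglobin `q`.
#' The resting point `(0, 1, 1, 1)` with `z = 0` is a fixed point.
#'
#' @param h State vector `c(s, f, nu, q)` with `f, nu, q > 0`.
#' @param z Neural activity of the region.
#' @param p A [hemo_params()] (the first transit time is used).
#' @return Derivative vector `c(ds, df, dnu, dq)`.
#' @export
hemo_drift <- function(h, z, p) {
  stopifnot(inherits(p, "hemo_params"), length(h) == 4)
  s <- h[1]; f <- h[2]; nu <- h[3]; q <- h[4]
  if (f <= 0 || nu <= 0 || q <= 0)
    stop("hemodynamic states f, nu, q must stay positive", call. = FALSE)
  tau <- p$tau[1]
  fout <- nu^(1 / p$alpha)
  Ef <- 1 - (1 - p$E0)^(1 / f)
  c(z - p$kappa * s - p$gamma_h * (f - 1),
    s,
    (f - fout) / tau,
    (f * Ef / p$E0 - fout * q / nu) / tau)
}

#' BOLD observation equation
#'
#' `y = V0 * (k1 (1 - q) + k2 (1 - q / nu) + k3 (1 - nu))`; zero at the
#' resting state `nu = q = 1`.
#'
#' @param nu Venous volume (normalized), `> 0`.
#' @param q Deoxyhemoglobin content (normalized), `> 0`.
#' @param p A [hemo_params()].
#' @return BOLD signal value(s).
#' @export
bold_observe <- function(nu, q, p) {
  stopifnot(inherits(p, "hemo_params"), all(nu > 0), all(q > 0))
  p$V0 * (p$k1 * (1 - q) + p$k2 * (1 - q / nu) + p$k3 * (1 - nu))
}

#' Build the three DCM input channels from task events
#'
#' Channel 1 is the union of boxcars over all face trials (positive,
#' negative, neutral), mean-centered over the session; channels 2 and
#' 3 are unit boxcars over positive and negative trials (not
#' centered). Shapes trials drive no channel.
#'
#' @param events Data frame with `onset`, `duration` (seconds) and
#'   `condition` columns.
#' @param micro_dt Sampling step of the input series (s).
#' @param total_time Session length in seconds.
#' @return Matrix `n_micro x 3` with columns `faces`, `positive`,
#'   `negative`.
#' @export
build_task_inputs <- function(events, micro_dt = 0.1,
                              total_time = 335 * 1.6) {
  stopifnot(all(c("onset", "duration", "condition") %in% names(events)))
  n <- ceiling(total_time / micro_dt) + 1L
  tgrid <- (seq_len(n) - 1L) * micro_dt
  box <- function(conds) {
    on <- rep(FALSE, n)
    ev <- events[events$condition %in% conds, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      sel <- tgrid >= ev$onset[i] & tgrid < ev$onset[i] + ev$duration[i]
      if (any(on & sel))
        warning("overlapping events; using union of boxcars", call. = FALSE)
      on <- on | sel
    }
    as.numeric(on)
  }
  faces <- box(c("positive", "negative", "neutral"))
  U <- cbind(faces = faces - mean(faces),
             positive = box("positive"), negative = box("negative"))
  attr(U, "micro_dt") <- micro_dt
  U
}

#' Simulate a BOLD session from the DCM
#'
#' Integrates the neural and hemodynamic ODEs with a fixed-step RK4 at
#' micro-time resolution, samples the BOLD observation at mid-volume
#' times, and adds white Gaussian noise. Deterministic given the seed.
#'
#' @param spec A [dcm_spec()].
#' @param hemo A [hemo_params()].
#' @param events Task events (see [build_task_inputs()]), or a
#'   prebuilt input matrix via `inputs`.
#' @param TR Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param noise_sd SD of additive measurement noise.
#' @param noise_ar Lag-1 autocorrelation of the noise (0 = white; an
#'   AR(1) process with this coefficient and stationary SD `noise_sd`
#'   otherwise).
#' @param micro_dt Integration step; must be at most `TR / 16`.
#' @param seed Integer seed for the noise.
#' @param inputs Optional precomputed input matrix (overrides
#'   `events`).
#' @param return_neural Also return the neural micro-time trajectory.
#' @return Object of class `bold_session`: list with `bold` (4 x
#'   n_volumes matrix, rows named by region), `TR`, `n_volumes`,
#'   `micro_dt`, `noise_sd`, `seed`, and optionally `neural`.
#' @export
simulate_session <- function(spec, hemo = hemo_params(), events = NULL,
                             TR = 1.6, n_volumes = 335, noise_sd = 0,
                             noise_ar = 0, micro_dt = TR / 16, seed = 1,
                             inputs = NULL, return_neural = FALSE) {
  stopifnot(inherits(spec, "dcm_spec"), inherits(hemo, "hemo_params"))
  if (micro_dt > TR / 16 + 1e-12)
    stop("micro_dt must be at most TR / 16", call. = FALSE)
  if (is.null(inputs)) {
    if (is.null(events)) {
      inputs <- matrix(0, ceiling(n_volumes * TR / micro_dt) + 1L, 3)
    } else {
      inputs <- build_task_inputs(events, micro_dt, n_volumes * TR)
    }
  }
  sim <- cpp_dcm_simulate(spec$A, spec$B_pos, spec$B_neg, spec$C,
                          inputs, micro_dt, as.integer(n_volumes), TR,
                          hemo$kappa, hemo$gamma_h, hemo$tau, hemo$alpha,
                          hemo$E0, hemo$V0, hemo$k1, hemo$k2, hemo$k3,
                          return_neural)
  if (!isTRUE(sim$ok))
    stop("DCM integration became unstable (|state| > 1e6); check the ",
         "A matrix of the specification", call. = FALSE)
  bold <- sim$bold
  rownames(bold) <- .dcm_regions
  if (noise_sd > 0) {
    local_rng(seed)
    if (noise_ar != 0) {
      stopifnot(abs(noise_ar) < 1)
      innov_sd <- noise_sd * sqrt(1 - noise_ar^2)
      noise <- t(vapply(1:4, function(r) {
        as.numeric(stats::filter(rnorm(n_volumes, 0, innov_sd),
                                 noise_ar, method = "recursive"))
      }, numeric(n_volumes)))
    } else {
      noise <- matrix(rnorm(length(bold), 0, noise_sd), nrow = 4)
    }
    bold <- bold + noise
  }
  out <- list(bold = bold, TR = TR, n_volumes = as.integer(n_volumes),
              micro_dt = micro_dt, noise_sd = noise_sd,
              noise_ar = noise_ar, seed = seed)
  if (return_neural) out$neural <- sim$neural
  structure(out, class = "bold_session")
}
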