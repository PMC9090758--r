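#' Linear ballistic accumulator parameter set
#'
#' Bundles the subject-level parameters of the two-accumulator LBA used
#' for the face-matching task. The accumulators are accuracy coded: one
#' matches the correct response (drift mean `v_true`, trial-to-trial
#' drift SD `sv_true`), the other mismatches (drift mean `v_false`,
#' drift SD fixed at 1 for identifiability). The response threshold is
#' `b = A + B`, where `A` is the start-point range and `B` the excursion
#' above it; `t0` is the non-decision time.
#'
#' `v_true`, `v_false` and `B` may be given either as a single shared
#' value or as one value per condition (`positive`, `negative`,
#' `neutral`, `shapes`); shared values are recycled across conditions.
#'
#' @param A Start-point range (evidence units, `>= 0`).
#' @param B Threshold excursion above `A` (`> 0`); scalar or length 4.
#' @param t0 Non-decision time in seconds (`>= 0`).
#' @param v_true Mean drift of the matching accumulator; scalar or
#'   length 4.
#' @param v_false Mean drift of the mismatching accumulator; scalar or
#'   length 4.
#' @param sv_true Trial-to-trial drift SD of the matching accumulator
#'   (`> 0`).
#' @return An object of class `lba_params`: a list with fields `A`,
#'   `B`, `t0`, `v_true`, `v_false`, `sv_true` (condition-indexed fields
#'   expanded to named length-4 vectors) and `sv_false = 1`.
#' @examples
#' p <- lba_params(A = 0.5, B = 0.5, t0 = 0.3,
#'                 v_true = c(2.2, 2.0, 1.4, 2.4), v_false = 0.8)
#' p$v_true[["neutral"]]
#' @export
lba_params <- function(A, B, t0, v_true, v_false, sv_true = 1) {
  chk_num <- function(x, nm, len_ok = 1L) {
    if (!is.numeric(x) || !all(is.finite(x)))
      stop("parameter '", nm, "' must be finite numeric", call. = FALSE)
    x
  }
  expand4 <- function(x, nm) {
    x <- chk_num(x, nm)
    if (length(x) == 1L) x <- rep(x, 4L)
    if (length(x) != 4L)
      stop("parameter '", nm, "' must have length 1 or 4", call. = FALSE)
    stats::setNames(as.numeric(x), .cond_levels)
  }
  A <- chk_num(A, "A"); t0 <- chk_num(t0, "t0"); sv_true <- chk_num(sv_true, "sv_true")
  if (A < 0) stop("parameter 'A' must be >= 0", call. = FALSE)
  if (t0 < 0) stop("parameter 't0' must be >= 0", call. = FALSE)
  if (sv_true <= 0) stop("parameter 'sv_true' must be > 0", call. = FALSE)
  B <- expand4(B, "B")
  if (any(B <= 0)) stop("parameter 'B' must be > 0", call. = FALSE)
  structure(list(A = as.numeric(A), B = B, t0 = as.numeric(t0),
                 v_true = expand4(v_true, "v_true"),
                 v_false = expand4(v_false, "v_false"),
                 sv_true = as.numeric(sv_true), sv_false = 1),
            class = "lba_params")
}

#' Condition-dependence variants of the LBA
#'
#' Describes which subject-level parameters vary over the four task
#' conditions under each model variant: `M_v` lets both drift means
#' (`v_true`, `v_false`) vary by condition with a shared threshold,
#' `M_B` lets the threshold excursion `B` vary with shared drifts, and
#' `M_null` shares everything. `A`, `t0` and `sv_true` are always
#' shared.
#'
#' @param name One of `"M_v"`, `"M_B"`, `"M_null"`.
#' @return A list of class `lba_variant` with elements `name`,
#'   `varies` (character vector of condition-varying fields),
#'   `par_names` (subject-parameter labels on the sampling scale),
#'   `n_subject_params`, and `n_chains` (three times the parameter
#'   count, the chain rule used for sampling).
#' @examples
#' model_variant("M_v")$n_chains  # 36
#' @export
model_variant <- function(name = c("M_v", "M_B", "M_null")) {
  name <- match.arg(name)
  varies <- switch(name,
    M_v = c("v_true", "v_false"),
    M_B = "B",
    M_null = character(0))
  nm <- function(field) {
    if (field %in% varies) paste0(field, ".", .cond_levels) else field
  }
  par_names <- c(nm("v_true"), nm("v_false"),
                 paste0("log_", nm("A")), paste0("log_", if ("B" %in% varies)
                   paste0("B.", .cond_levels) else "B"),
                 "log_t0", "log_sv_true")
  # A is never condition dependent; drop any accidental suffixing
  par_names <- sub("^log_A$", "log_A", par_names)
  d <- length(par_names)
  structure(list(name = name, varies = varies, par_names = par_names,
                 n_subject_params = d, n_chains = 3L * d),
            class = "lba_variant")
}

# Map a sampling-scale parameter vector (named per variant) to lba_params.
variant_to_params <- function(x, variant) {
  stopifnot(length(x) == variant$n_subject_params)
  names(x) <- variant$par_names
  pick <- function(field, log_scale = FALSE) {
    pref <- if (log_scale) paste0("log_", field) else field
    if (field %in% variant$varies) {
      v <- x[paste0(pref, ".", .cond_levels)]
    } else {
      v <- x[[pref]]
    }
    if (log_scale) exp(v) else v
  }
  lba_params(A = pick("A", TRUE), B = pick("B", TRUE),
             t0 = pick("t0", TRUE),
             v_true = unname(pick("v_true")), v_false = unname(pick("v_false")),
             sv_true = pick("sv_true", TRUE))
}

# Inverse of variant_to_params: lba_params -> sampling-scale vector.
params_to_variant <- function(p, variant) {
  take <- function(field, log_scale = FALSE) {
    v <- p[[field]]
    if (!(field %in% variant$varies)) v <- v[1]
    if (log_scale) log(v) else v
  }
  x <- c(take("v_true"), take("v_false"), log(p$A), take("B", TRUE),
         log(max(p$t0, 1e-6)), log(p$sv_true))
  stats::setNames(as.numeric(x), variant$par_names)
}

# Expand a matrix of sampling-scale parameter vectors (rows = chains) to the
# natural-scale blocks the C++ likelihood kernel expects.
expand_chain_params <- function(theta, variant) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  colnames(theta) <- variant$par_names
  grab <- function(field, log_scale = FALSE) {
    pref <- if (log_scale) paste0("log_", field) else field
    if (field %in% variant$varies) {
      m <- theta[, paste0(pref, ".", .cond_levels), drop = FALSE]
    } else {
      m <- matrix(theta[, pref], nrow = nrow(theta), ncol = 4)
    }
    if (log_scale) exp(m) else m
  }
  A <- exp(theta[, "log_A"])
  list(A = A,
       b = grab("B", TRUE) + A,   # threshold = A + B, recycled columnwise
       t0 = exp(theta[, "log_t0"]),
       sv = exp(theta[, "log_sv_true"]),
       vt = grab("v_true"),
       vf = grab("v_false"))
}
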