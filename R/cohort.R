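# Synthetic study generator: behavioral trials, BOLD sessions and
# covariates for a cohort with the statistical structure the analysis
# assumes (33 controls / 30 patients; 80 trials per subject; 335 volumes at
# TR 1.6 s; group gap on the neutral drift rate; group deltas on the
# FFA-LPFC-sgACC-amygdala couplings; SSRI effect on the sgACC
# self-connection).

default_dcm_base <- function() {
  rg <- .dcm_regions
  A <- matrix(0, 4, 4, dimnames = list(rg, rg))
  # feedforward couplings excitatory, feedback/top-down inhibitory (the
  # canonical hierarchy; an all-excitatory network would sit near
  # criticality and is not what empirical effective-connectivity studies
  # report)
  A["LPFC", "FFA"] <- 0.30; A["FFA", "LPFC"] <- -0.15
  A["sgACC", "FFA"] <- 0.15; A["FFA", "sgACC"] <- -0.05
  A["AMY", "FFA"] <- 0.25; A["FFA", "AMY"] <- -0.10
  A["sgACC", "LPFC"] <- 0.20; A["LPFC", "sgACC"] <- -0.10
  A["AMY", "LPFC"] <- -0.15; A["LPFC", "AMY"] <- 0.10
  A["AMY", "sgACC"] <- -0.20; A["sgACC", "AMY"] <- 0.15
  Bp <- matrix(0, 4, 4, dimnames = list(rg, rg))
  Bn <- Bp
  # common valence modulations of the amygdala efferents and the
  # FFA/LPFC -> sgACC couplings
  Bp["FFA", "AMY"] <- -0.434; Bn["FFA", "AMY"] <- -0.26
  Bp["LPFC", "AMY"] <- -0.121; Bn["LPFC", "AMY"] <- -0.174
  Bp["sgACC", "AMY"] <- -0.308; Bn["sgACC", "AMY"] <- -0.127
  Bp["sgACC", "FFA"] <- 0.228; Bn["sgACC", "FFA"] <- 0.095
  Bp["sgACC", "LPFC"] <- -0.186
  Bp["AMY", "sgACC"] <- 0.291
  list(A = A, B_pos = Bp, B_neg = Bn, C = 0.4)
}

#' Cohort configuration
#'
#' All generating quantities of the synthetic study. Defaults
#' reproduce the study conditions: group sizes 33/30; control
#' group-level drift means ordered positive > negative > neutral for
#' faces (so responses are fastest for positive and slowest for
#' neutral faces); a `neutral_gap` lowering the patients' neutral
#' matching drift; connectivity deltas on the FFA-LPFC, LPFC-sgACC and
#' sgACC-amygdala couplings (patient minus control, Hz); an SSRI delta
#' on the sgACC self-connection (log-scaling units); and demographic
#' covariates matched between groups.
#'
#' @param n_controls,n_patients Group sizes.
#' @param lba_mu Named group-level means (control group) on the
#'   sampling scale, ordered as `model_variant("M_v")$par_names`.
#' @param lba_sigma Group-level SDs, same order.
#' @param neutral_gap Control-minus-patient gap on the neutral
#'   matching drift.
#' @param dcm_base List with base `A`, `B_pos`, `B_neg`, `C`.
#' @param dcm_group_delta Patient-minus-control deltas, named
#'   `A.to.from`.
#' @param ssri_delta SSRI effect on the sgACC diagonal log-scaling
#'   parameter.
#' @param dcm_subject_sd Between-subject SD of every free A/B entry.
#' @param bold_noise_sd Measurement noise SD of the BOLD signal.
#' @param ssri_rate SSRI probability among patients.
#' @param male_rate,right_handed_rate Length-2 (control, patient)
#'   probabilities.
#' @param age_mean,age_sd Length-2 (control, patient) age moments.
#' @param response_window Behavioral censoring limit (s).
#' @param TR,n_volumes Scan geometry.
#' @param seed Master seed; all subject-level seeds derive from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 33, n_patients = 30,
                          lba_mu = NULL, lba_sigma = NULL,
                          neutral_gap = 0.14,
                          dcm_base = default_dcm_base(),
                          dcm_group_delta = c("A.LPFC.FFA" = -0.033,
                                              "A.FFA.LPFC" = -0.085,
                                              "A.sgACC.LPFC" = 0.054,
                                              "A.LPFC.sgACC" = -0.036,
                                              "A.AMY.sgACC" = -0.035),
                          ssri_delta = -0.145,
                          dcm_subject_sd = 0.03,
                          bold_noise_sd = 0.005,
                          ssri_rate = 0.6,
                          male_rate = c(0.30, 0.33),
                          right_handed_rate = c(0.97, 0.93),
                          age_mean = c(16.2, 16.1), age_sd = c(1.9, 1.4),
                          response_window = 5, TR = 1.6, n_volumes = 335,
                          seed = 1) {
  variant <- model_variant("M_v")
  if (is.null(lba_mu)) {
    lba_mu <- c(2.2, 2.0, 1.4, 2.4,          # v_true: pos, neg, neu, shapes
                0.6, 0.7, 1.0, 0.5,          # v_false
                log(0.5), log(0.7), log(0.3), log(0.6))
    names(lba_mu) <- variant$par_names
  }
  if (is.null(lba_sigma)) {
    lba_sigma <- c(rep(0.2, 8), rep(0.15, 4))
    names(lba_sigma) <- variant$par_names
  }
  stop_fields(n_controls < 2 || n_patients < 2,
              "invalid config field 'n_controls'/'n_patients': need >= 2 per group")
  stop_fields(any(lba_sigma <= 0), "invalid config field 'lba_sigma': SDs must be > 0")
  stop_fields(dcm_subject_sd <= 0, "invalid config field 'dcm_subject_sd': must be > 0")
  stop_fields(bold_noise_sd < 0, "invalid config field 'bold_noise_sd': must be >= 0")
  stop_fields(ssri_rate < 0 || ssri_rate > 1,
              "invalid config field 'ssri_rate': must be in [0, 1]")
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 variant = variant, lba_mu = lba_mu, lba_sigma = lba_sigma,
                 neutral_gap = neutral_gap, dcm_base = dcm_base,
                 dcm_group_delta = dcm_group_delta, ssri_delta = ssri_delta,
                 dcm_subject_sd = dcm_subject_sd,
                 bold_noise_sd = bold_noise_sd, ssri_rate = ssri_rate,
                 male_rate = male_rate,
                 right_handed_rate = right_handed_rate,
                 age_mean = age_mean, age_sd = age_sd,
                 response_window = response_window, TR = TR,
                 n_volumes = n_volumes, seed = seed),
            class = "cohort_config")
}

# Add subject-level variability (and group/SSRI deltas) to the base spec.
subject_dcm_spec <- function(config, is_patient, ssri) {
  base <- config$dcm_base
  A <- base$A; Bp <- base$B_pos; Bn <- base$B_neg
  offd <- !diag(4)
  A[offd] <- A[offd] + rnorm(12, 0, config$dcm_subject_sd)
  diag(A) <- diag(A) + rnorm(4, 0, config$dcm_subject_sd)
  Bp[offd] <- Bp[offd] + rnorm(12, 0, config$dcm_subject_sd)
  Bn[offd] <- Bn[offd] + rnorm(12, 0, config$dcm_subject_sd)
  if (is_patient) {
    for (nm in names(config$dcm_group_delta)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      A[parts[2], parts[3]] <- A[parts[2], parts[3]] +
        config$dcm_group_delta[[nm]]
    }
    if (ssri) A["sgACC", "sgACC"] <- A["sgACC", "sgACC"] + config$ssri_delta
  }
  dcm_spec(A = A, B_pos = Bp, B_neg = Bn, C = base$C)
}

#' Generate a synthetic cohort
#'
#' Draws covariates and generating parameters for every subject, then
#' simulates the behavioral session (via the LBA race) and the BOLD
#' session (via the DCM forward model) from the same randomized
#' session design. Regenerating with the same configuration (which
#' includes the master seed) is bit-identical, and all generating
#' parameters are stored as ground truth.
#'
#' @param config A [cohort_config()].
#' @param simulate_bold Set `FALSE` to skip BOLD simulation (faster
#'   when only behavior is needed).
#' @return Object of class `cohort`: list with `config`,
#'   `participants` (data frame: `subject_id`, `group`, `ssri`,
#'   `sex`, `age`, `handedness`), `trials` (combined trial table),
#'   `sessions` (named list of `bold_session`), `events` (named list
#'   of event frames) and `truth` (generating LBA matrix and DCM
#'   specs).
#' @export
generate_cohort <- function(config = cohort_config(), simulate_bold = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_controls + config$n_patients
  group <- rep(c("control", "MDD"), c(config$n_controls, config$n_patients))
  ids <- sprintf("sub-%02d", seq_len(n))
  variant <- config$variant
  d <- variant$n_subject_params

  mu_pat <- config$lba_mu
  mu_pat[["v_true.neutral"]] <- mu_pat[["v_true.neutral"]] - config$neutral_gap

  participants <- data.frame(subject_id = ids, group = group,
                             ssri = FALSE, sex = NA_character_,
                             age = NA_real_, handedness = NA_character_,
                             stringsAsFactors = FALSE)
  truth_lba <- matrix(NA_real_, n, d, dimnames = list(ids, variant$par_names))
  truth_dcm <- vector("list", n); names(truth_dcm) <- ids
  trials <- vector("list", n)
  sessions <- vector("list", n); names(sessions) <- ids
  events <- vector("list", n); names(events) <- ids

  for (s in seq_len(n)) {
    local_rng(derive_seed(config$seed, s))
    gi <- if (group[s] == "control") 1L else 2L
    participants$ssri[s] <- group[s] == "MDD" && runif(1) < config$ssri_rate
    participants$sex[s] <- if (runif(1) < config$male_rate[gi]) "M" else "F"
    participants$age[s] <- min(18.9, max(11.1,
      rnorm(1, config$age_mean[gi], config$age_sd[gi])))
    participants$handedness[s] <-
      if (runif(1) < config$right_handed_rate[gi]) "R" else "L"

    mu <- if (group[s] == "control") config$lba_mu else mu_pat
    x <- rnorm(d, mu, config$lba_sigma)
    truth_lba[s, ] <- x
    pars <- variant_to_params(x, variant)
    des <- session_design(seed = derive_seed(config$seed, 1000 + s))
    trials[[s]] <- simulate_trials(pars, des,
                                   seed = derive_seed(config$seed, 2000 + s),
                                   response_window = config$response_window,
                                   subject_id = ids[s], group = group[s])
    ev <- data.frame(onset = des$onset, duration = des$duration,
                     condition = des$condition, stringsAsFactors = FALSE)
    events[[s]] <- ev
    spec <- subject_dcm_spec(config, group[s] == "MDD",
                             participants$ssri[s])
    truth_dcm[[s]] <- spec
    if (simulate_bold)
      sessions[[s]] <- simulate_session(
        spec, events = ev, TR = config$TR, n_volumes = config$n_volumes,
        noise_sd = config$bold_noise_sd,
        seed = derive_seed(config$seed, 3000 + s))
  }
  structure(list(config = config, participants = participants,
                 trials = do.call(rbind, trials), sessions = sessions,
                 events = events,
                 truth = list(lba = truth_lba, dcm = truth_dcm)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_controls, "controls +",
      x$config$n_patients, "patients;",
      nrow(x$trials) / nrow(x$participants), "trials/subject",
      if (length(x$sessions) && !is.null(x$sessions[[1]]))
        paste0("; BOLD ", x$config$n_volumes, " volumes @ TR ",
               x$config$TR, " s") else "", "\n")
  invisible(x)
}

#' Design matrix of a cohort for PEB
#'
#' Intercept, group (control = 0, MDD = 1, mean-centered like all
#' further columns), SSRI status, sex, age and handedness.
#'
#' @param cohort A [generate_cohort()] result or its `participants`
#'   data frame.
#' @return Design matrix via [peb_design()].
#' @export
cohort_design <- function(cohort) {
  pt <- if (inherits(cohort, "cohort")) cohort$participants else cohort
  peb_design(group = as.numeric(pt$group == "MDD"),
             ssri = as.numeric(pt$ssri),
             sex = as.numeric(pt$sex == "M"),
             age = pt$age,
             hand = as.numeric(pt$handedness == "R"))
}
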