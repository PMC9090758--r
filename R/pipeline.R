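# Pipeline orchestration: a run configuration (R list, JSON or YAML)
# drives the stages cohort -> LBA fit -> model selection -> group
# comparison -> posterior-predictive check -> DCM inversion -> PEB ->
# LOOCV, with a JSON manifest of inputs, outputs, seeds and wall times.

.pipeline_stages <- c("cohort", "lba_fit", "model_selection",
                      "group_comparison", "ppc", "dcm_inversion", "peb",
                      "loocv")

#' Run configuration
#'
#' @param stages Stage names, a subset of the canonical order.
#' @param out_dir Output directory.
#' @param seed Master seed (overrides stage seeds).
#' @param cohort Arguments for [cohort_config()].
#' @param sampler Arguments for [sampler_config()].
#' @param variants Model variants fitted during model selection.
#' @param comparison_parameter Group-level parameter compared between
#'   groups.
#' @param dcm Arguments for [invert_dcm()] (e.g. `max_iter`, `tol`).
#' @param peb_parameters First-level parameters taken to the PEB level
#'   (default: the A-matrix entries).
#' @param ppc Arguments for [posterior_predictive_cohort()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(stages = .pipeline_stages, out_dir = tempfile("run-"),
                       seed = 1, cohort = list(), sampler = list(),
                       variants = c("M_v", "M_B", "M_null"),
                       comparison_parameter = "mu.v_true.neutral",
                       dcm = list(), peb_parameters = NULL, ppc = list()) {
  unknown <- setdiff(stages, .pipeline_stages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  structure(list(stages = stages, out_dir = out_dir, seed = seed,
                 cohort = cohort, sampler = sampler, variants = variants,
                 comparison_parameter = comparison_parameter, dcm = dcm,
                 peb_parameters = peb_parameters, ppc = ppc),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, cfg)
}

#' Execute the analysis pipeline
#'
#' Runs the configured stages in order on a synthetic cohort (or one
#' loaded from `data_dir`), writing every stage's outputs under
#' `out_dir` and a manifest (inputs, outputs, seeds, wall times,
#' package version) as `manifest.json`. A stage failure aborts the
#' downstream stages and is recorded in the manifest.
#'
#' @param config A [run_config()] (or path readable by
#'   [read_run_config()]).
#' @return The manifest, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!("cohort" %in% config$stages))
    stop("configuration error: no 'cohort' stage and no data path ",
         "configured; nothing to analyse", call. = FALSE)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  manifest <- list(seed = config$seed, stages = list(),
                   version = as.character(utils::packageVersion("accumdcm")))
  state <- new.env(parent = emptyenv())
  outputs <- character(0)

  save_json <- function(obj, fname) {
    p <- file.path(config$out_dir, fname)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    outputs <<- c(outputs, p)
    p
  }

  stage_funs <- list(
    cohort = function() {
      cc <- do.call(cohort_config,
                    modifyList(list(seed = config$seed), config$cohort))
      state$cohort <- generate_cohort(cc)
      files <- export_cohort(state$cohort,
                             file.path(config$out_dir, "cohort"))
      outputs <<- c(outputs, files)
      length(files)
    },
    lba_fit = function() {
      sc <- do.call(sampler_config,
                    modifyList(list(seed = config$seed), config$sampler))
      tr <- state$cohort$trials
      state$fits <- list(
        control = run_hierarchical(tr[tr$group == "control", ], "M_v", sc),
        MDD = run_hierarchical(tr[tr$group == "MDD", ], "M_v", sc))
      save_json(list(
        control = unclass(state$fits$control$convergence)[c("multivariate", "pass")],
        MDD = unclass(state$fits$MDD$convergence)[c("multivariate", "pass")]),
        "lba_convergence.json")
      vapply(state$fits, function(f) f$convergence$multivariate, numeric(1))
    },
    model_selection = function() {
      sc <- do.call(sampler_config,
                    modifyList(list(seed = config$seed), config$sampler))
      tr <- state$cohort$trials
      ctrl <- tr[tr$group == "control", ]
      fits <- lapply(config$variants, function(v)
        if (v == "M_v") state$fits$control else run_hierarchical(ctrl, v, sc))
      names(fits) <- config$variants
      state$comparison <- elpd_compare(fits)
      save_json(list(winner = state$comparison$winner,
                     table = state$comparison$table), "model_selection.json")
      state$comparison$winner
    },
    group_comparison = function() {
      gd <- compare_groups(state$fits$control, state$fits$MDD,
                           config$comparison_parameter)
      state$group_diff <- gd
      save_json(list(parameter = gd$parameter, mean = gd$mean,
                     hpdi = gd$hpdi, significant = gd$significant),
                "group_comparison.json")
      gd$significant
    },
    ppc = function() {
      args <- modifyList(list(group_fits = state$fits, n_per_group = 200,
                              seed = config$seed), config$ppc)
      pp <- do.call(posterior_predictive_cohort, args)
      sub <- subsample_cohort(pp, seed = config$seed)
      st <- behavioral_stats(sub)
      state$ppc_stats <- st
      p <- file.path(config$out_dir, "ppc_stats.tsv")
      write_tsv(st, p)
      outputs <<- c(outputs, p)
      nrow(st)
    },
    dcm_inversion = function() {
      co <- state$cohort
      state$posteriors <- do.call(fit_dcm_cohort,
        c(list(sessions = co$sessions[co$participants$subject_id],
               events = co$events[co$participants$subject_id]),
          config$dcm))
      save_json(lapply(state$posteriors, function(p)
        list(F = p$F, iterations = p$iterations)), "dcm_inversion.json")
      length(state$posteriors)
    },
    peb = function() {
      X <- cohort_design(state$cohort)
      pars <- config$peb_parameters %||%
        grep("^A", names(dcm_priors()$mean), value = TRUE)
      fit <- peb_fit(state$posteriors, X, parameters = pars)
      state$peb <- greedy_prune_and_average(fit)
      state$X <- X
      save_json(list(F = state$peb$F, gamma = state$peb$gamma,
                     bma = as.list(state$peb$bma_mean),
                     pp = as.list(state$peb$pp)), "peb.json")
      sum(state$peb$present)
    },
    loocv = function() {
      pars <- config$peb_parameters %||%
        grep("^A", names(dcm_priors()$mean), value = TRUE)
      lc <- loocv_classify(state$posteriors, state$X, group_col = "group",
                           parameters = pars, seed = config$seed)
      state$loocv <- lc
      save_json(list(auc = lc$auc, ci = lc$ci, prob = lc$prob), "loocv.json")
      lc$auc
    })

  aborted <- FALSE
  for (st_name in config$stages) {
    rec <- list(stage = st_name)
    if (aborted) {
      rec$status <- "skipped"
    } else {
      t0 <- Sys.time()
      res <- tryCatch(stage_funs[[st_name]](), error = function(e)
        structure(conditionMessage(e), class = "stage_error"))
      rec$seconds <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
      if (inherits(res, "stage_error")) {
        rec$status <- "failed"
        rec$error <- unclass(res)
        aborted <- TRUE
      } else {
        rec$status <- "completed"
        rec$result <- res
      }
    }
    manifest$stages[[st_name]] <- rec
  }
  manifest$outputs <- c(outputs, file.path(config$out_dir, "manifest.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Mixed-model analysis of the behavioral outcomes
#'
#' The conventional analysis of the task: linear mixed models (REML,
#' Satterthwaite denominator degrees of freedom) with condition, group
#' and their interaction as fixed effects and subject as random
#' intercept, fitted to (a) trial-level log response times, (b) the
#' per-subject-by-condition error counts and (c) omission counts.
#'
#' @param trials Trial table covering both groups.
#' @return Data frame with columns `outcome`, `effect`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
behavioral_stats <- function(trials) {
  stopifnot(length(unique(trials$group)) >= 2,
            length(unique(trials$condition)) >= 2)
  all_omit <- tapply(trials$response == "omission", trials$subject_id, all)
  if (any(all_omit)) {
    warning("excluding all-omission subject(s): ",
            paste(names(all_omit)[all_omit], collapse = ", "), call. = FALSE)
    trials <- trials[!trials$subject_id %in% names(all_omit)[all_omit], ]
  }
  trials$condition <- factor(trials$condition, levels = .cond_levels)
  trials$group <- factor(trials$group)

  anova_tab <- function(fml, data, outcome) {
    # a degenerate outcome (e.g. no omissions anywhere) cannot support
    # the mixed model; report NA effects rather than failing
    res <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(fml, data = data, REML = TRUE)))
      a <- suppressMessages(anova(fit, type = 3))
      data.frame(outcome = outcome, effect = rownames(a),
                 F = a[, "F value"], df1 = a[, "NumDF"], df2 = a[, "DenDF"],
                 p = a[, "Pr(>F)"], row.names = NULL,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) {
      warning("mixed model for outcome '", outcome,
              "' could not be fitted; reporting NA", call. = FALSE)
      res <- data.frame(outcome = outcome,
                        effect = c("condition", "group", "condition:group"),
                        F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE)
    }
    res
  }

  resp <- trials[trials$response != "omission" & !is.na(trials$rt), ]
  resp$logRT <- log(resp$rt)
  out <- anova_tab(logRT ~ condition * group + (1 | subject_id), resp,
                   "logRT")

  agg <- do.call(rbind, lapply(split(trials,
    list(trials$subject_id, trials$condition), drop = TRUE),
    function(dd) data.frame(
      subject_id = dd$subject_id[1], group = dd$group[1],
      condition = dd$condition[1],
      errors = sum(!is.na(dd$correct) & !dd$correct),
      omissions = sum(dd$response == "omission"),
      stringsAsFactors = FALSE)))
  out <- rbind(out,
    anova_tab(errors ~ condition * group + (1 | subject_id), agg, "errors"),
    anova_tab(omissions ~ condition * group + (1 | subject_id), agg,
              "omissions"))
  out
}
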