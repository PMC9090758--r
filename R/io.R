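# Plain-text serialization: TSV for tabular data, JSON for metadata and
# results, BIDS-style events.tsv for task timing.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a trial table as BIDS-style events.tsv
#'
#' Columns `onset`, `duration`, `trial_type`, `response_time` in that
#' order (plus `response` and `correct` as extra columns).
#'
#' @param trials Trial table of one subject.
#' @param path Output file.
#' @param duration Stimulus duration (s).
#' @export
write_events_tsv <- function(trials, path, duration = 4) {
  ev <- data.frame(onset = trials$onset, duration = duration,
                   trial_type = trials$condition,
                   response_time = trials$rt,
                   response = trials$response,
                   correct = as.integer(trials$correct))
  write_tsv(ev, path)
}

#' Write a BOLD session as TSV + JSON sidecar
#'
#' The TSV holds volumes as rows and regions as columns (header =
#' region labels); the sidecar records TR, volume count, noise SD and
#' seed.
#'
#' @param session A `bold_session`.
#' @param path Output TSV path; the sidecar replaces `.tsv` by
#'   `.json`.
#' @export
write_bold_session <- function(session, path) {
  stopifnot(inherits(session, "bold_session"))
  m <- t(session$bold)
  write_tsv(as.data.frame(m), path)
  side <- list(TR = session$TR, n_volumes = session$n_volumes,
               micro_dt = session$micro_dt, noise_sd = session$noise_sd,
               seed = session$seed)
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
}

#' Read a BOLD session written by [write_bold_session()]
#' @param path TSV path (sidecar expected alongside).
#' @return A `bold_session`.
#' @export
read_bold_session <- function(path) {
  m <- as.matrix(read_tsv(path))
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(bold = t(m), TR = side$TR, n_volumes = side$n_volumes,
                 micro_dt = side$micro_dt, noise_sd = side$noise_sd,
                 seed = side$seed),
            class = "bold_session")
}

#' Export a cohort to disk
#'
#' Writes the participants table, per-subject trials TSV, BIDS-style
#' events.tsv, BOLD TSV + JSON sidecar, and the generating ground
#' truth as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
export_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory, call. = FALSE)
  paths <- character(0)
  wr <- function(fun, obj, fname) {
    p <- file.path(directory, fname)
    ok <- tryCatch({ fun(obj, p); TRUE }, error = function(e) {
      stop("failed writing ", p, ": ", conditionMessage(e), call. = FALSE)
    })
    paths <<- c(paths, p)
    p
  }
  wr(write_tsv, cohort$participants, "participants.tsv")
  for (id in cohort$participants$subject_id) {
    tr <- cohort$trials[cohort$trials$subject_id == id, , drop = FALSE]
    wr(write_tsv, tr, paste0(id, "_trials.tsv"))
    wr(function(obj, p) write_events_tsv(obj, p), tr,
       paste0(id, "_events.tsv"))
    if (!is.null(cohort$sessions[[id]])) {
      wr(write_bold_session, cohort$sessions[[id]], paste0(id, "_bold.tsv"))
      paths <- c(paths, file.path(directory, paste0(id, "_bold.json")))
    }
  }
  truth <- list(
    lba = as.data.frame(cohort$truth$lba),
    dcm = lapply(cohort$truth$dcm, function(sp)
      list(A = sp$A, B_pos = sp$B_pos, B_neg = sp$B_neg, C = sp$C)))
  tp <- file.path(directory, "ground_truth.json")
  jsonlite::write_json(truth, tp, digits = NA)
  paths <- c(paths, tp)
  invisible(paths)
}

#' Persist thinned posterior draws as columnar TSV
#'
#' Long-format table of the group-level draws: one row per (chain,
#' stored iteration, parameter) with the sampled value; the natural
#' companion of the JSON convergence report for archiving a fit.
#'
#' @param fit An `lba_hierfit`.
#' @param path Output TSV path.
#' @export
write_posterior_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "lba_hierfit"))
  g <- fit$group_draws
  n_it <- dim(g)[1]; n_ch <- dim(g)[2]; d <- dim(g)[3]
  out <- data.frame(
    chain = rep(seq_len(n_ch), each = n_it, times = d),
    iteration = rep(seq_len(n_it), times = n_ch * d),
    parameter = rep(fit$group_names, each = n_it * n_ch),
    value = as.numeric(g))
  write_tsv(out, path)
}
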