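test_that("default cohort reproduces the study structure deterministically", {
  cc <- cohort_config(seed = 51)
  expect_equal(cc$n_controls, 33)
  expect_equal(cc$n_patients, 30)
  expect_equal(cc$neutral_gap, 0.14)
  co <- generate_cohort(cc, simulate_bold = FALSE)
  expect_equal(nrow(co$participants), 63)
  expect_equal(sum(co$participants$group == "control"), 33)
  expect_equal(sum(co$participants$group == "MDD"), 30)
  expect_equal(nrow(co$trials), 63 * 80)
  # SSRI only among patients
  expect_true(all(!co$participants$ssri[co$participants$group == "control"]))
  # bit-identical regeneration
  co2 <- generate_cohort(cohort_config(seed = 51), simulate_bold = FALSE)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$truth$lba, co2$truth$lba)
  expect_error(cohort_config(n_controls = 1), "n_controls")
  expect_error(cohort_config(ssri_rate = 1.4), "ssri_rate")
})

test_that("the generating neutral-drift gap matches its configuration", {
  gaps <- vapply(1:50, function(r) {
    co <- generate_cohort(cohort_config(n_controls = 8, n_patients = 8,
                                        seed = 600 + r),
                          simulate_bold = FALSE)
    truth <- co$truth$lba
    grp <- co$participants$group
    mean(truth[grp == "control", "v_true.neutral"]) -
      mean(truth[grp == "MDD", "v_true.neutral"])
  }, numeric(1))
  # SD of a single-cohort gap is sigma * sqrt(2/8); 50 replicates
  se <- 0.2 * sqrt(2 / 8) / sqrt(50)
  expect_lt(abs(mean(gaps) - 0.14), 3 * se)
})

test_that("patient specs carry the connectivity deltas and SSRI effect", {
  cc <- cohort_config(n_controls = 30, n_patients = 30, seed = 53,
                      dcm_subject_sd = 1e-9, ssri_rate = 1)
  co <- generate_cohort(cc, simulate_bold = FALSE)
  ctrl <- co$truth$dcm[[which(co$participants$group == "control")[1]]]
  pat_i <- which(co$participants$group == "MDD" & co$participants$ssri)[1]
  pat <- co$truth$dcm[[pat_i]]
  expect_equal(pat$A["LPFC", "FFA"] - ctrl$A["LPFC", "FFA"], -0.033,
               tolerance = 1e-6)
  expect_equal(pat$A["sgACC", "LPFC"] - ctrl$A["sgACC", "LPFC"], 0.054,
               tolerance = 1e-6)
  expect_equal(pat$A["AMY", "sgACC"] - ctrl$A["AMY", "sgACC"], -0.035,
               tolerance = 1e-6)
  expect_equal(pat$A["sgACC", "sgACC"] - ctrl$A["sgACC", "sgACC"], -0.145,
               tolerance = 1e-6)
})

test_that("covariates are matched between groups", {
  ages <- replicate(30, {
    co <- generate_cohort(cohort_config(n_controls = 10, n_patients = 10,
                                        seed = sample.int(1e6, 1)),
                          simulate_bold = FALSE)
    with(co$participants, mean(age[group == "control"]) -
           mean(age[group == "MDD"]))
  })
  # matched design: expected group age difference well under half an SD
  expect_lt(abs(mean(ages)), 0.5 * 1.9)
})

test_that("cohort export round-trips through plain-text files", {
  co <- generate_cohort(cohort_config(n_controls = 2, n_patients = 2,
                                      seed = 54, n_volumes = 64))
  dir <- tempfile("cohort-")
  paths <- export_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  pt <- accumdcm:::read_tsv(file.path(dir, "participants.tsv"))
  expect_equal(nrow(pt), 4)
  expect_equal(pt$subject_id, co$participants$subject_id)
  # trials round trip
  tr <- accumdcm:::read_tsv(file.path(dir, "sub-01_trials.tsv"))
  orig <- co$trials[co$trials$subject_id == "sub-01", ]
  expect_equal(tr$rt, orig$rt, tolerance = 1e-12)
  expect_equal(tr$response, orig$response)
  # events.tsv has the BIDS column order
  ev <- readLines(file.path(dir, "sub-01_events.tsv"), n = 1)
  expect_equal(strsplit(ev, "\t")[[1]][1:4],
               c("onset", "duration", "trial_type", "response_time"))
  # BOLD round trip within float formatting
  ses <- read_bold_session(file.path(dir, "sub-01_bold.tsv"))
  expect_equal(ses$bold, co$sessions[["sub-01"]]$bold, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ses$TR, 1.6)
  expect_equal(ses$n_volumes, 64)
})
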