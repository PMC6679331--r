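sim_fast <- function(seed = 1, ...) {
  simulate_session(seed = seed, seg_s = 180, gap_s = 20, lead_s = 10,
                   fs_internal = 100, ...)
}

test_that("six FSR pulses delimit three labelled segments, rest first", {
  ses <- sim_fast(seed = 41)
  segs <- segment_by_fsr(ses$recording, layout = ses$layout)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$label, c("rest", "motion_drive", "no_motion_drive"))
  truth <- ses$segments[match(segs$label, ses$segments$label), ]
  expect_equal(segs$start_s, truth$start_s, tolerance = 1)
  expect_equal(segs$end_s, truth$end_s, tolerance = 1)
})

test_that("a flat FSR raises a synchronization error", {
  rec <- small_recording(n = 200)
  rec$data$fsr <- rep(0, 200)
  expect_error(segment_by_fsr(rec), "synchronization error")
})

test_that("double-taps are debounced into one press", {
  n <- 400
  fsr <- numeric(n)
  # six logical presses, the first one a double-tap 0.5 s apart
  press_samples <- c(20, 21, 60, 120, 200, 260, 340)
  fsr[press_samples] <- 1
  rec <- egg_recording(replicate(3, rnorm(n, sd = 10), simplify = FALSE),
                       fsr, fs = 2, subject_id = "T")
  segs <- segment_by_fsr(rec, layout = session_layout())
  expect_equal(nrow(segs), 3)
  expect_equal(min(segs$start_s), (20 - 1) / 2)
})

test_that("a pulse count inconsistent with the layout reports the times", {
  n <- 400
  fsr <- numeric(n)
  fsr[c(20, 100)] <- 1
  rec <- egg_recording(replicate(3, rnorm(n, sd = 10), simplify = FALSE),
                       fsr, fs = 2, subject_id = "T")
  expect_error(segment_by_fsr(rec), "2 press events.*9.5")
})

test_that("a clean synthetic session yields three valid rows at 3 cpm", {
  ses <- sim_fast(seed = 42)
  segs <- segment_by_fsr(ses$recording, layout = ses$layout)
  feats <- extract_segment_features(ses$recording, segs)
  expect_equal(nrow(feats), 3)
  expect_true(all(feats$valid))
  expect_equal(feats$DF_cpm, rep(3, 3), tolerance = 0.2 / 3)
  expect_true(all(feats$rhythm == "normogastric"))
})

test_that("a dysrhythmic drive raises MF above rest, mirroring nausea shifts", {
  ses <- sim_fast(seed = 43, motion = list(freq_cpm = 7))
  segs <- segment_by_fsr(ses$recording, layout = ses$layout)
  feats <- extract_segment_features(ses$recording, segs)
  mf <- function(lab) feats$MF_cpm[feats$label == lab]
  expect_gt(mf("motion_drive"), mf("rest"))
})

test_that("segments too short after excision are flagged invalid, not dropped", {
  ses <- sim_fast(seed = 44)
  segs <- segment_by_fsr(ses$recording, layout = ses$layout)
  rest <- segs[segs$label == "rest", ]
  big_artifact <- markers(rest$start_s + 2, rest$end_s - 2, "artifact")
  feats <- extract_segment_features(ses$recording, segs,
                                    artifact_markers = big_artifact)
  expect_equal(nrow(feats), 3)
  rest_row <- feats[feats$label == "rest", ]
  expect_false(rest_row$valid)
  expect_match(rest_row$note, "length error")
  expect_true(all(feats$valid[feats$label != "rest"]))
})

test_that("counterbalancing swaps labels, not values, for identical sessions", {
  a <- sim_fast(seed = 45, order = "motion_first")
  b <- sim_fast(seed = 45, order = "no_motion_first")
  fa <- extract_segment_features(a$recording,
                                 segment_by_fsr(a$recording, a$layout))
  fb <- extract_segment_features(b$recording,
                                 segment_by_fsr(b$recording, b$layout))
  expect_equal(fa$DF_cpm[fa$label == "rest"], fb$DF_cpm[fb$label == "rest"])
  # with no episodes the two drives occupy the same time windows, so the
  # motion features under order A equal the no-motion features under order B
  expect_equal(fa$RMS_mV[fa$label == "motion_drive"],
               fb$RMS_mV[fb$label == "no_motion_drive"])
})

test_that("paired t test matches its closed form on the worked example", {
  tt <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(tt$t, -2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  expect_equal(tt$n, 3)

  swapped <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swapped$t, -tt$t)
  expect_equal(swapped$p, tt$p)

  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(paired_t_test(1, 2), "length error")
  expect_error(paired_t_test(1:3, 1:4), "length error")
})

test_that("paired t test agrees with a numerical-integration oracle to 1e-6", {
  t_density <- function(x, nu) {
    gamma((nu + 1) / 2) / (sqrt(nu * pi) * gamma(nu / 2)) *
      (1 + x^2 / nu)^(-(nu + 1) / 2)
  }
  withr::with_seed(46, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      a <- rnorm(n)
      b <- rnorm(n, mean = runif(1, -1, 1))
      d <- a - b
      t_direct <- mean(d) / (sd(d) / sqrt(n))
      p_direct <- 2 * stats::integrate(t_density, abs(t_direct), Inf,
                                       nu = n - 1,
                                       rel.tol = 1e-10)$value
      tt <- paired_t_test(a, b)
      expect_equal(tt$t, t_direct, tolerance = 1e-6)
      expect_equal(tt$p, p_direct, tolerance = 1e-6)
    }
  })
})

test_that("tidy and glance expose the t-test result as tibbles", {
  tt <- paired_t_test(c(1, 2, 3, 5), c(2, 4, 6, 6))
  td <- tidy(tt)
  expect_named(td, c("estimate", "statistic", "p.value", "parameter"))
  gl <- glance(tt)
  expect_equal(gl$nobs, 4)
  expect_equal(gl$df, 3)
})

test_that("cohort summary reproduces the published demographic statistics", {
  s <- summarize_cohort(cohort_demographics())
  get <- function(v, col) s[[col]][s$variable == v]
  expect_equal(round(get("age_years", "mean")), 29)
  expect_equal(round(get("age_years", "sd")), 8)
  expect_equal(get("age_years", "min"), 23)
  expect_equal(get("age_years", "max"), 47)
  expect_equal(round(get("weight_kg", "mean")), 73)
  expect_equal(round(get("weight_kg", "sd")), 19)
  expect_equal(round(get("height_cm", "mean")), 177)
  expect_equal(round(get("height_cm", "sd")), 8)

  one <- summarize_cohort(cohort_demographics()[1, ])
  expect_true(is.na(one$sd[1]))
  expect_error(summarize_cohort(cohort_demographics()[0, ]), "empty")
})

test_that("run_study isolates failing subjects and reports exclusions", {
  good1 <- sim_fast(seed = 47)
  good2 <- sim_fast(seed = 48, order = "no_motion_first")
  broken <- sim_fast(seed = 49)
  broken$recording$data$fsr <- rep(0, nrow(broken$recording$data))
  subjects <- list(
    list(id = "S1", recording = good1$recording, layout = good1$layout),
    list(id = "S2", recording = good2$recording, layout = good2$layout),
    list(id = "S3", recording = broken$recording, layout = broken$layout)
  )
  report <- run_study(subjects)
  expect_equal(sort(unique(report$features$subject)), c("S1", "S2"))
  expect_equal(report$exclusions$subject, "S3")
  expect_match(report$exclusions$reason, "synchronization")
  expect_equal(nrow(report$ttests), 15) # 3 condition pairs x 5 features
})

test_that("run_study is deterministic and writes the report bundle", {
  ses <- sim_fast(seed = 50)
  # plant a movement-artifact spike on all channels inside the rest
  # segment and mark it for excision
  spike_t <- ses$segments$start_s[1] + 25
  tvec <- ses$recording$data$time_s
  spike <- 1000 * exp(-(tvec - spike_t)^2 / (2 * 0.5^2))
  for (ch in c("ch1_uV", "ch2_uV", "ch3_uV")) {
    ses$recording$data[[ch]] <- ses$recording$data[[ch]] + spike
  }
  art <- markers(spike_t - 5, spike_t + 5, "artifact")
  subjects <- list(list(id = "S1", recording = ses$recording,
                        layout = ses$layout, artifact_markers = art))
  ssq <- dplyr::bind_cols(
    tibble::tibble(subject = "S1", stage = "resting"),
    uniform_ssq_response(1))
  out_dir <- withr::local_tempdir()
  r1 <- run_study(subjects, ssq_responses = ssq,
                  cohort = cohort_demographics(), out_dir = out_dir,
                  welch_window_s = 60)
  r2 <- run_study(subjects, ssq_responses = ssq,
                  cohort = cohort_demographics(), welch_window_s = 60)
  expect_identical(r1$features, r2$features)
  expect_true(all(file.exists(file.path(
    out_dir, c("features.csv", "ttests.csv", "exclusions.csv",
               "scatter_rms_normo.csv", "ssq_scores.csv",
               "cohort_summary.csv")))))
  # uncorrected pass exists because artifact markers were supplied
  expect_equal(nrow(r1$features_raw), 3)
  expect_equal(r1$ssq_scores$total, 78.54)
  # excising the marked spike strictly reduces the segment RMS
  rest_exc <- r1$features$RMS_mV[r1$features$label == "rest"]
  rest_raw <- r1$features_raw$RMS_mV[r1$features_raw$label == "rest"]
  expect_lt(rest_exc, rest_raw)
  expect_equal(r1$features$excised_s[r1$features$label == "rest"], 10)
})

test_that("a 9-subject cohort with 50% drive RMS amplification is detected in most of 200 reps", {
  significant <- 0
  for (rep in 1:200) {
    withr::with_seed(5000 + rep, {
      base_amp <- runif(9, 200, 500)
      drive_amp <- 1.5 * base_amp * exp(rnorm(9, 0, 0.1))
    })
    rest <- numeric(9)
    drive <- numeric(9)
    for (s in 1:9) {
      cfg_r <- synth_config(duration_s = 300, fs_internal = 2,
                            slow_wave = list(amp_uVpp = base_amp[s]),
                            seed = rep * 100 + s)
      cfg_d <- synth_config(duration_s = 300, fs_internal = 2,
                            slow_wave = list(amp_uVpp = drive_amp[s]),
                            seed = rep * 100 + s + 50)
      rest[s] <- rms_mv(bandpass(generate_sources(cfg_r)$channels[[1]], 2))
      drive[s] <- rms_mv(bandpass(generate_sources(cfg_d)$channels[[1]], 2))
    }
    if (paired_t_test(rest, drive)$p < 0.05) significant <- significant + 1
  }
  expect_gt(significant, 100)
})
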