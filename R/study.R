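#' Session layout labels in recorded order
#'
#' A session comprises a familiarisation test drive, a resting baseline,
#' and two ~5-min simulator drives (with and without platform motion)
#' whose order is counterbalanced across volunteers. Only the resting
#' and drive segments are analysed; the participant presses the FSR
#' pushbutton at the start and end of each analysed segment (SSQ forms
#' are filled in between, so segments are separated by gaps).
#'
#' @param order `"motion_first"` or `"no_motion_first"`.
#' @return Character vector of analysed-segment labels in recorded order.
#' @export
session_layout <- function(order = c("motion_first", "no_motion_first")) {
  order <- match.arg(order)
  if (order == "motion_first") {
    c("rest", "motion_drive", "no_motion_drive")
  } else {
    c("rest", "no_motion_drive", "motion_drive")
  }
}

segment_label_order <- c("rest", "motion_drive", "no_motion_drive",
                         "test_drive")

#' Segment a session by FSR pushbutton presses
#'
#' Detects press events as upward crossings of `threshold_frac` times the
#' FSR maximum, separated by at least `debounce_s` (a double-tap counts
#' once). Consecutive event pairs delimit the analysed segments, labelled
#' per the layout; in the returned table the resting segment always
#' precedes the drives, whatever the recorded (counterbalanced) order.
#'
#' @param rec An [egg_recording()] whose FSR channel carries the pulses.
#' @param layout Segment labels in recorded order, see [session_layout()].
#' @param threshold_frac Fraction of the FSR maximum used as threshold.
#' @param debounce_s Minimum separation between distinct presses (s).
#' @return A marker tibble with one row per analysed segment.
#' @export
segment_by_fsr <- function(rec, layout = session_layout(),
                           threshold_frac = 0.5, debounce_s = 2) {
  stopifnot(inherits(rec, "egg_recording"))
  fsr <- rec$data$fsr
  if (max(fsr) <= 0) {
    stop("synchronization error: FSR channel is flat, no presses found",
         call. = FALSE)
  }
  thr <- threshold_frac * max(fsr)
  up <- which(fsr >= thr & c(-Inf, fsr[-length(fsr)]) < thr)
  times <- (up - 1) / rec$fs
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= debounce_s)
    # a run of close taps collapses onto its first tap
    for (i in seq_along(times)[-1]) {
      last_kept <- max(which(keep[seq_len(i - 1)]))
      keep[i] <- times[i] - times[last_kept] >= debounce_s
    }
    times <- times[keep]
  }
  if (length(times) != 2 * length(layout)) {
    stop(sprintf(
      "synchronization error: %d press events for %d segments (need %d); detected at %s s",
      length(times), length(layout), 2 * length(layout),
      paste(round(times, 1), collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    start_s = times[seq(1, length(times), by = 2)],
    end_s = times[seq(2, length(times), by = 2)],
    label = layout
  )
  out[order(match(out$label, segment_label_order)), ]
}

# clip artifact markers to one segment, in segment-local time
local_artifacts <- function(mk, start_s, end_s) {
  if (is.null(mk) || nrow(mk) == 0) return(markers())
  mk <- mk[mk$label == "artifact", ]
  mk <- mk[mk$end_s > start_s & mk$start_s < end_s, ]
  if (nrow(mk) == 0) return(markers())
  markers(pmax(mk$start_s, start_s) - start_s,
          pmin(mk$end_s, end_s) - start_s,
          "artifact")
}

#' Per-segment feature extraction for one session
#'
#' For every analysed segment: band-pass each channel over the whole
#' record, slice the segment, select the least-affected channel, excise
#' marked artifacts from the chosen channel, and compute the five
#' slow-wave features. A segment that becomes too short for the feature
#' contracts after excision is flagged invalid (with the reason), never
#' dropped silently.
#'
#' @param rec An [egg_recording()].
#' @param segments Segment marker tibble from [segment_by_fsr()] (or
#'   built manually).
#' @param artifact_markers Optional artifact marker tibble in record
#'   time; `NULL` for none.
#' @param bp A [bandpass_spec()].
#' @param selection_threshold Range-ratio elimination threshold.
#' @param bands A [rhythm_bands()].
#' @param welch_window_s Welch window length (s).
#' @param apply_excision Excise artifact markers (default `TRUE`); set
#'   `FALSE` to compute features on the uncorrected segments.
#' @return A tibble, one row per segment: `label`, `start_s`, `end_s`,
#'   `chosen_channel`, `eliminated`, `excised_s`, the five features,
#'   `rhythm`, `valid`, `note`.
#' @export
extract_segment_features <- function(rec, segments, artifact_markers = NULL,
                                     bp = bandpass_spec(),
                                     selection_threshold = 2,
                                     bands = rhythm_bands(),
                                     welch_window_s = 120,
                                     apply_excision = TRUE) {
  stopifnot(inherits(rec, "egg_recording"))
  fs <- rec$fs
  filtered <- lapply(recording_channels(rec), bandpass, fs = fs, spec = bp)
  t <- rec$data$time_s
  segments <- segments[segments$label != "artifact", ]
  na_row <- tibble::tibble(DF_cpm = NA_real_, MF_cpm = NA_real_,
                           CF = NA_real_, RMS_mV = NA_real_,
                           normo_pct = NA_real_, rhythm = NA_character_)
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    idx <- t >= seg$start_s & t < seg$end_s
    head_cols <- tibble::tibble(label = seg$label, start_s = seg$start_s,
                                end_s = seg$end_s)
    res <- tryCatch({
      chs <- lapply(filtered, `[`, idx)
      sel <- select_channel(chs, threshold = selection_threshold)
      x <- chs[[sel$chosen]]
      exc_s <- 0
      if (apply_excision) {
        la <- local_artifacts(artifact_markers, seg$start_s, seg$end_s)
        x <- excise(x, fs, la)
        exc_s <- attr(x, "excised_s")
      }
      feats <- extract_features(x, fs, bands = bands,
                                welch_window_s = welch_window_s)
      dplyr::bind_cols(
        head_cols,
        tibble::tibble(
          chosen_channel = sel$chosen,
          eliminated = paste(sel$eliminated, collapse = ","),
          excised_s = exc_s),
        feats,
        tibble::tibble(valid = TRUE, note = ""))
    }, error = function(e) {
      dplyr::bind_cols(
        head_cols,
        tibble::tibble(chosen_channel = NA_integer_, eliminated = "",
                       excised_s = NA_real_),
        na_row,
        tibble::tibble(valid = FALSE, note = conditionMessage(e)))
    })
    res
  })
}

#' Paired-sample t test
#'
#' Two-sided paired t test on per-subject feature pairs: with
#' differences `d`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees
#' of freedom (sample standard deviation). Differences below p = 0.05
#' are conventionally called significant in this workflow. Wraps
#' [stats::t.test()].
#'
#' @param a,b Equal-length numeric vectors of paired values, `n >= 2`.
#' @return An object of class `egg_ttest` with elements `t`, `df`, `p`,
#'   `n`, `mean_diff`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 4, 6))
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length error: a and b must be paired", call. = FALSE)
  }
  if (length(a) < 2) stop("length error: need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("degenerate error: all paired differences identical", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  structure(list(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    n = length(a),
    mean_diff = unname(ht$estimate)
  ), class = "egg_ttest")
}

#' @export
print.egg_ttest <- function(x, ...) {
  cat(sprintf("Paired t test: t(%d) = %.3f, p = %.4f (n = %d, mean diff %.4g)\n",
              x$df, x$t, x$p, x$n, x$mean_diff))
  invisible(x)
}

#' @rdname paired_t_test
#' @param x An `egg_ttest` object.
#' @param ... Unused.
#' @method tidy egg_ttest
#' @export
tidy.egg_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$t,
                 p.value = x$p, parameter = x$df)
}

#' @rdname paired_t_test
#' @method glance egg_ttest
#' @export
glance.egg_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$t, p.value = x$p, df = x$df, nobs = x$n)
}

#' Summarise a cohort demographics table
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of every numeric column; presentation conventionally rounds
#' to integers (e.g. age 29 +/- 8 years).
#'
#' @param cohort Data frame of per-subject demographics.
#' @return A tibble with one row per numeric column: `variable`, `n`,
#'   `mean`, `sd`, `min`, `max`.
#' @export
#' @examples
#' summarize_cohort(cohort_demographics())
summarize_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) stop("empty error: no subjects", call. = FALSE)
  num <- dplyr::select(cohort, dplyr::where(is.numeric))
  purrr::map_dfr(names(num), function(v) {
    x <- num[[v]]
    tibble::tibble(
      variable = v, n = length(x), mean = mean(x),
      sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
      min = min(x), max = max(x)
    )
  })
}

#' Demographics of the 13-subject driving-simulator cohort
#'
#' Per-subject demographic data for the thirteen healthy volunteers of
#' the reference driving-simulator EGG study (nine analysed, ID1-ID9;
#' four excluded, IDN1-IDN4), bundled as example data for
#' [summarize_cohort()] and [run_study()].
#'
#' @return A tibble with columns `subject`, `age_years`, `sex`,
#'   `height_cm`, `weight_kg`, `driving_experience_years`,
#'   `simulator_experience`.
#' @export
cohort_demographics <- function() {
  tibble::tribble(
    ~subject, ~age_years, ~sex, ~height_cm, ~weight_kg,
    ~driving_experience_years, ~simulator_experience,
    "ID1", 23, "F", 173, 60, 5, TRUE,
    "ID2", 23, "M", 172, 60, 5, FALSE,
    "ID3", 26, "F", 169, 56, 8, FALSE,
    "ID4", 23, "M", 180, 88, 4, FALSE,
    "ID5", 32, "M", 192, 115, 14, TRUE,
    "ID6", 47, "M", 182, 87, 29, FALSE,
    "ID7", 23, "M", 173, 65, 5, TRUE,
    "ID8", 40, "F", 160, 49, 15, TRUE,
    "ID9", 25, "F", 169, 59, 6, TRUE,
    "IDN1", 26, "M", 183, 97, 6, TRUE,
    "IDN2", 27, "M", 181, 75, 9, TRUE,
    "IDN3", 33, "M", 177, 60, 15, TRUE,
    "IDN4", 35, "M", 186, 78, 17, FALSE
  )
}

#' Simulate one complete session recording
#'
#' Builds a synthetic session in the study's shape: a resting segment
#' followed by two drives (counterbalanced order), separated by gaps in
#' which the SSQ would be filled in, with FSR pulses at every segment
#' start and end. Drives may carry a dysrhythmic episode (frequency
#' shift and/or RMS scaling) spanning the drive.
#'
#' @param seed Integer seed.
#' @param order Drive order, see [session_layout()].
#' @param seg_s Analysed-segment duration (s; ~5 min in the protocol).
#' @param gap_s Gap between segments (s).
#' @param lead_s Lead-in before the first segment (s).
#' @param fs_internal Dense generation rate (Hz).
#' @param amp_uVpp Slow-wave peak-to-peak amplitude (µV).
#' @param motion,no_motion Per-drive lists with `freq_cpm` and
#'   `rms_scale` (defaults: unchanged rhythm, unchanged amplitude).
#' @param spikes,respiration,ecg,drift Passed to [synth_config()].
#' @param spec A [front_end_spec()].
#' @param subject_id Subject identifier.
#' @return A list with `recording`, `truth`, `layout` (recorded order),
#'   `segments` (ground-truth segment markers) and `config`.
#' @export
simulate_session <- function(seed = 1, order = "motion_first", seg_s = 300,
                             gap_s = 20, lead_s = 10, fs_internal = 250,
                             amp_uVpp = 300,
                             motion = list(), no_motion = list(),
                             spikes = list(), respiration = list(),
                             ecg = list(), drift = list(),
                             spec = front_end_spec(), subject_id = "synth") {
  layout <- session_layout(order)
  starts <- lead_s + (seq_along(layout) - 1) * (seg_s + gap_s)
  ends <- starts + seg_s
  duration <- ends[length(ends)] + lead_s
  drive_cfg <- list(motion_drive = utils::modifyList(
    list(freq_cpm = NULL, rms_scale = 1), motion),
    no_motion_drive = utils::modifyList(
      list(freq_cpm = NULL, rms_scale = 1), no_motion))
  episodes <- purrr::map_dfr(seq_along(layout), function(i) {
    lab <- layout[i]
    if (!lab %in% names(drive_cfg)) return(NULL)
    dc <- drive_cfg[[lab]]
    if (is.null(dc$freq_cpm) && dc$rms_scale == 1) return(NULL)
    tibble::tibble(start_s = starts[i], end_s = ends[i],
                   target_freq_cpm = dc$freq_cpm %||% 3,
                   rms_scale = dc$rms_scale)
  })
  if (nrow(episodes) == 0) episodes <- NULL
  cfg <- synth_config(
    duration_s = duration, fs_internal = fs_internal,
    slow_wave = list(amp_uVpp = amp_uVpp),
    episodes = episodes, spikes = spikes, respiration = respiration,
    ecg = ecg, drift = drift,
    fsr_pulse_times = sort(c(starts, ends)), seed = seed
  )
  gen <- generate_recording(cfg, spec = spec, subject_id = subject_id)
  list(recording = gen$recording, truth = gen$truth, layout = layout,
       segments = tibble::tibble(start_s = starts, end_s = ends,
                                 label = layout),
       config = cfg)
}

#' Run the full study workflow over a cohort of sessions
#'
#' For each subject: FSR segmentation, per-segment feature extraction
#' with artifact excision (and, when markers exist, a second pass
#' without excision so corrected/uncorrected value pairs can be
#' plotted), then cohort-level paired t tests per feature and condition
#' pair, SSQ scoring and a demographic summary. A subject whose session
#' fails validation is excluded and reported, never silently dropped,
#' and never aborts the rest of the cohort.
#'
#' @param subjects A list; each element a list with `id`, `recording`
#'   (an [egg_recording()]), `layout` (recorded segment order), and
#'   optionally `artifact_markers`.
#' @param ssq_responses Optional data frame of SSQ item ratings with
#'   `subject`, `stage`, `item_1` ... `item_16`.
#' @param cohort Optional demographics table.
#' @param out_dir Optional directory: writes `features.csv`,
#'   `ttests.csv`, `exclusions.csv`, `scatter_rms_normo.csv` and, when
#'   inputs are given, `ssq_scores.csv` and `cohort_summary.csv`.
#' @param ... Passed to [extract_segment_features()].
#' @return A list of class `egg_study_report` with tibbles `features`
#'   (excised), `features_raw` (no excision, where markers existed),
#'   `ttests`, `ssq_scores`, `cohort_summary`, `exclusions`.
#' @export
run_study <- function(subjects, ssq_responses = NULL, cohort = NULL,
                      out_dir = NULL, ...) {
  feats <- list()
  feats_raw <- list()
  exclusions <- list()
  for (sub in subjects) {
    res <- tryCatch({
      segs <- segment_by_fsr(sub$recording,
                             layout = sub$layout %||% session_layout())
      f <- extract_segment_features(sub$recording, segs,
                                    artifact_markers = sub$artifact_markers,
                                    ...)
      if (!any(f$valid)) stop("no valid segment for subject ", sub$id)
      fr <- NULL
      if (!is.null(sub$artifact_markers) &&
          nrow(sub$artifact_markers) > 0) {
        fr <- extract_segment_features(sub$recording, segs,
                                       artifact_markers = NULL, ...)
      }
      list(f = f, fr = fr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1]] <-
        tibble::tibble(subject = sub$id, reason = conditionMessage(res))
    } else {
      feats[[length(feats) + 1]] <-
        dplyr::bind_cols(tibble::tibble(subject = sub$id), res$f)
      if (!is.null(res$fr)) {
        feats_raw[[length(feats_raw) + 1]] <-
          dplyr::bind_cols(tibble::tibble(subject = sub$id), res$fr)
      }
    }
  }
  features <- dplyr::bind_rows(feats)
  features_raw <- dplyr::bind_rows(feats_raw)
  exclusions <- dplyr::bind_rows(exclusions)

  ttests <- study_ttests(features)
  ssq_scores <- if (!is.null(ssq_responses)) score_ssq(ssq_responses) else NULL
  cohort_summary <- if (!is.null(cohort)) summarize_cohort(cohort) else NULL

  report <- structure(list(
    features = features, features_raw = features_raw, ttests = ttests,
    ssq_scores = ssq_scores, cohort_summary = cohort_summary,
    exclusions = exclusions
  ), class = "egg_study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      if (!is.null(df)) readr::write_csv(df, file.path(out_dir, name),
                                         progress = FALSE)
    }
    w(features, "features.csv")
    w(ttests, "ttests.csv")
    w(exclusions, "exclusions.csv")
    if (nrow(features) > 0) {
      w(dplyr::select(features, "subject", "label", "RMS_mV", "normo_pct"),
        "scatter_rms_normo.csv")
    }
    w(ssq_scores, "ssq_scores.csv")
    w(cohort_summary, "cohort_summary.csv")
  }
  report
}

# paired t tests per feature for each pair of conditions
study_ttests <- function(features) {
  if (nrow(features) == 0) return(tibble::tibble())
  conds <- intersect(c("rest", "motion_drive", "no_motion_drive"),
                     unique(features$label))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  feat_names <- c("DF_cpm", "MF_cpm", "CF", "RMS_mV", "normo_pct")
  purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(feat_names, function(fn) {
      wide <- features |>
        dplyr::filter(.data$label %in% pr, .data$valid) |>
        dplyr::select("subject", "label", dplyr::all_of(fn)) |>
        tidyr::pivot_wider(names_from = "label",
                           values_from = dplyr::all_of(fn)) |>
        tidyr::drop_na()
      base <- tibble::tibble(feature = fn, condition_a = pr[1],
                             condition_b = pr[2], n = nrow(wide))
      tt <- tryCatch(paired_t_test(wide[[pr[1]]], wide[[pr[2]]]),
                     error = function(e) NULL)
      if (is.null(tt)) {
        dplyr::bind_cols(base, tibble::tibble(t = NA_real_, df = NA_real_,
                                              p = NA_real_))
      } else {
        dplyr::bind_cols(base, tibble::tibble(t = tt$t, df = tt$df, p = tt$p))
      }
    })
  })
}

#' @export
print.egg_study_report <- function(x, ...) {
  cat(sprintf("<egg_study_report> %d subjects analysed, %d excluded\n",
              length(unique(x$features$subject)), nrow(x$exclusions)))
  if (nrow(x$ttests) > 0) {
    sig <- dplyr::filter(x$ttests, !is.na(.data$p), .data$p < 0.05)
    cat(sprintf("paired t tests: %d run, %d with p < 0.05\n",
                nrow(x$ttests), nrow(sig)))
  }
  invisible(x)
}
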