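#' Configuration for the synthetic EGG generator
#'
#' Describes a phenomenological multi-channel EGG source: a gastric slow
#' wave (a sinusoid of 200-500 µV peak-to-peak near 3 cpm, optionally
#' drifting or shifted into dysrhythmic episodes), physiological
#' contaminants (respiration, an ECG-like pulse train, baseline drift),
#' and motion-artifact spikes that hit all channels simultaneously --
#' unlike the gastric component, which reaches the three electrodes with
#' a short propagation lag.
#'
#' @param duration_s Recording duration in seconds.
#' @param fs_internal Dense generation rate in Hz (>= 100 for use with
#'   [acquire()]).
#' @param slow_wave List with `freq_cpm` (baseline dominant frequency,
#'   cycles per minute; default 3), `amp_uVpp` (peak-to-peak amplitude in
#'   µV; default 300, mid-range of the physiological 200-500 µV), and
#'   `freq_drift_cpm_per_min` (slow linear drift; default 0).
#' @param episodes `NULL` or a data frame with columns `start_s`, `end_s`,
#'   `target_freq_cpm`, `rms_scale`: dysrhythmic intervals in which the
#'   slow-wave frequency switches to the target (piecewise constant) and
#'   the amplitude is scaled with 5 s cosine ramps at the edges.
#' @param respiration,ecg,drift Contaminant settings, each a list:
#'   respiration `freq_hz` (default 0.3) and `amp_uV`; ecg `rate_hz`
#'   (default 1.2, aliasing to 0.8 Hz at a 2 Hz output rate) and
#'   `amp_uV`; drift `amp_uV` (standard deviation) and `corner_hz` of the
#'   shaping low-pass. Set an `amp_uV` to 0 to disable a contaminant.
#' @param spikes List with `count`, `amp_uV` (`NULL` = 5 x the slow-wave
#'   peak), `width_s` and `simultaneous` (inject at identical times on
#'   all channels when `TRUE`).
#' @param channel_model List with per-channel `gains` and `lag_s`
#'   (propagation delay of the gastric source; contaminant realisations
#'   are independent per channel and not lagged).
#' @param fsr_pulse_times Times (s) of pushbutton pulses to place on the
#'   FSR channel by [generate_recording()]; `NULL` for a silent FSR.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, fs_internal = 250,
                         slow_wave = list(), episodes = NULL,
                         respiration = list(), ecg = list(), drift = list(),
                         spikes = list(), channel_model = list(),
                         fsr_pulse_times = NULL, seed = 1L) {
  merge_defaults <- function(given, defaults) {
    utils::modifyList(defaults, as.list(given))
  }
  cfg <- list(
    duration_s = duration_s,
    fs_internal = fs_internal,
    slow_wave = merge_defaults(slow_wave, list(
      freq_cpm = 3, amp_uVpp = 300, freq_drift_cpm_per_min = 0)),
    episodes = if (is.null(episodes)) NULL else tibble::as_tibble(episodes),
    respiration = merge_defaults(respiration, list(freq_hz = 0.3, amp_uV = 20)),
    ecg = merge_defaults(ecg, list(rate_hz = 1.2, amp_uV = 50)),
    drift = merge_defaults(drift, list(amp_uV = 50, corner_hz = 0.005)),
    spikes = merge_defaults(spikes, list(
      count = 0, amp_uV = NULL, width_s = 1, simultaneous = TRUE)),
    channel_model = merge_defaults(channel_model, list(
      gains = c(1, 1, 1), lag_s = c(0, 0.5, 1))),
    fsr_pulse_times = fsr_pulse_times,
    seed = as.integer(seed)
  )
  if (duration_s <= 0 || fs_internal <= 0) {
    stop("duration_s and fs_internal must be positive", call. = FALSE)
  }
  if (!is.null(cfg$episodes)) {
    ep <- cfg$episodes
    if (!all(c("start_s", "end_s", "target_freq_cpm", "rms_scale") %in%
             names(ep))) {
      stop("episodes need start_s, end_s, target_freq_cpm, rms_scale",
           call. = FALSE)
    }
    if (any(ep$start_s < 0) || any(ep$end_s > duration_s)) {
      stop("configuration error: episode outside recording duration",
           call. = FALSE)
    }
  }
  structure(cfg, class = "synth_config")
}

# piecewise-constant slow-wave frequency (cpm) at times t
slow_wave_freq_cpm <- function(cfg, t) {
  f <- cfg$slow_wave$freq_cpm + cfg$slow_wave$freq_drift_cpm_per_min * t / 60
  if (!is.null(cfg$episodes)) {
    for (i in seq_len(nrow(cfg$episodes))) {
      ep <- cfg$episodes[i, ]
      f[t >= ep$start_s & t < ep$end_s] <- ep$target_freq_cpm
    }
  }
  f
}

# amplitude envelope with 5 s cosine ramps at episode edges
slow_wave_envelope <- function(cfg, t, ramp_s = 5) {
  env <- rep(1, length(t))
  if (is.null(cfg$episodes)) return(env)
  for (i in seq_len(nrow(cfg$episodes))) {
    ep <- cfg$episodes[i, ]
    if (ep$rms_scale == 1) next
    w <- rep(0, length(t))
    ramp_in <- t >= ep$start_s & t < pmin(ep$start_s + ramp_s, ep$end_s)
    ramp_out <- t >= pmax(ep$end_s - ramp_s, ep$start_s) & t < ep$end_s
    core <- t >= ep$start_s & t < ep$end_s
    w[core] <- 1
    w[ramp_in] <- 0.5 * (1 - cos(pi * (t[ramp_in] - ep$start_s) / ramp_s))
    w[ramp_out] <- pmin(w[ramp_out],
                        0.5 * (1 - cos(pi * (ep$end_s - t[ramp_out]) / ramp_s)))
    env <- env * (1 + (ep$rms_scale - 1) * w)
  }
  env
}

gaussian_pulse_train <- function(t, times, amp, sigma) {
  y <- numeric(length(t))
  for (tc in times) {
    win <- abs(t - tc) < 5 * sigma
    y[win] <- y[win] + amp * exp(-(t[win] - tc)^2 / (2 * sigma^2))
  }
  y
}

#' Generate dense per-channel EGG source signals with ground truth
#'
#' Builds the gastric slow wave (piecewise-constant frequency from the
#' baseline and dysrhythmic episodes, integrated to a continuous phase),
#' lags and scales it per channel, and adds independent contaminant
#' realisations and motion-artifact spikes per the configuration. All
#' randomness is drawn under the configured seed, in fixed order, so the
#' output is reproducible to the last bit.
#'
#' @param cfg A [synth_config()].
#' @return A list with `time` (s), `channels` (list of 3 µV vectors at
#'   `fs_internal`), `slow` (the noiseless lagged slow-wave component per
#'   channel), and `truth`: a list with `freq_segments` (tibble of
#'   constant-frequency intervals with `df_cpm` and `rms_scale`),
#'   `spike_markers` (artifact marker tibble) and `spike_times_s`.
#' @export
generate_sources <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs_internal
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  lags <- cfg$channel_model$lag_s
  gains <- cfg$channel_model$gains
  max_lag <- max(lags)
  n_pad <- ceiling(max_lag * fs)
  t_ext <- (seq_len(n + n_pad) - 1 - n_pad) / fs  # from -max_lag to duration

  f_cpm <- slow_wave_freq_cpm(cfg, pmax(t_ext, 0))
  phase <- 2 * pi * cumsum(f_cpm / 60) / fs
  env <- slow_wave_envelope(cfg, pmax(t_ext, 0))
  amp <- cfg$slow_wave$amp_uVpp / 2
  slow_ext <- amp * env * sin(phase)

  spikes <- cfg$spikes
  spike_amp <- if (is.null(spikes$amp_uV)) 5 * amp else spikes$amp_uV
  sigma_spike <- spikes$width_s / 4

  withr::with_seed(cfg$seed, {
    # spike times first so the count does not depend on contaminant draws
    margin <- spikes$width_s
    spike_times <- if (spikes$count > 0) {
      sort(stats::runif(spikes$count, margin,
                        max(cfg$duration_s - margin, margin)))
    } else {
      numeric()
    }
    per_channel_spikes <- lapply(1:3, function(i) {
      if (spikes$count == 0) return(numeric())
      if (spikes$simultaneous) spike_times else
        sort(stats::runif(spikes$count, margin,
                          max(cfg$duration_s - margin, margin)))
    })
    channels <- vector("list", 3)
    slow_ch <- vector("list", 3)
    for (i in 1:3) {
      shift <- n_pad - round(lags[i] * fs)
      slow_i <- gains[i] * slow_ext[seq_len(n) + shift]
      x <- slow_i
      if (cfg$respiration$amp_uV > 0) {
        x <- x + cfg$respiration$amp_uV *
          sin(2 * pi * cfg$respiration$freq_hz * t + stats::runif(1, 0, 2 * pi))
      }
      if (cfg$ecg$amp_uV > 0) {
        offset <- stats::runif(1, 0, 1 / cfg$ecg$rate_hz)
        beat_times <- seq(offset, cfg$duration_s, by = 1 / cfg$ecg$rate_hz)
        x <- x + gaussian_pulse_train(t, beat_times, cfg$ecg$amp_uV,
                                      0.040 / 2.355)
      }
      if (cfg$drift$amp_uV > 0) {
        w <- stats::rnorm(n)
        alpha <- exp(-2 * pi * cfg$drift$corner_hz / fs)
        d <- as.numeric(stats::filter(w * (1 - alpha), alpha,
                                      method = "recursive"))
        d_sd <- stats::sd(d)
        if (d_sd > 0) x <- x + cfg$drift$amp_uV * d / d_sd
      }
      if (length(per_channel_spikes[[i]]) > 0) {
        x <- x + gaussian_pulse_train(t, per_channel_spikes[[i]], spike_amp,
                                      sigma_spike)
      }
      channels[[i]] <- x
      slow_ch[[i]] <- slow_i
    }
  })

  spike_markers <- if (length(spike_times) > 0 && spikes$simultaneous) {
    markers(pmax(spike_times - spikes$width_s, 0),
            pmin(spike_times + spikes$width_s, cfg$duration_s), "artifact")
  } else if (spikes$count > 0) {
    all_t <- sort(unlist(per_channel_spikes))
    markers(pmax(all_t - spikes$width_s, 0),
            pmin(all_t + spikes$width_s, cfg$duration_s), "artifact")
  } else {
    markers()
  }

  list(
    time = t,
    channels = channels,
    slow = slow_ch,
    truth = list(
      freq_segments = truth_freq_segments(cfg),
      spike_markers = spike_markers,
      spike_times_s = spike_times
    )
  )
}

# constant-frequency intervals implied by baseline + episodes
truth_freq_segments <- function(cfg) {
  base <- cfg$slow_wave$freq_cpm
  if (is.null(cfg$episodes) || nrow(cfg$episodes) == 0) {
    return(tibble::tibble(start_s = 0, end_s = cfg$duration_s,
                          df_cpm = base, rms_scale = 1))
  }
  ep <- dplyr::arrange(cfg$episodes, .data$start_s)
  bounds <- sort(unique(c(0, ep$start_s, ep$end_s, cfg$duration_s)))
  purrr::map_dfr(seq_len(length(bounds) - 1), function(i) {
    mid <- (bounds[i] + bounds[i + 1]) / 2
    hit <- ep[ep$start_s <= mid & mid < ep$end_s, ]
    tibble::tibble(
      start_s = bounds[i], end_s = bounds[i + 1],
      df_cpm = if (nrow(hit) > 0) hit$target_freq_cpm[1] else base,
      rms_scale = if (nrow(hit) > 0) hit$rms_scale[1] else 1
    )
  })
}

#' Generate a sampled EGG recording through the front-end twin
#'
#' Passes each dense source channel through [acquire()] (amplifier, HP
#' and LP stages, 2 Hz subsampling), refers the result back to the input
#' by dividing by the amplifier gain (so stored samples stay in
#' physiological µV, with the gain recorded as metadata), and adds a
#' pushbutton FSR channel with 0.5 s pulses at the configured times.
#'
#' @param cfg A [synth_config()].
#' @param spec A [front_end_spec()].
#' @param fs_out Output sampling rate in Hz (default 2).
#' @param subject_id Subject identifier stored in the recording.
#' @return A list with `recording` (an [egg_recording()]) and `truth`
#'   (as in [generate_sources()]).
#' @export
generate_recording <- function(cfg, spec = front_end_spec(), fs_out = 2,
                               subject_id = "synth") {
  src <- generate_sources(cfg)
  G <- amplifier_gain(spec$Rg, spec$amp_gain_constant)
  chans <- lapply(src$channels, function(x) {
    acquire(x, cfg$fs_internal, spec, fs_out = fs_out) / G
  })
  n_out <- length(chans[[1]])
  t_out <- (seq_len(n_out) - 1) / fs_out
  fsr <- numeric(n_out)
  for (tp in cfg$fsr_pulse_times %||% numeric()) {
    fsr[t_out >= tp & t_out < tp + 0.5] <- 1
  }
  list(
    recording = egg_recording(chans, fsr, fs_out, subject_id, gain = G),
    truth = src$truth
  )
}
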