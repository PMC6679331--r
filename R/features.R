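#' Gastric rhythm bands
#'
#' Frequency bands of gastric myoelectrical activity in cycles per
#' minute (1 cpm = 1/60 Hz): bradygastric below 2 cpm, normogastric
#' 2-4 cpm (the healthy slow-wave range), tachygastric 4-10 cpm. The
#' analysis band is the band-pass passband, 0.03-0.25 Hz (1.8-15 cpm);
#' outside it the signal is filter-shaped rather than physiological.
#'
#' @param analysis_band_hz Two-element numeric, Hz.
#' @return A list of class `rhythm_bands`.
#' @export
rhythm_bands <- function(analysis_band_hz = c(0.03, 0.25)) {
  structure(list(
    bradygastric_cpm = c(0, 2),
    normogastric_cpm = c(2, 4),
    tachygastric_cpm = c(4, 10),
    analysis_band_hz = analysis_band_hz
  ), class = "rhythm_bands")
}

#' Magnitude spectrum of an EGG segment
#'
#' Removes the mean, zero-pads to `pad_factor` times the segment length,
#' takes the FFT and returns magnitude and power per bin restricted to
#' the analysis band. Attributes `fs`, `n` (segment length) and `n_fft`
#' are attached so band power can be related to time-domain power
#' (Parseval).
#'
#' @param x Segment samples (µV), at least 60 samples (30 s at 2 Hz).
#' @param fs Sampling rate in Hz.
#' @param bands A [rhythm_bands()].
#' @param pad_factor Zero-padding factor (default 4).
#' @return A tibble of class `egg_spectrum` with columns `freq_hz`,
#'   `freq_cpm`, `magnitude`, `power`.
#' @export
compute_spectrum <- function(x, fs, bands = rhythm_bands(), pad_factor = 4) {
  if (length(x) < 60) {
    stop("length error: segment must have at least 60 samples", call. = FALSE)
  }
  n <- length(x)
  n_fft <- pad_factor * n
  xc <- c(x - mean(x), numeric(n_fft - n))
  X <- stats::fft(xc)
  k <- seq_len(floor(n_fft / 2) + 1)
  freq <- (k - 1) * fs / n_fft
  lo <- bands$analysis_band_hz[1]
  hi <- bands$analysis_band_hz[2]
  keep <- freq >= lo & freq <= hi
  out <- tibble::tibble(
    freq_hz = freq[keep],
    freq_cpm = freq[keep] * 60,
    magnitude = Mod(X[k][keep]),
    power = Mod(X[k][keep])^2
  )
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  attr(out, "n_fft") <- n_fft
  attr(out, "band_hz") <- c(lo, hi)
  attr(out, "method") <- "fft"
  class(out) <- c("egg_spectrum", class(out))
  out
}

#' Dominant frequency (DF)
#'
#' Frequency of the maximum magnitude peak within the analysis band, in
#' cpm, refined by parabolic interpolation around the peak bin. Ties go
#' to the lowest frequency.
#'
#' @param spec A spectrum tibble with `freq_cpm` and `magnitude`.
#' @return DF in cpm.
#' @export
dominant_frequency <- function(spec) {
  m <- spec$magnitude
  if (length(m) == 0) stop("empty spectrum", call. = FALSE)
  i <- which(m == max(m))[1]
  f <- spec$freq_cpm
  if (i > 1 && i < length(m)) {
    denom <- m[i - 1] - 2 * m[i] + m[i + 1]
    if (denom < 0) {
      delta <- 0.5 * (m[i - 1] - m[i + 1]) / denom
      delta <- max(min(delta, 0.5), -0.5)
      return(f[i] + delta * (f[i + 1] - f[i]))
    }
  }
  f[i]
}

#' Median frequency (MF)
#'
#' Frequency dividing the band-limited power spectrum into two halves of
#' equal integral, with linear interpolation of the cumulative power
#' between bins. When the cumulative curve is flat at exactly half the
#' total (two equal-power peaks), the midpoint of the flat region is
#' returned.
#'
#' @param spec A spectrum tibble with `freq_cpm` and `power`.
#' @return MF in cpm.
#' @export
median_frequency <- function(spec) {
  p <- spec$power
  f <- spec$freq_cpm
  total <- sum(p)
  if (total <= 0) stop("degenerate error: zero band power", call. = FALSE)
  cum <- cumsum(p)
  half <- total / 2
  # crossing from below: after the last bin with cum < half
  i_lo <- max(which(cum < half), 0)
  # crossing from above: at the first bin with cum > half
  i_hi <- min(which(cum > half))
  interp <- function(i) {
    # crossing inside bin i+1, between cum[i] (or 0) and cum[i+1]
    c0 <- if (i == 0) 0 else cum[i]
    f0 <- if (i == 0) f[1] - (f[2] - f[1]) else f[i]
    f1 <- f[i + 1]
    f0 + (half - c0) / (cum[i + 1] - c0) * (f1 - f0)
  }
  f_lo <- interp(i_lo)
  f_hi <- if (i_hi == i_lo + 1) f_lo else interp(i_hi - 1)
  (f_lo + f_hi) / 2
}

#' Crest factor (CF)
#'
#' Peak magnitude of the spectrum divided by the RMS of the spectrum
#' over the analysis band (default), or by the time-domain signal RMS
#' when `denominator = "signal"`. High for a single clean rhythm, near 1
#' for broadband content.
#'
#' @param spec A spectrum tibble with `magnitude`.
#' @param denominator `"spectrum"` (default) or `"signal"`.
#' @param x Time-domain segment (µV), required for `"signal"`.
#' @return Dimensionless crest factor.
#' @export
crest_factor <- function(spec, denominator = c("spectrum", "signal"),
                         x = NULL) {
  denominator <- match.arg(denominator)
  m <- spec$magnitude
  if (length(m) == 0 || all(m == 0)) {
    stop("degenerate error: zero spectrum", call. = FALSE)
  }
  if (denominator == "spectrum") {
    max(m) / sqrt(mean(m^2))
  } else {
    if (is.null(x)) stop("x required for signal-RMS denominator", call. = FALSE)
    max(m) / sqrt(mean(x^2))
  }
}

#' Root mean square of a segment, in millivolts
#'
#' Samples are stored in µV; the RMS is reported in mV (division by
#' exactly 1000 at this boundary).
#'
#' @param x Segment samples (µV), non-empty.
#' @return RMS in mV.
#' @export
rms_mv <- function(x) {
  if (length(x) == 0) stop("length error: empty segment", call. = FALSE)
  sqrt(mean(x^2)) / 1000
}

#' Welch power spectral density
#'
#' Mean periodogram over Hann-tapered, mean-removed, 50%-overlapping
#' windows (defaults: 120 s windows), the standard Welch estimate.
#'
#' @param x Samples (µV).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 120, resolving
#'   0.5 cpm while fitting at least two windows in a 5-min segment).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @return A tibble with `freq_hz`, `freq_cpm`, `psd` (µV²/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 120, overlap = 0.5) {
  wlen <- round(window_s * fs)
  step <- max(1, round(wlen * (1 - overlap)))
  n <- length(x)
  if (n < wlen + step) {
    stop("length error: segment shorter than two Welch windows",
         call. = FALSE)
  }
  starts <- seq(1, n - wlen + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)))
  scale <- fs * sum(w^2)
  k <- seq_len(floor(wlen / 2) + 1)
  psd <- rowMeans(vapply(starts, function(s0) {
    seg <- x[s0:(s0 + wlen - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[k])^2 / scale
    # one-sided: double all but DC and (for even wlen) Nyquist
    dbl <- rep(2, length(k))
    dbl[1] <- 1
    if (wlen %% 2 == 0) dbl[length(k)] <- 1
    P * dbl
  }, numeric(length(k))))
  freq <- (k - 1) * fs / wlen
  tibble::tibble(freq_hz = freq, freq_cpm = freq * 60, psd = psd)
}

#' Normogastric power fraction
#'
#' Percentage of Welch PSD power in the normogastric band (2-4 cpm)
#' relative to the analysis band (0.03-0.25 Hz by default), the share of
#' spectral power carried by the healthy slow-wave rhythm.
#'
#' @param x Segment samples (µV), at least two Welch windows long.
#' @param fs Sampling rate in Hz.
#' @param bands A [rhythm_bands()].
#' @param window_s,overlap Welch parameters, see [welch_psd()].
#' @return Percentage in `[0, 100]`.
#' @export
normogastric_power_fraction <- function(x, fs, bands = rhythm_bands(),
                                        window_s = 120, overlap = 0.5) {
  psd <- welch_psd(x, fs, window_s = window_s, overlap = overlap)
  lo <- bands$analysis_band_hz[1]
  hi <- bands$analysis_band_hz[2]
  in_band <- psd$freq_hz >= lo & psd$freq_hz <= hi
  normo <- psd$freq_cpm >= bands$normogastric_cpm[1] &
    psd$freq_cpm <= bands$normogastric_cpm[2]
  denom <- sum(psd$psd[in_band])
  if (denom <= 0) stop("degenerate error: zero band power", call. = FALSE)
  100 * sum(psd$psd[in_band & normo]) / denom
}

#' Classify a frequency into a gastric rhythm band
#'
#' Below 2 cpm is bradygastric, 2-4 cpm (boundaries included) is
#' normogastric, above 4 up to 10 cpm is tachygastric, beyond 10 cpm is
#' out of band.
#'
#' @param freq_cpm Frequency (cpm), non-negative; vectorised.
#' @return Character vector of band names.
#' @export
classify_rhythm <- function(freq_cpm) {
  if (any(freq_cpm < 0)) {
    stop("domain error: negative frequency", call. = FALSE)
  }
  dplyr::case_when(
    freq_cpm < 2 ~ "bradygastric",
    freq_cpm <= 4 ~ "normogastric",
    freq_cpm <= 10 ~ "tachygastric",
    TRUE ~ "out_of_band"
  )
}

#' All five slow-wave features for one segment
#'
#' Computes dominant frequency, median frequency, crest factor, RMS and
#' the normogastric power fraction of one (band-passed, artifact-free)
#' segment, plus the rhythm-band classification of the DF.
#'
#' @param x Segment samples (µV).
#' @param fs Sampling rate in Hz.
#' @param bands A [rhythm_bands()].
#' @param pad_factor FFT zero-padding factor.
#' @param welch_window_s,welch_overlap Welch parameters.
#' @param cf_denominator Crest-factor denominator, see [crest_factor()].
#' @return One-row tibble: `DF_cpm`, `MF_cpm`, `CF`, `RMS_mV`,
#'   `normo_pct`, `rhythm`.
#' @export
#' @examples
#' t <- seq(0, 299.5, by = 0.5)
#' extract_features(150 * sin(2 * pi * 0.05 * t), fs = 2)
extract_features <- function(x, fs, bands = rhythm_bands(), pad_factor = 4,
                             welch_window_s = 120, welch_overlap = 0.5,
                             cf_denominator = "spectrum") {
  spec <- compute_spectrum(x, fs, bands, pad_factor)
  tibble::tibble(
    DF_cpm = dominant_frequency(spec),
    MF_cpm = median_frequency(spec),
    CF = crest_factor(spec, denominator = cf_denominator, x = x),
    RMS_mV = rms_mv(x),
    normo_pct = normogastric_power_fraction(
      x, fs, bands, window_s = welch_window_s, overlap = welch_overlap),
    rhythm = classify_rhythm(DF_cpm)
  )
}
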