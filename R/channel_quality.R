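#' Amplitude range of a channel
#'
#' Peak-to-peak amplitude, `max - min`; a channel with non-physiological
#' spikes shows an inflated range.
#'
#' @param x Numeric vector (µV), non-empty.
#' @return Range in µV.
#' @export
amplitude_range <- function(x) {
  if (length(x) == 0) stop("length error: empty channel", call. = FALSE)
  max(x) - min(x)
}

#' Mean-of-squares signal power
#'
#' @param x Numeric vector (µV), non-empty.
#' @return Power in µV².
#' @export
signal_power <- function(x) {
  if (length(x) == 0) stop("length error: empty channel", call. = FALSE)
  mean(x^2)
}

#' Automatic selection of the least-affected channel
#'
#' Two-step rule applied to the band-passed channels: (1) a channel is
#' eliminated when its amplitude range is at least `threshold` times the
#' reference range of the other channels ("100% higher" at the default
#' threshold of 2); (2) among the survivors the channel with the lowest
#' mean-of-squares power is chosen, ties going to the lowest index. With
#' the default `others = "min"` reference, the channel with the smallest
#' range can never be eliminated, so a survivor always exists.
#'
#' @param channels A list of three equal-length numeric vectors, or an
#'   [egg_recording()] whose EGG channels are used.
#' @param threshold Elimination ratio (> 1); default 2.
#' @param others How to summarise the other channels' ranges for the
#'   comparison: `"min"` (default, strictest), `"mean"` or `"max"`.
#' @return An object of class `egg_selection`: list with `chosen`
#'   (1-based index), `eliminated` (integer vector), `ranges` and
#'   `powers` (per channel).
#' @export
#' @examples
#' chs <- list(sin(1:100), 1.1 * sin(1:100), 5 * sin(1:100))
#' select_channel(chs)
select_channel <- function(channels, threshold = 2, others = c("min", "mean", "max")) {
  others <- match.arg(others)
  if (inherits(channels, "egg_recording")) {
    channels <- recording_channels(channels)
  }
  stopifnot(length(channels) == 3,
            length(unique(lengths(channels))) == 1)
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  ranges <- vapply(channels, amplitude_range, numeric(1))
  powers <- vapply(channels, signal_power, numeric(1))
  ref_fun <- switch(others, min = min, mean = mean, max = max)
  eliminated <- which(vapply(1:3, function(i) {
    ranges[i] >= threshold * ref_fun(ranges[-i])
  }, logical(1)))
  survivors <- setdiff(1:3, eliminated)
  chosen <- survivors[which.min(powers[survivors])]
  structure(list(chosen = chosen, eliminated = eliminated,
                 ranges = ranges, powers = powers),
            class = "egg_selection")
}

#' @export
print.egg_selection <- function(x, ...) {
  cat(sprintf("<egg_selection> chosen channel %d; eliminated: %s\n",
              x$chosen,
              if (length(x$eliminated) == 0) "none"
              else paste(x$eliminated, collapse = ", ")))
  print(tibble::tibble(channel = 1:3, range_uV = x$ranges,
                       power_uV2 = x$powers))
  invisible(x)
}

#' @method tidy egg_selection
#' @export
tidy.egg_selection <- function(x, ...) {
  tibble::tibble(channel = 1:3, range_uV = x$ranges, power_uV2 = x$powers,
                 eliminated = 1:3 %in% x$eliminated,
                 chosen = 1:3 == x$chosen)
}

#' Propose markers for simultaneous motion-artifact spikes
#'
#' Sudden movements induce large spikes on all channels at the same time,
#' unlike gastric activity which propagates with an inter-channel lag.
#' This pre-screen flags windows in which every channel exceeds a robust
#' z-score threshold (median/MAD) and merges adjacent flagged windows
#' into proposed artifact intervals. The z-score is computed on the
#' first difference of each channel, which suppresses the slow wave
#' (a few tens of µV per sample at 3 cpm) while a spike keeps its full
#' excursion, so the screen works on raw or band-passed channels alike.
#' It is intended to propose markers for human review, never to excise
#' automatically.
#'
#' @param channels List of three equal-length numeric vectors, or an
#'   [egg_recording()].
#' @param fs Sampling rate in Hz.
#' @param z_threshold Robust z-score threshold (default 5).
#' @param window_s Window length in seconds (default 2).
#' @return An artifact marker tibble (possibly empty).
#' @export
detect_simultaneous_spikes <- function(channels, fs, z_threshold = 5,
                                       window_s = 2) {
  if (inherits(channels, "egg_recording")) {
    fs <- channels$fs
    channels <- recording_channels(channels)
  }
  stopifnot(length(channels) == 3)
  z <- lapply(channels, function(x) {
    d <- c(0, diff(x))
    m <- stats::median(d)
    s <- stats::mad(d)
    if (s == 0) {
      stop("degenerate-signal error: zero MAD on a channel", call. = FALSE)
    }
    abs(d - m) / s
  })
  n <- length(z[[1]])
  wlen <- max(1, round(window_s * fs))
  starts <- seq(1, n, by = wlen)
  flagged <- vapply(starts, function(s0) {
    idx <- s0:min(s0 + wlen - 1, n)
    all(vapply(z, function(zc) max(zc[idx]) > z_threshold, logical(1)))
  }, logical(1))
  if (!any(flagged)) return(markers())
  runs <- rle(flagged)
  ends_run <- cumsum(runs$lengths)
  starts_run <- ends_run - runs$lengths + 1
  keep <- which(runs$values)
  markers(
    start_s = (starts[starts_run[keep]] - 1) / fs,
    end_s = pmin((starts[ends_run[keep]] - 1 + wlen) / fs, n / fs),
    label = "artifact"
  )
}

#' Excise marked artifact intervals from a channel
#'
#' Samples falling inside `artifact` intervals (closed-open in time) are
#' deleted and the remainder is concatenated in order, exactly as when
#' marked movement artifacts are removed from an EGG record before
#' feature extraction. The total excised duration is attached as the
#' `excised_s` attribute.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param mk Marker tibble; only rows labelled `artifact` are applied.
#' @return The shortened vector with attribute `excised_s`.
#' @export
excise <- function(x, fs, mk) {
  mk <- normalize_markers(mk)
  mk <- mk[mk$label == "artifact", ]
  n <- length(x)
  dur <- n / fs
  if (nrow(mk) == 0) {
    return(structure(x, excised_s = 0))
  }
  if (any(mk$end_s > dur + 1e-9)) {
    stop("bounds error: marker beyond record end", call. = FALSE)
  }
  t <- (seq_len(n) - 1) / fs
  drop <- rep(FALSE, n)
  for (i in seq_len(nrow(mk))) {
    drop <- drop | (t >= mk$start_s[i] & t < mk$end_s[i])
  }
  structure(x[!drop], excised_s = sum(drop) / fs)
}
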