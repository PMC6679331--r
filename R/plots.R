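#' Plot a front-end frequency response
#'
#' Log-frequency magnitude plot of the acquisition chain, the same view
#' as a swept-sine bench characterisation.
#'
#' @param object An `egg_freq_response` tibble from
#'   [frequency_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot egg_freq_response
#' @export
autoplot.egg_freq_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_hz, .data$magnitude_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude (dB)",
                  title = "Front-end frequency response") +
    ggplot2::theme_minimal()
}

#' Plot an EGG magnitude spectrum
#'
#' @param object An `egg_spectrum` tibble from [compute_spectrum()].
#' @param ... Unused.
#' @return A ggplot object with the normogastric band shaded.
#' @method autoplot egg_spectrum
#' @export
autoplot.egg_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_cpm, .data$magnitude)) +
    ggplot2::annotate("rect", xmin = 2, xmax = 4, ymin = -Inf, ymax = Inf,
                      alpha = 0.12, fill = "seagreen") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (cpm)", y = "FFT magnitude",
                  title = "EGG segment spectrum",
                  subtitle = "Shaded: normogastric band (2-4 cpm)") +
    ggplot2::theme_minimal()
}

#' Per-condition feature distribution plots
#'
#' Box plots of one feature across the session conditions (resting,
#' motion drive, no-motion drive), the standard presentation of
#' segment-level EGG features.
#'
#' @param features Feature tibble from [extract_segment_features()] or
#'   [run_study()] (needs `label` and the feature column).
#' @param feature Column to plot (default `"RMS_mV"`).
#' @return A ggplot object.
#' @export
plot_feature_by_condition <- function(features, feature = "RMS_mV") {
  stopifnot(feature %in% names(features))
  df <- dplyr::filter(features, .data$valid)
  df$label <- factor(df$label, levels = segment_label_order)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data[[feature]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' Scatter plot of RMS against normogastric power fraction
#'
#' One point per analysed segment, coloured by condition; when an
#' uncorrected feature table is supplied, arrows join each segment's
#' uncorrected value to its artifact-excised value.
#'
#' @param features Excised feature tibble (with `subject`).
#' @param features_raw Optional matching uncorrected tibble.
#' @return A ggplot object.
#' @export
plot_rms_normo <- function(features, features_raw = NULL) {
  df <- dplyr::filter(features, .data$valid)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$RMS_mV, .data$normo_pct,
                                        colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "RMS (mV)", y = "Normogastric power (%)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
  if (!is.null(features_raw) && nrow(features_raw) > 0) {
    joined <- dplyr::inner_join(
      dplyr::filter(features_raw, .data$valid),
      df, by = c("subject", "label"), suffix = c("_raw", "")
    )
    p <- p + ggplot2::geom_segment(
      data = joined,
      ggplot2::aes(x = .data$RMS_mV_raw, y = .data$normo_pct_raw,
                   xend = .data$RMS_mV, yend = .data$normo_pct,
                   colour = .data$label),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.6)
  }
  p
}
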