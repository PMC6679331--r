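#' Analog front-end specification
#'
#' Component values for one EGG acquisition channel: an instrumentation
#' amplifier whose gain follows `G = 1 + amp_gain_constant / Rg`, a
#' second-order unity-gain Sallen-Key high-pass stage (equal `R_hp`,
#' `C_hp`), and a matching low-pass stage (`R_lp`, `C_lp`). With equal
#' components and unity gain each stage has two coincident real poles
#' (Q = 1/2) at `1 / (2 pi R C)`.
#'
#' Defaults correspond to the reference three-channel EGG device:
#' Rg = 50 ohm (gain 1001, nominally 1000), high-pass 10 Mohm / 1 uF
#' (cutoff 0.0159 Hz, i.e. 0.016 Hz) and low-pass 15 kohm / 2.2 uF
#' (cutoff 4.82 Hz).
#'
#' @param Rg Gain-set resistor (ohm).
#' @param R_hp,C_hp High-pass stage resistance (ohm) and capacitance (F).
#' @param R_lp,C_lp Low-pass stage resistance (ohm) and capacitance (F).
#' @param amp_gain_constant Internal gain resistance of the
#'   instrumentation amplifier (ohm); 50 kohm for the INA114 gain law.
#' @return An object of class `front_end_spec`.
#' @export
front_end_spec <- function(Rg = 50, R_hp = 10e6, C_hp = 1e-6,
                           R_lp = 15e3, C_lp = 2.2e-6,
                           amp_gain_constant = 50e3) {
  vals <- c(Rg = Rg, R_hp = R_hp, C_hp = C_hp, R_lp = R_lp, C_lp = C_lp,
            amp_gain_constant = amp_gain_constant)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all front-end component values must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "front_end_spec")
}

#' @export
print.front_end_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<front_end_spec> gain %.0f; HP pole %.4g Hz (%.3g ohm, %.3g F); ",
           "LP pole %.4g Hz (%.3g ohm, %.3g F)\n"),
    amplifier_gain(x$Rg, x$amp_gain_constant),
    pole_frequency(x$R_hp, x$C_hp), x$R_hp, x$C_hp,
    pole_frequency(x$R_lp, x$C_lp), x$R_lp, x$C_lp))
  invisible(x)
}

#' RC pole frequency
#'
#' `f = 1 / (2 pi R C)`, the cutoff of an equal-component unity-gain
#' Sallen-Key stage (coincident real poles).
#'
#' @param R Resistance (ohm), positive.
#' @param C Capacitance (F), positive.
#' @return Frequency in Hz.
#' @export
#' @examples
#' pole_frequency(10e6, 1e-6)   # 0.0159 Hz -> rounds to 0.016
#' pole_frequency(15e3, 2.2e-6) # 4.82 Hz
pole_frequency <- function(R, C) {
  if (any(R <= 0) || any(C <= 0)) {
    stop("R and C must be positive", call. = FALSE)
  }
  1 / (2 * pi * R * C)
}

#' Instrumentation-amplifier gain
#'
#' `G = 1 + amp_gain_constant / Rg`; with Rg = 50 ohm and the 50 kohm
#' INA114 constant this gives 1001 (nominally 1000).
#'
#' @param Rg Gain-set resistor (ohm), positive.
#' @param amp_gain_constant Amplifier gain constant (ohm).
#' @return Dimensionless gain.
#' @export
amplifier_gain <- function(Rg, amp_gain_constant = 50e3) {
  if (any(Rg <= 0)) stop("Rg must be positive", call. = FALSE)
  1 + amp_gain_constant / Rg
}

# complex front-end transfer function at frequency f (Hz)
frontend_H <- function(spec, f) {
  G <- amplifier_gain(spec$Rg, spec$amp_gain_constant)
  w_hp <- 2 * pi * pole_frequency(spec$R_hp, spec$C_hp)
  w_lp <- 2 * pi * pole_frequency(spec$R_lp, spec$C_lp)
  s <- 1i * 2 * pi * f
  G * (s / (s + w_hp))^2 * (w_lp / (s + w_lp))^2
}

#' Front-end frequency response
#'
#' Magnitude of the amplifier + HP + LP cascade
#' `H(s) = G * s^2/(s + w_hp)^2 * w_lp^2/(s + w_lp)^2` on a log-spaced
#' frequency grid, emulating a swept-sine characterisation of the device
#' (by default 41 points from 0.01 to 100 Hz).
#'
#' @param spec A [front_end_spec()].
#' @param freqs Optional vector of frequencies in Hz (positive,
#'   increasing); overrides the grid parameters.
#' @param n_points,fmin,fmax Log-spaced grid definition used when
#'   `freqs` is `NULL`.
#' @return A tibble of class `egg_freq_response` with columns `freq_hz`
#'   and `magnitude_db`.
#' @export
#' @examples
#' frequency_response(front_end_spec())
frequency_response <- function(spec, freqs = NULL, n_points = 41,
                               fmin = 0.01, fmax = 100) {
  stopifnot(inherits(spec, "front_end_spec"))
  if (is.null(freqs)) {
    freqs <- 10^seq(log10(fmin), log10(fmax), length.out = n_points)
  }
  if (any(freqs <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(
    freq_hz = freqs,
    magnitude_db = 20 * log10(Mod(frontend_H(spec, freqs)))
  )
  class(out) <- c("egg_freq_response", class(out))
  out
}

# bilinear-transform biquad for a double real pole at w (rad/s);
# kind "hp" has zeros at z = 1, "lp" at z = -1
biquad_coincident <- function(w, fs, kind) {
  c2 <- 2 * fs
  a <- c((c2 + w)^2, 2 * (c2 + w) * (w - c2), (w - c2)^2)
  b <- switch(kind,
    hp = c2^2 * c(1, -2, 1),
    lp = w^2 * c(1, 2, 1)
  )
  list(b = b / a[1], a = a / a[1])
}

#' Simulate acquisition through the analog chain
#'
#' Applies the discretised front-end transfer function (gain, HP and LP
#' biquads obtained by bilinear transform at the internal rate) to a
#' densely sampled source signal, then decimates to the output rate by
#' plain subsampling -- deliberately with no extra digital anti-aliasing,
#' mimicking the hardware whose analog low-pass near 4.8 Hz does not
#' prevent aliasing at a 2 Hz output rate. Optionally quantises to a
#' 16-bit ADC over a configurable full-scale range.
#'
#' @param x Source signal in µV, sampled at `fs_internal`.
#' @param fs_internal Internal (dense) sampling rate in Hz; must be at
#'   least `50 * fs_out` and an integer multiple of `fs_out`.
#' @param spec A [front_end_spec()].
#' @param fs_out Output sampling rate in Hz (default 2).
#' @param quantize If `TRUE`, quantise the post-gain signal to 16 bits.
#' @param full_scale_v Full-scale range of the ADC in volts (± this value)
#'   used when `quantize = TRUE`.
#' @return Numeric vector of post-gain samples (µV) at `fs_out`.
#' @export
acquire <- function(x, fs_internal, spec = front_end_spec(), fs_out = 2,
                    quantize = FALSE, full_scale_v = 5) {
  stopifnot(inherits(spec, "front_end_spec"))
  ratio <- fs_internal / fs_out
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("configuration error: fs_internal must be divisible by fs_out",
         call. = FALSE)
  }
  if (fs_internal < 50 * fs_out) {
    stop("configuration error: fs_internal must be >= 50 * fs_out",
         call. = FALSE)
  }
  G <- amplifier_gain(spec$Rg, spec$amp_gain_constant)
  hp <- biquad_coincident(2 * pi * pole_frequency(spec$R_hp, spec$C_hp),
                          fs_internal, "hp")
  lp <- biquad_coincident(2 * pi * pole_frequency(spec$R_lp, spec$C_lp),
                          fs_internal, "lp")
  y <- G * x
  y <- as.numeric(signal::filter(hp$b, hp$a, y))
  y <- as.numeric(signal::filter(lp$b, lp$a, y))
  if (quantize) {
    fs_uV <- full_scale_v * 1e6
    step <- 2 * fs_uV / 2^16
    y <- pmin(pmax(round(y / step) * step, -fs_uV), fs_uV - step)
  }
  y[seq(1, length(y), by = round(ratio))]
}
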