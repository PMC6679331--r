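# shared fixtures built in code

sine_uV <- function(freq_hz, amp_uV = 150, duration_s = 300, fs = 2,
                    phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  amp_uV * sin(2 * pi * freq_hz * t + phase)
}

small_recording <- function(n = 120, fs = 2, seed = 1) {
  withr::with_seed(seed, {
    chs <- replicate(3, stats::rnorm(n, sd = 100), simplify = FALSE)
    fsr <- abs(stats::rnorm(n, sd = 0.01))
  })
  egg_recording(chs, fsr, fs, subject_id = "T1", gain = 1001)
}

# amplitude of a known-frequency sinusoid via least squares
fitted_amplitude <- function(y, fs, f) {
  t <- (seq_along(y) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::coef(stats::lm(y ~ X - 1))
  sqrt(sum(cf^2))
}
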