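#' Synthetic multi-tone cosine signal
#'
#' Generates `sum_j amps[j] * cos(2 * pi * freqs[j] * k / fs)` on the grid
#' `k = 1..n`, i.e. the time axis runs from `1/fs` to `n/fs` inclusive. The
#' default arguments produce the standard three-tone test signal
#' `cos(2*2*pi*t) + cos(12*2*pi*t)/2 + cos(36*2*pi*t)/4` on 1024 points of
#' one second, whose constituents (2, 12, 36 Hz) sit on exact FFT bins.
#'
#' @param freqs Tone frequencies in Hz, all below `fs/2`.
#' @param amps Tone amplitudes, same length as `freqs`.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @return An [eeg_signal()] tibble.
#' @examples
#' y <- synth_multitone()
#' envelope_entropy(y)
#' @export
synth_multitone <- function(freqs = c(2, 12, 36), amps = c(1, 1 / 2, 1 / 4),
                            n = 1024, fs = 1024) {
  if (length(freqs) != length(amps) || !length(freqs)) {
    abort("`freqs` and `amps` must have equal, positive length.")
  }
  if (n < 1) abort("`n` must be at least 1.")
  if (any(freqs >= fs / 2)) {
    abort("all tone frequencies must lie below the Nyquist frequency fs/2.")
  }
  k <- seq_len(n)
  y <- rowSums(vapply(seq_along(freqs),
                      function(j) amps[j] * cos(2 * pi * freqs[j] * k / fs),
                      numeric(n)))
  eeg_signal(y, fs = fs, source = "synth_multitone")
}

# Band-limited Gaussian noise via an FFT brick-wall mask on [f_lo, f_hi] Hz,
# rescaled to unit variance (zero vector if the band holds no bins).
band_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  f <- fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided |frequency| of each bin
  mask <- freq >= f_lo & freq <= f_hi
  if (!any(mask)) return(numeric(n))
  x <- Re(fft(f * mask, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else numeric(n)
}

#' Synthetic anesthesia-like EEG
#'
#' Emulates the spectral structure of frontal EEG under propofol general
#' anesthesia: slow-delta activity (band-limited noise in 0.5--4 Hz), a
#' narrowband alpha component centered near 11 Hz (bandwidth `alpha_bw`),
#' and broadband noise. Component variances match the requested powers, so
#' the generator is a controllable stand-in for maintenance-phase recordings
#' when real data are unavailable.
#'
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz (default 128).
#' @param delta_power Variance of the 0.5--4 Hz component.
#' @param alpha_power Variance of the narrowband alpha component.
#' @param alpha_center Center of the alpha band in Hz (default 11, must be
#'   below `fs/2`).
#' @param alpha_bw Alpha bandwidth in Hz (default 2).
#' @param noise_power Variance of the broadband noise floor.
#' @param seed Integer seed; when given, generation is bit-reproducible and
#'   the caller's RNG state is untouched.
#' @return An [eeg_signal()] tibble.
#' @examples
#' eeg <- synth_anesthesia_eeg(duration = 16, seed = 1)
#' @export
synth_anesthesia_eeg <- function(duration = 60, fs = 128,
                                 delta_power = 1, alpha_power = 1,
                                 alpha_center = 11, alpha_bw = 2,
                                 noise_power = 0.05, seed = NULL) {
  if (duration <= 0 || fs <= 0) abort("`duration` and `fs` must be positive.")
  if (any(c(delta_power, alpha_power, noise_power) < 0)) {
    abort("component powers must be non-negative.")
  }
  if (alpha_center >= fs / 2) {
    abort("`alpha_center` must lie below the Nyquist frequency fs/2.")
  }
  n <- round(duration * fs)
  gen <- function() {
    y <- numeric(n)
    if (delta_power > 0) {
      y <- y + sqrt(delta_power) * band_noise(n, fs, 0.5, 4)
    }
    if (alpha_power > 0) {
      y <- y + sqrt(alpha_power) *
        band_noise(n, fs, alpha_center - alpha_bw / 2, alpha_center + alpha_bw / 2)
    }
    if (noise_power > 0) y <- y + stats::rnorm(n, sd = sqrt(noise_power))
    y
  }
  y <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  eeg_signal(y, fs = fs, source = "synth_anesthesia_eeg")
}
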