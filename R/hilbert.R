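#' Discrete analytic signal
#'
#' One-sided-spectrum construction of the analytic signal `x + i H[x]`: the
#' FFT of `x` is doubled on positive-frequency bins, zeroed on negative ones
#' (DC and, for even lengths, the Nyquist bin kept with unit weight), and
#' inverse-transformed. The real part equals `x` exactly; the modulus is the
#' envelope and the phase derivative the instantaneous frequency.
#'
#' @param x Real numeric vector (or [eeg_signal()]), at least 4 samples.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  s <- resolve_signal(x)
  x <- s$samples
  n <- length(x)
  if (n < 4) abort("signal must have at least 4 samples.")
  if (any(!is.finite(x))) abort("signal contains non-finite samples.")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(z))  # pin the real part to the input
}

#' Hilbert envelope
#'
#' Modulus of the [analytic_signal()], `sqrt(x^2 + H[x]^2)`: the
#' instantaneous amplitude of a narrowband signal.
#'
#' @inheritParams analytic_signal
#' @return Non-negative numeric vector.
#' @export
envelope <- function(x) {
  Mod(analytic_signal(x))
}

#' Instantaneous frequency
#'
#' Derivative of the unwrapped analytic phase, divided by `2 pi`: central
#' differences in the interior, one-sided differences at the endpoints.
#' Samples where the envelope is exactly zero (undefined phase) report 0 Hz.
#'
#' @inheritParams analytic_signal
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of instantaneous frequencies in Hz.
#' @export
instantaneous_frequency <- function(x, fs = NULL) {
  s <- resolve_signal(x, fs)
  if (is.na(s$fs)) abort("sampling rate unknown; pass `fs`.")
  n <- length(s$samples)
  if (n < 8) abort("signal must have at least 8 samples.")
  z <- analytic_signal(s$samples)
  phase <- signal::unwrap(Arg(z))
  dph <- numeric(n)
  dph[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  dph[1] <- phase[2] - phase[1]
  dph[n] <- phase[n] - phase[n - 1]
  f <- dph * s$fs / (2 * pi)
  f[Mod(z) == 0] <- 0
  f
}

#' Hilbert spectrum of a set of modes
#'
#' Time-frequency distribution of a decomposition: for every mode and time
#' sample, the squared envelope `a(t)^2` is deposited into the frequency bin
#' containing that sample's instantaneous frequency. Bins are uniform on
#' `[0, f_max]`; out-of-range frequencies are clipped to the edge bins. The
#' marginal spectrum is the per-bin sum over time, so total power is
#' conserved exactly.
#'
#' @param x A `vmd` object or a modes matrix (rows = modes).
#' @param fs Sampling rate in Hz; taken from a `vmd` object when available.
#' @param n_bins Number of frequency bins (default 64).
#' @param f_max Upper frequency edge in Hz (default `fs/2`).
#' @param t0 Time offset added to the time axis (seconds).
#' @return An object of class `hilbert_spectrum`: list with `power`
#'   (time x bin matrix), `freq_edges` (length `n_bins + 1`), `times`,
#'   `marginal` (length `n_bins`) and `fs`.
#' @examples
#' fit <- vmd(synth_multitone(), k = 3, alpha = 2000)
#' hs <- hilbert_spectrum(fit, n_bins = 64, f_max = 64)
#' @export
hilbert_spectrum <- function(x, fs = NULL, n_bins = 64, f_max = NULL, t0 = 0) {
  if (inherits(x, "vmd")) {
    modes <- x$modes
    if (is.null(fs)) fs <- x$fs
  } else {
    modes <- as.matrix(x)
  }
  if (is.null(fs) || is.na(fs)) abort("sampling rate unknown; pass `fs`.")
  if (nrow(modes) < 1) abort("need at least one mode.")
  if (is.null(f_max)) f_max <- fs / 2
  if (f_max <= 0) abort("`f_max` must be positive.")
  n <- ncol(modes)
  power <- matrix(0, n, n_bins)
  for (j in seq_len(nrow(modes))) {
    a2 <- envelope(modes[j, ])^2
    fr <- instantaneous_frequency(modes[j, ], fs)
    bin <- pmin(pmax(ceiling(fr / f_max * n_bins), 1L), n_bins)
    for (b in unique(bin)) {
      sel <- bin == b
      power[sel, b] <- power[sel, b] + a2[sel]
    }
  }
  structure(list(
    power = power,
    freq_edges = seq(0, f_max, length.out = n_bins + 1),
    times = t0 + (seq_len(n) - 1) / fs,
    marginal = colSums(power),
    fs = fs), class = "hilbert_spectrum")
}

#' @describeIn hilbert_spectrum Long tibble of the time-frequency power.
#' @param ... Unused.
#' @export
tidy.hilbert_spectrum <- function(x, ...) {
  centers <- (head(x$freq_edges, -1) + tail(x$freq_edges, -1)) / 2
  tibble::tibble(
    t = rep(x$times, times = length(centers)),
    freq = rep(centers, each = length(x$times)),
    power = as.vector(x$power)
  )
}

#' @describeIn hilbert_spectrum Heatmap of the Hilbert spectrum.
#' @param object A `hilbert_spectrum`.
#' @export
autoplot.hilbert_spectrum <- function(object, ...) {
  df <- tidy.hilbert_spectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "power")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d time samples x %d bins, 0-%g Hz\n",
              nrow(x$power), ncol(x$power), max(x$freq_edges)))
  invisible(x)
}
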