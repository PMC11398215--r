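# Shared fixtures and small independent oracles.

# The standard three-tone test signal: 2/12/36 Hz cosines with amplitudes
# 1, 1/2, 1/4 on 1024 points of one second.
three_tone <- function() synth_multitone()

# Periodogram-argmax oracle: dominant frequency in Hz (excludes DC).
periodogram_peak <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2
  half <- 2:(floor(n / 2) + 1)
  freq <- (half - 1) * fs / n
  freq[which.max(p[half])]
}

# Naive loop-summed signed Shannon entropy of a probability vector, the
# reference the fast path must match.
naive_signed_entropy <- function(b) {
  p <- b / sum(b)
  acc <- 0
  for (pi in p) if (pi > 0) acc <- acc + pi * log2(pi)
  acc
}

# RMS spectral spread around the centroid (bins) — a bandwidth proxy that is
# sensitive to cross-tone leakage as well as mainlobe width.
spectral_spread <- function(x) {
  p <- Mod(fft(x))[1:(length(x) %/% 2)]^2
  f <- seq_along(p) - 1
  mu <- sum(f * p) / sum(p)
  sqrt(sum((f - mu)^2 * p) / sum(p))
}
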