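#' Signed envelope entropy
#'
#' Shannon-type entropy of the Hilbert envelope normalized to a probability
#' vector, with a sign convention making it a minimization target: the
#' envelope `B` of `x` is normalized to `p_i = B_i / sum(B)` and the value
#' `sum(p_i * log2(p_i))` is returned (terms with `p_i = 0` contribute 0).
#' The result lies in `[-log2(N), 0]`: a perfectly flat envelope (a pure
#' narrowband tone) attains the minimum `-log2(N)`, a single-sample point
#' mass attains 0, and for N = 1024 the flat-envelope value is exactly -10.
#' Lower values therefore mean flatter envelopes, i.e. cleaner narrowband
#' modes, which is the direction the optimizer minimizes.
#'
#' @param x Real numeric vector (or [eeg_signal()]), at least 2 samples, not
#'   all zero.
#' @return Signed envelope entropy in bits (a scalar `<= 0`).
#' @examples
#' envelope_entropy(synth_multitone())
#' envelope_entropy(cos(2 * pi * 12 * (1:1024) / 1024))  # flat: -10
#' @export
envelope_entropy <- function(x) {
  s <- resolve_signal(x)
  x <- s$samples
  if (length(x) < 2) abort("signal must have at least 2 samples.")
  if (all(x == 0)) abort("envelope entropy is undefined for an all-zero signal.")
  b <- envelope(x)
  p <- b / sum(b)
  sum(ifelse(p > 0, p * log2(p), 0))
}

#' Envelope-entropy fitness of a VMD configuration
#'
#' Runs [vmd()] with mode count `k` and penalty factor `pf` on the signal,
#' computes the signed envelope entropy of every mode (on the original-length,
#' unmirrored segments), and aggregates: `method = "max"` returns the largest
#' (least negative, i.e. most informative) per-mode value -- the fitness the
#' grey wolf optimizer minimizes -- and `method = "mean"` the arithmetic mean.
#' All-zero modes carry no envelope information and are excluded from
#' aggregation (with a warning).
#'
#' @inheritParams vmd
#' @param pf Penalty factor passed to [vmd()] as `alpha`.
#' @param method Aggregation over modes: `"max"` (default) or `"mean"`.
#' @param ... Further arguments passed to [vmd()] (e.g. `tau`, `tol`,
#'   `mirror`, `init`).
#' @return An object of class `entropy_report`: list with `per_imf` (signed
#'   entropies by ascending mode frequency), `aggregate`, `method`, `k`, `pf`.
#' @examples
#' vmd_fitness(synth_multitone(), k = 3, pf = 4984)
#' @export
vmd_fitness <- function(x, k, pf, fs = NULL, method = c("max", "mean"), ...) {
  method <- match.arg(method)
  fit <- vmd(x, k = k, alpha = pf, fs = fs, ...)
  zero <- apply(fit$modes, 1, function(u) all(u == 0))
  if (any(zero)) {
    warn(sprintf("%d all-zero mode(s) excluded from entropy aggregation.",
                 sum(zero)))
  }
  per_imf <- rep(NA_real_, fit$k)
  per_imf[!zero] <- apply(fit$modes[!zero, , drop = FALSE], 1,
                          envelope_entropy)
  usable <- per_imf[!is.na(per_imf)]
  if (!length(usable)) abort("all modes are zero; fitness undefined.")
  aggregate <- if (method == "max") max(usable) else mean(usable)
  structure(list(per_imf = per_imf, aggregate = aggregate, method = method,
                 k = fit$k, pf = pf, fit = fit),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> K = %d, PF = %g, %s-aggregated fitness = %.7f\n",
              x$k, x$pf, x$method, x$aggregate))
  cat("  per-IMF:", paste(sprintf("%.7f", x$per_imf), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn vmd_fitness Per-mode entropies as a tibble.
#' @export
tidy.entropy_report <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$per_imf), entropy = x$per_imf)
}

#' @describeIn vmd_fitness One-row summary of the fitness evaluation.
#' @export
glance.entropy_report <- function(x, ...) {
  tibble::tibble(k = x$k, pf = x$pf, method = x$method,
                 fitness = x$aggregate)
}
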