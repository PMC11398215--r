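#' Construct an EEG signal tibble
#'
#' An `eeg_signal` is a tibble with a time column `t` (seconds) and a sample
#' column `value` (arbitrary units, typically microvolts), carrying the
#' sampling rate as an attribute so downstream functions never need it
#' re-stated.
#'
#' @param samples Numeric vector of finite samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param source Free-text label describing where the samples came from.
#' @return A tibble of class `eeg_signal` with columns `t` and `value`.
#' @examples
#' sig <- eeg_signal(sin(2 * pi * 4 * (0:127) / 128), fs = 128)
#' signal_fs(sig)
#' @export
eeg_signal <- function(samples, fs, source = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  if (length(samples) && any(!is.finite(samples))) {
    abort("all samples must be finite.")
  }
  out <- tibble::tibble(
    t = if (length(samples)) (seq_along(samples) - 1) / fs else numeric(),
    value = samples
  )
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "source") <- as.character(source)
  class(out) <- c("eeg_signal", class(out))
  out
}

#' Sampling rate of a signal
#'
#' @param x An `eeg_signal` tibble.
#' @return The sampling rate in Hz.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("`x` carries no sampling-rate attribute; pass `fs` explicitly.")
  fs
}

# Resolve (samples, fs) from either an eeg_signal, a data frame with a value
# column, or a bare numeric vector.
resolve_signal <- function(x, fs = NULL) {
  if (inherits(x, "eeg_signal") || (is.data.frame(x) && "value" %in% names(x))) {
    samples <- x$value
    if (is.null(fs)) fs <- attr(x, "fs")
  } else {
    samples <- as.numeric(x)
  }
  if (is.null(fs)) fs <- NA_real_
  list(samples = samples, fs = as.numeric(fs))
}

#' Read a raw EEG text stream
#'
#' Reads a plain-text sample stream: one numeric sample per line, optional
#' blank lines and `#` comment lines. This is the dialect used for raw
#' single-channel EEG exports at a known sampling rate.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz attached to the record (default 128).
#' @param source Label stored on the record; defaults to the file name.
#' @return An [eeg_signal()] tibble.
#' @export
read_raw_eeg <- function(path, fs = 128, source = basename(path)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  bad <- which(is.na(vals))
  if (length(bad)) {
    line_no <- which(keep)[bad[1L]]
    abort(sprintf("line %d of '%s' is not a number: '%s'",
                  line_no, path, lines[which(keep)[bad[1L]]]))
  }
  if (!length(vals)) abort(paste0("no samples found in '", path, "'"))
  eeg_signal(vals, fs = fs, source = source)
}

#' Write a signal as a raw text stream
#'
#' Inverse of [read_raw_eeg()]: one sample per line.
#'
#' @param x An `eeg_signal` or numeric vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raw_eeg <- function(x, path) {
  s <- resolve_signal(x)
  writeLines(format(s$samples, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Segment a signal into fixed-length epochs
#'
#' Cuts the record into consecutive non-overlapping windows of
#' `epoch_seconds`; a trailing partial window is dropped. For the standard
#' anesthesia-EEG setting (128 Hz, 8 s) each epoch holds exactly 1024 samples.
#'
#' @param x An `eeg_signal`, data frame with a `value` column, or numeric
#'   vector.
#' @param epoch_seconds Epoch duration in seconds (default 8).
#' @param fs Sampling rate in Hz; taken from `x` when it is an `eeg_signal`.
#' @return A tibble with one row per epoch: `epoch_index` (0-based), `t0`
#'   (start time, s), `n` (sample count) and a list-column `samples`.
#' @examples
#' sig <- synth_multitone()
#' epoch_signal(sig, epoch_seconds = 0.25)
#' @export
epoch_signal <- function(x, epoch_seconds = 8, fs = NULL) {
  s <- resolve_signal(x, fs)
  if (is.na(s$fs)) abort("sampling rate unknown; pass `fs`.")
  if (epoch_seconds <= 0) abort("`epoch_seconds` must be positive.")
  len_exact <- s$fs * epoch_seconds
  len <- round(len_exact)
  if (abs(len_exact - len) > 1e-9) {
    abort("`fs * epoch_seconds` must be a whole number of samples.")
  }
  n_epochs <- length(s$samples) %/% len
  if (n_epochs == 0L) {
    return(tibble::tibble(epoch_index = integer(), t0 = numeric(),
                          n = integer(), samples = list()))
  }
  idx <- seq_len(n_epochs) - 1L
  tibble::tibble(
    epoch_index = idx,
    t0 = idx * epoch_seconds,
    n = as.integer(len),
    samples = lapply(idx, function(i) s$samples[(i * len + 1):((i + 1) * len)]),
    fs = s$fs
  )
}
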