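#' Per-epoch hyperparameter optimization of a whole recording
#'
#' Segments the signal into epochs (unless an epoch table from
#' [epoch_signal()] is supplied) and runs one independent grey wolf
#' optimization of the VMD hyperparameters per epoch, minimizing the signed
#' envelope-entropy fitness of [vmd_fitness()]. Each epoch's GWO is seeded
#' deterministically as `seed + epoch_index`, so the whole table is
#' reproducible while epochs stay independent. A failing epoch is recorded
#' as a row of `NA`s (with a warning) and the run continues.
#'
#' @param x An [eeg_signal()], numeric vector, or epoch tibble from
#'   [epoch_signal()].
#' @param space A [gwo_search_space()].
#' @param epoch_seconds Epoch duration, used when `x` is not yet epoched.
#' @param n_wolves,n_iter GWO pack size and loop count (defaults 20 and 20).
#' @param method Fitness aggregation over modes, `"max"` or `"mean"`.
#' @param seed Base seed; epoch `i` runs with seed `seed + i`.
#' @param fs Sampling rate in Hz when `x` carries none.
#' @param vmd_args Named list of extra arguments for [vmd()] (e.g. `tau`,
#'   `tol`, `mirror`).
#' @param keep_trace Keep each epoch's full GWO trace in a list-column.
#' @return A tibble with one row per epoch: `epoch_index`, `t0`, `best_k`,
#'   `best_pf`, `best_fitness`, `n_evaluations`, `converged_iteration` (and
#'   `trace` when `keep_trace = TRUE`).
#' @examples
#' \donttest{
#' eeg <- synth_anesthesia_eeg(duration = 24, seed = 1)
#' optimize_epochs(eeg, n_wolves = 8, n_iter = 6, seed = 1)
#' }
#' @export
optimize_epochs <- function(x, space = gwo_search_space(), epoch_seconds = 8,
                            n_wolves = 20, n_iter = 20,
                            method = c("max", "mean"), seed = 1, fs = NULL,
                            vmd_args = list(), keep_trace = FALSE) {
  method <- match.arg(method)
  epochs <- as_epochs(x, epoch_seconds, fs)
  if (nrow(epochs) < 1) abort("the record yields no complete epoch.")

  one <- function(idx, t0, samples, fs_i) {
    objective <- function(k, pf) {
      do.call(vmd_fitness,
              c(list(x = samples, k = k, pf = pf, fs = fs_i, method = method),
                vmd_args))$aggregate
    }
    g <- gwo_minimize(objective, space, n_wolves = n_wolves, n_iter = n_iter,
                      seed = seed + idx)
    tibble::tibble(
      epoch_index = idx, t0 = t0,
      best_k = g$best_k, best_pf = g$best_pf, best_fitness = g$best_fitness,
      n_evaluations = g$n_evaluations,
      converged_iteration = g$converged_iteration,
      trace = if (keep_trace) list(g$trace) else list(NULL))
  }
  rows <- purrr::pmap(
    list(epochs$epoch_index, epochs$t0, epochs$samples, epochs$fs),
    function(epoch_index, t0, samples, fs) {
      tryCatch(
        suppressWarnings(one(epoch_index, t0, samples, fs)),
        error = function(e) {
          warn(sprintf("epoch %d failed: %s", epoch_index, conditionMessage(e)))
          tibble::tibble(epoch_index = epoch_index, t0 = t0,
                         best_k = NA_real_, best_pf = NA_real_,
                         best_fitness = NA_real_, n_evaluations = NA_integer_,
                         converged_iteration = NA_integer_,
                         trace = list(NULL))
        })
    })
  out <- dplyr::bind_rows(rows)
  if (!keep_trace) out$trace <- NULL
  out
}

as_epochs <- function(x, epoch_seconds, fs) {
  if (is.data.frame(x) && "samples" %in% names(x)) return(x)
  epoch_signal(x, epoch_seconds = epoch_seconds, fs = fs)
}

#' Fixed-hyperparameter VMD with a concatenated Hilbert spectrogram
#'
#' Decomposes every epoch with the same `(k, pf)` and concatenates the
#' per-epoch Hilbert spectra along time into one spectrogram, the standard
#' rendering for inspecting how narrowband EEG components (e.g. the
#' propofol-induced frontal alpha band in the second mode) evolve over a
#' recording.
#'
#' @inheritParams optimize_epochs
#' @param k,pf Fixed VMD hyperparameters.
#' @param n_bins Number of spectrogram frequency bins.
#' @param f_max Upper spectrogram frequency (default `fs/2`).
#' @return A list of class `vmd_spectrogram`: `fits` (list of `vmd` objects,
#'   one per epoch), `modes` (tibble: epoch_index, mode, omega_hz),
#'   `spectrogram` (a `hilbert_spectrum` whose time axis spans all epochs).
#' @examples
#' \donttest{
#' eeg <- synth_anesthesia_eeg(duration = 24, seed = 1)
#' sg <- run_fixed_vmd(eeg, k = 2, pf = 2000)
#' }
#' @export
run_fixed_vmd <- function(x, k, pf, epoch_seconds = 8, fs = NULL,
                          n_bins = 64, f_max = NULL, vmd_args = list()) {
  if (k < 1) abort("`k` must be at least 1.")
  epochs <- as_epochs(x, epoch_seconds, fs)
  if (nrow(epochs) < 1) abort("the record yields no complete epoch.")
  fits <- purrr::pmap(
    list(epochs$samples, epochs$fs),
    function(samples, fs) {
      do.call(vmd, c(list(x = samples, k = k, alpha = pf, fs = fs), vmd_args))
    })
  fs1 <- epochs$fs[[1]]
  if (is.null(f_max)) f_max <- fs1 / 2
  spectra <- purrr::map2(fits, epochs$t0, function(fit, t0) {
    hilbert_spectrum(fit, n_bins = n_bins, f_max = f_max, t0 = t0)
  })
  spectrogram <- structure(list(
    power = do.call(rbind, lapply(spectra, `[[`, "power")),
    freq_edges = spectra[[1]]$freq_edges,
    times = unlist(lapply(spectra, `[[`, "times")),
    marginal = Reduce(`+`, lapply(spectra, `[[`, "marginal")),
    fs = fs1), class = "hilbert_spectrum")
  modes <- dplyr::bind_rows(purrr::map2(fits, epochs$epoch_index, function(fit, i) {
    tibble::tibble(epoch_index = i, mode = seq_len(fit$k),
                   omega_hz = fit$omega_hz)
  }))
  structure(list(fits = fits, modes = modes, spectrogram = spectrogram),
            class = "vmd_spectrogram")
}

#' @export
print.vmd_spectrogram <- function(x, ...) {
  cat(sprintf("<vmd_spectrogram> %d epochs, K = %d\n",
              length(x$fits), x$fits[[1]]$k))
  print(x$spectrogram)
  invisible(x)
}

#' @describeIn run_fixed_vmd Heatmap of the concatenated Hilbert spectrogram.
#' @param object A `vmd_spectrogram`.
#' @param ... Unused.
#' @export
autoplot.vmd_spectrogram <- function(object, ...) {
  autoplot.hilbert_spectrum(object$spectrogram)
}

#' Before/after-emergence summary of per-epoch optimization records
#'
#' Splits the per-epoch records at a supplied emergence time and compares
#' the optimized K, PF and fitness between the two groups: group mean and SD
#' per quantity plus a Welch (unequal-variance) two-sample t-test p-value
#' when both groups hold at least two epochs (otherwise p is `NA` with a
#' warning).
#'
#' @param records Tibble from [optimize_epochs()].
#' @param emergence_t Emergence time in seconds; epochs with `t0 <
#'   emergence_t` form the "before" group.
#' @return A tibble with one row per quantity (`k`, `pf`, `fitness`):
#'   group sizes, means, SDs and `p_value`.
#' @export
emergence_summary <- function(records, emergence_t) {
  rec <- dplyr::filter(records, !is.na(.data$best_fitness))
  rec$group <- ifelse(rec$t0 < emergence_t, "before", "after")
  long <- tidyr::pivot_longer(
    dplyr::select(rec, "group", k = "best_k", pf = "best_pf",
                  fitness = "best_fitness"),
    cols = c("k", "pf", "fitness"),
    names_to = "quantity", values_to = "value")
  n_b <- sum(rec$group == "before")
  n_a <- sum(rec$group == "after")
  if (n_b < 2 || n_a < 2) {
    warn("a group has fewer than 2 epochs; p-values omitted.")
  }
  summarize_one <- function(df) {
    b <- df$value[df$group == "before"]
    a <- df$value[df$group == "after"]
    p <- if (length(b) >= 2 && length(a) >= 2 && (var(b) > 0 || var(a) > 0)) {
      t.test(b, a)$p.value  # Welch by default
    } else {
      NA_real_
    }
    tibble::tibble(
      n_before = length(b), mean_before = mean(b), sd_before = sd(b),
      n_after = length(a), mean_after = mean(a), sd_after = sd(a),
      p_value = p)
  }
  long |>
    dplyr::group_by(.data$quantity) |>
    dplyr::group_modify(~ summarize_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(quantity = factor(.data$quantity,
                                    levels = c("k", "pf", "fitness"))) |>
    dplyr::arrange(.data$quantity) |>
    dplyr::mutate(quantity = as.character(.data$quantity))
}
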