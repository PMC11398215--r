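---
title: "Methods: grey-wolf-optimized variational mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey-wolf-optimized variational mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwovmd)
```

## The model

Variational mode decomposition writes a real signal $f(t)$ as a sum of $K$
narrowband intrinsic mode functions $u_k(t)$, each concentrated around a
center frequency $\omega_k$. The decomposition minimizes the summed
bandwidth of the modes — measured as the squared $H^1$ norm of each mode's
demodulated analytic signal — under the reconstruction constraint
$\sum_k u_k = f$. The augmented Lagrangian adds a quadratic penalty with
weight $\alpha$ (the *penalty factor*, PF) and a multiplier $\lambda$, and
is solved by ADMM entirely in the frequency domain:

1. **Mode update** (Wiener filter on the non-negative half plane):
   $\hat u_k(\omega) \leftarrow
   \dfrac{\hat f(\omega) - \sum_{j \ne k}\hat u_j(\omega) + \hat\lambda(\omega)/2}
         {1 + 2\alpha(\omega - \omega_k)^2}$
2. **Center-frequency update**: $\omega_k$ becomes the power-weighted mean
   frequency (spectral centroid) of $|\hat u_k|^2$ over $\omega \ge 0$.
3. **Dual ascent**: $\hat\lambda \leftarrow \hat\lambda +
   \tau(\hat f - \sum_k \hat u_k)$.

Iteration stops when $\sum_k \|\hat u_k^{n+1}-\hat u_k^n\|_2^2 /
\|\hat u_k^n\|_2^2$ falls below `tol`, or at `max_iter`. Synthesis restores
Hermitian symmetry and inverse-transforms, so modes are real to machine
precision. The inner loop is compiled (RcppArmadillo) because hyperparameter
search evaluates it thousands of times per epoch.

**Assumptions.** The signal is a finite, uniformly sampled, real sequence
whose interesting structure is a small number of spectrally compact
components. VMD is not suited to broadband transients, and with a pure
penalty ($\tau = 0$) it is not obliged to reproduce every part of the
spectrum.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | — | number of modes; the central model-order choice |
| `alpha` (PF) | — | bandwidth penalty; larger is narrower. Dimensionless, tied to normalized frequency (cycles/sample) |
| `tau` | 0 | dual-ascent step. 0 = pure penalty (tolerant of noise, may leave spectrum unexplained); 0.5–1 enforces full-band coverage |
| `tol` | 1e-7 | relative-change stopping threshold; the three-tone fixture converges in ~15 iterations at this setting |
| `max_iter` | 500 | cap; reached only for near-degenerate mode configurations |
| `init` | `"zero"` | initial $\omega_k$ placement (see below) |
| `mirror` | `TRUE` | half-length reflection at both ends before decomposition; the central segment is returned |

## Numerical choices

**Center-frequency initialization.** All $\omega_k$ start at zero by
default, the convention of the original VMD reference implementation. We
also provide `"uniform"` ($\omega_k = 0.5\,k/(K+1)$ cycles/sample) and
seeded `"random"`. The default is not cosmetic: on the three-tone fixture
(2/12/36 Hz at 1024 Hz sampling — all content below 0.04 cycles/sample),
uniform initialization places every $\omega_k$ far above the signal and the
ADMM settles in a local optimum with two modes sharing the 2 Hz line
(max-mode entropy −9.9983 instead of −9.99999). Zero initialization lets
the modes peel off the spectrum from below and recovers the exact tones.
Neither choice dominates everywhere — on noisy EEG-band signals uniform
initialization can strand a mode on broadband noise near its starting
point — which is one more reason the hyperparameters are optimized per
epoch against an explicit fitness rather than trusted to any fixed recipe.

**Mirroring.** Half-length reflection suppresses boundary splatter that
otherwise leaks across modes and inflates envelope ripple. The worked
three-tone per-mode entropies quoted throughout (−9.9999946, −9.9999932,
−9.9999973) are obtained with mirroring on; without it the exact-bin tones
produce perfectly flat envelopes and all three values collapse to −10
exactly. Both settings are exposed.

**Degenerate inputs.** An all-zero signal returns $K$ zero modes at their
initialization frequencies, flagged converged. A zero-energy mode keeps its
previous $\omega_k$ (no 0/0). Modes are returned sorted by ascending
$\omega_k$, a deterministic canonical order.

**Dual ascent in the pipeline.** With $K = 2$, PF = 2000 and $\tau = 0$ on
noisy delta+alpha signals, both modes occasionally settle inside the delta
band, leaving the alpha band unexplained — legal under a pure penalty.
Setting $\tau = 0.5$ in `run_fixed_vmd()`'s `vmd_args` restores the
constraint and reliably pins the second mode to the alpha band; the fixed-
spectrogram examples and tests do so.

## The fitness: signed envelope entropy

For a candidate $(K, \mathrm{PF})$ the signal is decomposed and each mode's
Hilbert envelope $B$ (modulus of the analytic signal, computed on the
original-length segment) is normalized to $p_i = B_i/\sum_i B_i$. The
fitness of a mode is $\sum_i p_i \log_2 p_i$ — the *negated* Shannon
entropy, so it lies in $[-\log_2 N,\, 0]$ and is **minimized**: a flat
envelope (clean tone) reaches $-\log_2 N$ (−10 bits at $N = 1024$), a
point-mass envelope reaches 0. The sign convention makes "cleaner
narrowband separation" and "smaller fitness" the same direction, and it is
what the quoted reference values use. $0\log 0 := 0$; the measure is scale
invariant; an all-zero mode is excluded from aggregation. Aggregation over
modes is `max` (default — optimize the worst mode) or `mean`; all reported
selections here use `max`, and `mean` typically picks the same $K$ on
well-separated signals.

## The optimizer

The grey wolf optimizer maintains `n_wolves` candidate positions on the
discrete $(K, \mathrm{PF})$ grid. The three best solutions so far (alpha,
beta, delta) guide every update: per leader and dimension, with fresh
uniform draws $r_1, r_2$, $A = a(2r_1 - 1)$, $C = 2r_2$,
$D_L = |C X_L - X|$, $X_L' = X_L - A D_L$, and the proposal is the centroid
of the three $X_L'$, clamped to bounds and snapped to the grid (rounding in
each dimension). The scalar $a$ decays linearly from 2 to 0 over the loops,
moving the pack from exploration to exploitation.

Design points, each exposed or documented:

* **Greedy acceptance** (default): a wolf moves only if the proposal
  improves its fitness. The canonical always-move variant is
  `greedy = FALSE`. Greedy runs are stabler but keep less late-stage
  dispersion: on a separable bowl over the default grid, the canonical
  variant localizes both coordinates in ≥95% of seeds while greedy
  occasionally freezes the weakly informative coordinate, so the dispersion
  property is tested on the canonical variant.
* **Memoization**: the objective is cached per grid position (VMD is
  deterministic given a position), cutting a 20×20 run on the coarse grid
  to roughly 200 unique decompositions.
* **Ties** in the leader ranking break by wolf index; leaders may coincide.
* The returned optimum is the argmin over *every* evaluation made,
  including rejected proposals.
* `gwo_convergence()` reports the alpha leader's $K$, PF and fitness per
  loop as percentages of their final values, the conventional way to show
  that $K$ and the fitness settle within a handful of loops while PF — to
  which the fitness is nearly insensitive once large — wanders longer.

Every run is bit-reproducible given `seed`; `optimize_epochs()` derives the
epoch-level seed as `seed + epoch_index`, so records are independent but
the whole table reruns identically.

## The synthetic generators

`synth_multitone()` produces exact-bin cosine mixtures on the grid
$t = k/f_s$, $k = 1..n$; the default three-tone (2/12/36 Hz, amplitudes
1, 1/2, 1/4, $N = 1024$) is the canonical desk-scale fixture because its
correct decomposition is known in closed form.

`synth_anesthesia_eeg()` emulates the *spectral skeleton* of frontal EEG
under propofol anesthesia: band-limited Gaussian noise in 0.5–4 Hz
(slow-delta), a narrowband component at `alpha_center` ± 1 Hz (default
11 Hz), and a broadband noise floor, with component variances set by the
`*_power` arguments (defaults 1, 1, 0.05 — delta and alpha of comparable
power over a weak floor, the structure seen during maintenance). It does
**not** emulate burst suppression, electromyographic contamination after
emergence, electrode artifacts, line noise, or non-Gaussian amplitude
statistics. Passing tests on this generator therefore demonstrates that the
machinery recovers known narrowband structure in noise at realistic band
locations — not that any clinical claim holds on patient data.

## The per-epoch pipeline

`epoch_signal()` cuts consecutive, non-overlapping epochs (default 8 s;
1024 samples at 128 Hz), dropping a trailing partial window — the
fixed-length entropy floor and the FFT grid both assume full windows.
`optimize_epochs()` runs one GWO per epoch; failures yield `NA` rows
without aborting the run. `run_fixed_vmd()` decomposes every epoch at one
$(K, \mathrm{PF})$ and concatenates per-epoch Hilbert spectra into a
spectrogram. `emergence_summary()` splits the records at a user-supplied
emergence time and compares $K$, PF and fitness across groups with Welch's
unequal-variance $t$-test (chosen because the two phases have no reason to
share a variance); with fewer than two epochs on a side the means are
still reported but $p$-values are omitted. Emergence time is an input, not
detected.

## Problem sizes in the shipped tests

Unit and property tests run on 1024–5120-sample fixtures; stochastic GWO
properties use 20–50 seeds on cheap objectives and 20 seeds for the full
VMD-backed selection; pipeline tests use 3–5 epochs with reduced packs
(5–10 wolves, 3–8 loops), which exercise every contract at a fraction of
the full 20×20 budget. The full budget is used where the selection result
itself is asserted.

## Known limitations

* VMD's ADMM is a local method; the optimized $(K, \mathrm{PF})$ inherits
  whatever basin the initialization reaches. The per-epoch fitness search
  compensates but cannot guarantee a global optimum.
* The envelope entropy of a *raw* broadband mixture is a weak diagnostic —
  it is the per-mode values after decomposition that carry information.
* Offline only: a 20×20 GWO per 8-s epoch costs a few hundred VMD runs and
  is not real-time on one core.
* Single channel; no artifact rejection; no clinical index is computed.
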