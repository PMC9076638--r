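# FWHM-parameterized complex Morlet wavelet bank, FFT convolution giving
# phase and power, and dB baseline normalization of power.

#' Design a complex Morlet wavelet bank
#'
#' Center frequencies are logarithmically spaced from `fmin` to `fmax` (both
#' endpoints exact). Each wavelet is a complex sine tapered by a Gaussian
#' `exp(-4 ln 2 * t^2 / FWHM^2)`; the time-domain FWHM interpolates
#' log-linearly in frequency from `fwhm_start_ms` at `fmin` down to
#' `fwhm_end_ms` at `fmax`. Kernels are normalized to unit spectral peak
#' gain so power is comparable across frequencies.
#'
#' @param fmin,fmax Frequency range, Hz. Defaults 2 and 40.
#' @param n Number of log-spaced frequencies. Default 50.
#' @param fwhm_start_ms,fwhm_end_ms Time-domain FWHM at `fmin` / `fmax`, ms.
#'   Defaults 400 and 104.
#' @param fs Sampling rate, Hz; must exceed `2 * fmax`.
#' @return A `wavelet_bank`: list with `freqs` (Hz), `fwhm_ms`, `kernels`
#'   (list of complex vectors, odd length), `fs`.
#' @export
design_bank <- function(fmin = 2, fmax = 40, n = 50,
                        fwhm_start_ms = 400, fwhm_end_ms = 104, fs = 250) {
  if (fmin >= fmax) stop_invalid("`fmin` must be below `fmax`")
  if (n < 2) stop_invalid("`n` must be >= 2")
  if (fs <= 2 * fmax)
    stop_invalid("`fs` = %g Hz violates the Nyquist bound for fmax = %g Hz",
                 fs, fmax)
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n))
  freqs[1] <- fmin; freqs[n] <- fmax
  # log-linear FWHM interpolation in frequency
  fwhm <- exp(stats::approx(log(c(fmin, fmax)),
                            log(c(fwhm_start_ms, fwhm_end_ms)),
                            xout = log(freqs))$y)
  kernels <- purrr::map2(freqs, fwhm / 1000, function(f, w) {
    half <- max(ceiling(3 * w * fs), ceiling(2 * fs / f))
    t <- (-half:half) / fs
    k <- exp(2i * pi * f * t) * exp(-4 * log(2) * t^2 / w^2)
    # unit spectral peak gain
    k / max(Mod(fft(k)))
  })
  structure(list(freqs = freqs, fwhm_ms = fwhm, kernels = kernels, fs = fs),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank> %d freqs %.3g-%.3g Hz, FWHM %.0f-%.0f ms @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              max(x$fwhm_ms), min(x$fwhm_ms), x$fs))
  invisible(x)
}

# centered ("same") FFT convolution of the columns of a matrix with one
# complex kernel. x: [time, trial]; returns complex matrix of same shape.
# `Xf` may carry a precomputed forward FFT of x padded to length nf.
conv_same <- function(x, kern, Xf = NULL, nf = NULL) {
  n <- nrow(x); m <- length(kern)
  nf <- nf %||% nextn(n + m - 1, 2)
  K <- fft(c(kern, rep(0, nf - m)))
  X <- Xf %||% mvfft(rbind(x, matrix(0, nf - n, ncol(x))))
  out <- mvfft(X * K, inverse = TRUE) / nf
  half <- (m - 1) / 2
  out[(half + 1):(half + n), , drop = FALSE]
}

#' Time-frequency decomposition by wavelet convolution
#'
#' Convolves each trial with every wavelet of the bank ("same"-length,
#' centered). Samples within half a kernel length of either epoch edge are
#' flagged in the edge mask and should not be analyzed (the epoch padding
#' exists to absorb them).
#'
#' @param signal Numeric matrix `[trial, time]` (a vector is treated as one
#'   trial), or an `epoched_sources` object plus `source` to pick one source.
#' @param bank A [design_bank()] wavelet bank.
#' @param source Source label when `signal` is `epoched_sources`.
#' @param time_s Optional time axis (s); taken from the object if available.
#' @return A `tf_decomp`: list with complex `coef` `[trial, freq, time]`,
#'   `freqs`, `time_s`, `fs`, and logical `edge` `[freq, time]` (TRUE =
#'   contaminated by epoch edges).
#' @export
decompose <- function(signal, bank, source = NULL, time_s = NULL) {
  if (inherits(signal, "epoched_sources")) {
    time_s <- signal$time_s
    src <- source %||% signal$sources[1]
    signal <- signal$data[, src, , drop = TRUE]
    if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  }
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (anyNA(signal)) {
    bad <- which(apply(signal, 1, anyNA))
    stop_invalid("NaN/NA in signal at trial(s) %s",
                 paste(bad, collapse = ", "))
  }
  n_tr <- nrow(signal); n_t <- ncol(signal); n_f <- length(bank$freqs)
  longest <- max(lengths(bank$kernels))
  if (n_t < longest)
    stop_invalid("signal (%d samples) shorter than longest kernel (%d)",
                 n_t, longest)
  coef <- array(complex(real = 0), dim = c(n_tr, n_f, n_t))
  edge <- matrix(FALSE, n_f, n_t)
  xt <- t(signal)   # [time, trial]
  nf_pad <- nextn(n_t + longest - 1, 2)
  Xf <- mvfft(rbind(xt, matrix(0, nf_pad - n_t, n_tr)))
  for (j in seq_len(n_f)) {
    cj <- conv_same(xt, bank$kernels[[j]], Xf = Xf, nf = nf_pad)
    coef[, j, ] <- t(cj)
    half <- (length(bank$kernels[[j]]) - 1) / 2
    edge[j, c(seq_len(min(half, n_t)),
              seq.int(max(1, n_t - half + 1), n_t))] <- TRUE
  }
  structure(list(coef = coef, freqs = bank$freqs,
                 time_s = time_s %||% (seq_len(n_t) - 1) / bank$fs,
                 fs = bank$fs, edge = edge),
            class = "tf_decomp")
}

#' Extract instantaneous phase from a decomposition
#'
#' @param tf A `tf_decomp`.
#' @return Numeric array `[trial, freq, time]` of phase angles in (-pi, pi].
#' @export
tf_phase <- function(tf) {
  ph <- Arg(tf$coef)
  ph[ph <= -pi] <- pi
  ph
}

#' Extract instantaneous power from a decomposition
#'
#' @param tf A `tf_decomp`.
#' @return Numeric array `[trial, freq, time]`, squared magnitude.
#' @export
tf_power <- function(tf) Mod(tf$coef)^2

#' dB baseline normalization of power
#'
#' Converts power to dB change relative to a per-frequency baseline mean:
#' `10 * log10(power / baseline)`. The baseline is the trial- and
#' time-averaged power inside `baseline_window_ms` (the fused pre-cue
#' window pooled over start trials in the intended workflow).
#'
#' @param power Array `[trial, freq, time]` (or matrix `[freq, time]`).
#' @param time_s Time axis, s, matching the last dimension.
#' @param baseline_window_ms Length-2 window in ms. Default `c(-500, -200)`.
#' @param baseline_power Optional precomputed per-frequency baseline means
#'   (overrides the window).
#' @return Same shape as `power`, in dB.
#' @export
power_db <- function(power, time_s, baseline_window_ms = c(-500, -200),
                     baseline_power = NULL) {
  arr <- if (length(dim(power)) == 2)
    array(power, c(1, dim(power))) else power
  if (is.null(baseline_power)) {
    sel <- time_s * 1000 >= baseline_window_ms[1] &
      time_s * 1000 <= baseline_window_ms[2]
    if (!any(sel)) stop_invalid("baseline window is outside the epoch")
    baseline_power <- apply(arr[, , sel, drop = FALSE], 2, mean)
  }
  if (any(baseline_power <= 0))
    stop_invalid("baseline power must be positive at every frequency")
  out <- 10 * log10(sweep(arr, 2, baseline_power, "/"))
  if (length(dim(power)) == 2) out <- out[1, , ] else out
  out
}
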