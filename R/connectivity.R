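# Inter-site phase clustering over trials on the 50 Hz analysis grid,
# baseline subtraction, response-locked re-alignment, and single-trial
# band-pooled phase lags.

new_ispc_map <- function(values, freqs, time_s, variant, pair, alignment,
                         n_trials) {
  structure(list(values = values, freqs = freqs, time_s = time_s,
                 variant = variant, pair = pair, alignment = alignment,
                 n_trials = n_trials),
            class = "ispc_map")
}

#' @export
print.ispc_map <- function(x, ...) {
  cat(sprintf("<ispc_map %s> %s-%s, %d freqs x %d times, %d trials (%s)\n",
              x$variant, x$pair[1], x$pair[2], length(x$freqs),
              length(x$time_s), x$n_trials, x$alignment))
  invisible(x)
}

#' Tidy an ISPC map to a long tibble
#'
#' @param x An `ispc_map`.
#' @param ... Unused.
#' @return Tibble with `freq_hz`, `time_s`, `ispc`.
#' @method tidy ispc_map
#' @export
tidy.ispc_map <- function(x, ...) {
  tibble::tibble(
    freq_hz = rep(x$freqs, times = length(x$time_s)),
    time_s = rep(x$time_s, each = length(x$freqs)),
    ispc = as.vector(x$values))
}

#' Inter-site phase clustering over trials
#'
#' At each (frequency, time) cell, ISPC is the modulus of the across-trial
#' mean of `exp(1i * (phase_a - phase_b))`: 1 for a perfectly consistent
#' phase lag (of any value), 0 for uniformly scattered lags. Phase series
#' are evaluated on a down-sampled grid (`grid_hz`, default 50 Hz, i.e.
#' every 5th sample at 250 Hz).
#'
#' @param phases_a,phases_b Phase arrays `[trial, freq, time]` (radians) of
#'   the two sources, equal shapes, >= 2 trials.
#' @param freqs Frequency axis, Hz.
#' @param time_s Time axis, s (native sampling rate).
#' @param fs Sampling rate of the phase series, Hz. Default 250.
#' @param grid_hz Analysis grid rate, Hz. Default 50.
#' @param pair Character length-2 source labels.
#' @param alignment `"stimulus"` or `"response"`.
#' @return An `ispc_map` (variant `"raw"`).
#' @export
ispc <- function(phases_a, phases_b, freqs, time_s, fs = 250, grid_hz = 50,
                 pair = c("LSM1", "RSM1"), alignment = "stimulus") {
  if (!identical(dim(phases_a), dim(phases_b)))
    stop_invalid("phase arrays must have identical shapes")
  n_tr <- dim(phases_a)[1]
  if (n_tr < 2)
    stop_invalid("ISPC over trials is undefined for a single trial")
  step <- max(1L, as.integer(round(fs / grid_hz)))
  idx <- seq(1L, dim(phases_a)[3], by = step)
  dphi <- phases_a[, , idx, drop = FALSE] - phases_b[, , idx, drop = FALSE]
  vals <- Mod(colMeans(exp(1i * dphi)))   # mean over trials -> [freq, time]
  new_ispc_map(vals, freqs, time_s[idx], "raw", pair, alignment, n_tr)
}

#' ISPC over time within a sliding window (literal single-trial reading)
#'
#' Clusters phase-angle differences over time points inside a window,
#' averaged over trials afterwards; provided as the windowed alternative to
#' the default over-trials estimator.
#'
#' @inheritParams ispc
#' @param window_s Window length in seconds. Default 0.5.
#' @return An `ispc_map` (variant `"raw"`), time axis at window centers.
#' @export
ispc_over_time <- function(phases_a, phases_b, freqs, time_s, fs = 250,
                           grid_hz = 50, window_s = 0.5,
                           pair = c("LSM1", "RSM1"),
                           alignment = "stimulus") {
  if (!identical(dim(phases_a), dim(phases_b)))
    stop_invalid("phase arrays must have identical shapes")
  step <- max(1L, as.integer(round(fs / grid_hz)))
  idx <- seq(1L, dim(phases_a)[3], by = step)
  half <- floor(window_s * grid_hz / 2)
  dphi <- phases_a[, , idx, drop = FALSE] - phases_b[, , idx, drop = FALSE]
  z <- exp(1i * dphi)
  n_t <- length(idx)
  vals <- matrix(NA_real_, length(freqs), n_t)
  for (k in seq_len(n_t)) {
    win <- max(1, k - half):min(n_t, k + half)
    m <- apply(z[, , win, drop = FALSE], c(1, 2), mean)  # [trial, freq]
    vals[, k] <- colMeans(Mod(m))
  }
  new_ispc_map(vals, freqs, time_s[idx], "raw", pair, alignment, dim(z)[1])
}

#' Subtract the per-frequency baseline from an ISPC map
#'
#' @param map An `ispc_map` covering the time of interest.
#' @param baseline Either an `ispc_map` on the same frequency axis whose
#'   time average serves as baseline, or `NULL` to use
#'   `baseline_window_ms` within `map` itself.
#' @param baseline_window_ms Window (ms) used when `baseline` is `NULL`.
#'   Default `c(-500, -200)`.
#' @return An `ispc_map` with variant `"baseline_subtracted"`.
#' @export
baseline_subtract <- function(map, baseline = NULL,
                              baseline_window_ms = c(-500, -200)) {
  if (!is.null(baseline)) {
    if (!isTRUE(all.equal(map$freqs, baseline$freqs)))
      stop_invalid("frequency axes of map and baseline differ")
    base_mean <- rowMeans(baseline$values)
  } else {
    sel <- map$time_s * 1000 >= baseline_window_ms[1] &
      map$time_s * 1000 <= baseline_window_ms[2]
    if (!any(sel)) stop_invalid("baseline window outside the map")
    base_mean <- rowMeans(map$values[, sel, drop = FALSE])
  }
  out <- map
  out$values <- map$values - base_mean
  out$variant <- "baseline_subtracted"
  out
}

#' Re-align epochs to the individual median transition latency
#'
#' Windows each trial to `±half_window_ms` around the per-condition median
#' latency (midpoint convention for even counts). Trials whose window
#' exceeds the epoch bounds, and failed trials (latency `NA`), are dropped
#' with a message.
#'
#' @param epochs An `epoched_sources` object (stimulus-locked, cue at 0 s).
#' @param trials Scored-trial tibble with `latency_ms` and
#'   `transition_mode`, rows matching `epochs` trials.
#' @param half_window_ms Half window, ms. Default 260.
#' @return An `epoched_sources` object with `alignment = "response"`, time
#'   axis relative to the median-latency re-alignment point.
#' @export
response_lock <- function(epochs, trials, half_window_ms = 260) {
  stopifnot(inherits(epochs, "epoched_sources"))
  n_tr <- dim(epochs$data)[1]
  if (nrow(trials) != n_tr)
    stop_invalid("`trials` must have one row per epoch (%d != %d)",
                 nrow(trials), n_tr)
  ok <- !is.na(trials$latency_ms)
  med <- tapply(trials$latency_ms[ok], trials$transition_mode[ok], median)
  fs <- epochs$fs
  half_n <- round(half_window_ms / 1000 * fs)
  keep <- integer(); starts <- integer()
  for (tr in seq_len(n_tr)) {
    if (!ok[tr]) next
    center_s <- med[[trials$transition_mode[tr]]] / 1000
    c_idx <- which.min(abs(epochs$time_s - center_s))
    if (abs(epochs$time_s[c_idx] - center_s) > 1 / fs) next
    if (c_idx - half_n < 1 || c_idx + half_n > length(epochs$time_s)) next
    keep <- c(keep, tr); starts <- c(starts, c_idx - half_n)
  }
  dropped <- n_tr - length(keep)
  if (dropped > 0)
    message(sprintf("response_lock: dropped %d trial(s) (failed or out of bounds)",
                    dropped))
  if (!length(keep)) stop_invalid("no trial survives response locking")
  n_out <- 2 * half_n + 1
  dat <- array(NA_real_, c(length(keep), dim(epochs$data)[2], n_out),
               dimnames = dimnames(epochs$data)[c(1, 2, 3)])
  for (i in seq_along(keep))
    dat[i, , ] <- epochs$data[keep[i], , starts[i]:(starts[i] + n_out - 1)]
  out <- epochs
  out$data <- dat
  out$time_s <- seq(-half_n, half_n) / fs
  out$alignment <- "response"
  out$trial_info <- epochs$trial_info[keep, , drop = FALSE]
  attr(out, "median_latency_ms") <- med
  out
}

#' Extract a single-trial band-pooled phase lag
#'
#' Pools the phase-angle difference between two sources over the frequency
#' bins of a band by the circular mean (required for wrapped angles), at one
#' time point.
#'
#' @param phases_a,phases_b Phase arrays `[trial, freq, time]`.
#' @param freqs Frequency axis, Hz.
#' @param time_s Time axis, s.
#' @param band Length-2 numeric band (Hz), e.g. `c(15, 22)` (low beta) or
#'   `c(25, 30)` (high beta).
#' @param at_time_s Time (s) at which to extract, one value per trial or a
#'   single value recycled.
#' @param edge Optional logical edge mask `[freq, time]`; extraction at a
#'   masked sample is an error.
#' @return Tibble with `trial`, `lag_rad` (wrapped to (-pi, pi]),
#'   `at_time_s`.
#' @export
extract_phase_lag <- function(phases_a, phases_b, freqs, time_s, band,
                              at_time_s, edge = NULL) {
  n_tr <- dim(phases_a)[1]
  at_time_s <- rep_len(at_time_s, n_tr)
  fsel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(fsel)) stop_invalid("no frequency bins inside the band")
  lag <- vapply(seq_len(n_tr), function(tr) {
    ti <- which.min(abs(time_s - at_time_s[tr]))
    if (!is.null(edge) && any(edge[fsel, ti]))
      stop_invalid("requested time %.3f s lies in the masked edge region",
                   at_time_s[tr])
    dphi <- phases_a[tr, fsel, ti] - phases_b[tr, fsel, ti]
    circ_mean(wrap_pi(dphi))
  }, numeric(1))
  tibble::tibble(trial = seq_len(n_tr), lag_rad = wrap_pi(lag),
                 at_time_s = at_time_s)
}
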