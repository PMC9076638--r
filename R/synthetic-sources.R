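# Coupled oscillatory source simulation: band-limited oscillations with a
# controllable cross-source phase lag (von Mises across trials, optionally
# time-varying within the epoch) on top of 1/f + white background noise.

#' Specify cross-source phase coupling
#'
#' @param band Length-2 numeric, frequency band in Hz (within 2-40 Hz).
#' @param mean_lag Mean phase lag of the right relative to the left source,
#'   radians.
#' @param kappa von Mises concentration of the per-trial lag around
#'   `mean_lag`; `0` gives uniform lags (no locking), large values give
#'   near-deterministic lags.
#' @param snr Ratio of oscillation power to background-noise power (> 0).
#' @param lag_timecourse Optional function of peri-event time (s) returning an
#'   additive lag offset (radians), e.g. a step at the transition to emulate
#'   peri-transition coupling modulation. `NULL` means constant lag.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(band = c(15, 22), mean_lag = 0, kappa = 8,
                          snr = 1, lag_timecourse = NULL) {
  if (kappa < 0) stop_invalid("`kappa` must be >= 0")
  if (snr <= 0) stop_invalid("`snr` must be > 0")
  if (band[1] < 2 || band[2] > 40 || band[1] >= band[2])
    stop_invalid("`band` must be an increasing interval within [2, 40] Hz")
  structure(list(band = band, mean_lag = mean_lag, kappa = kappa,
                 snr = snr, lag_timecourse = lag_timecourse),
            class = "coupling_spec")
}

# 1/f (pink) noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  nf <- nextn(n, 2)
  spec <- fft(rnorm(nf))
  f <- c(1, seq_len(nf - 1))        # avoid division by zero at DC
  f <- pmin(f, nf - f + 1)          # symmetric shaping
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  as.numeric(scale(x))
}

#' Generate epoched three-source oscillatory data
#'
#' Simulates epoched source-level time series for three labelled sources
#' (`LSM1`, `RSM1`, `OCC`). `LSM1` and `RSM1` share a band-limited
#' oscillation with a per-trial phase lag drawn from a von Mises
#' distribution per `coupling`; `OCC` carries an independent oscillation
#' unless `occ_coupling` is supplied. All sources sit on 1/f + white
#' background noise scaled to the requested signal-to-noise ratio.
#'
#' @param n_trials Number of epochs to generate (or an event schedule, in
#'   which case one epoch per `switch` cue is generated and its cued mode
#'   recorded).
#' @param coupling A [coupling_spec()] for the LSM1-RSM1 pair.
#' @param fs Sampling rate in Hz; must exceed twice the band's upper edge.
#'   Default 250.
#' @param epoch_window Length-2 numeric, epoch extent in seconds relative to
#'   the alignment event. Default `c(-2.5, 2.5)`.
#' @param occ_coupling Optional [coupling_spec()] coupling OCC to LSM1.
#' @param seed Integer seed.
#'
#' @return An `epoched_sources` object: list with `data` (numeric array
#'   `[trial, source, sample]`), `time_s`, `fs`, `sources`, `alignment`
#'   (`"stimulus"`), `trial_info` (tibble with per-trial mode and the true
#'   simulated lag, radians).
#' @export
generate_sources <- function(n_trials, coupling = coupling_spec(),
                             fs = 250, epoch_window = c(-2.5, 2.5),
                             occ_coupling = NULL, seed = 1) {
  modes <- NULL
  if (is.data.frame(n_trials)) {
    sw <- n_trials[n_trials$event == "switch", ]
    modes <- sw$cued_mode
    n_trials <- nrow(sw)
  }
  if (n_trials < 1) stop_invalid("need at least one trial")
  if (fs < 2 * coupling$band[2])
    stop_invalid("`fs` = %g Hz is below twice the band's upper edge (%g Hz)",
                 fs, coupling$band[2])

  time_s <- seq(epoch_window[1], epoch_window[2], by = 1 / fs)
  n_samp <- length(time_s)
  f0 <- sqrt(prod(coupling$band))   # geometric band center
  amp <- sqrt(2 * coupling$snr)     # unit-power noise -> power ratio = snr

  with_seed(derive_seed(seed, "sources"), {
    dat <- array(0, dim = c(n_trials, 3L, n_samp),
                 dimnames = list(NULL, c("LSM1", "RSM1", "OCC"), NULL))
    lag_tc <- coupling$lag_timecourse %||% function(t) rep(0, length(t))
    true_lag <- rvonmises(n_trials, coupling$mean_lag, coupling$kappa)

    for (tr in seq_len(n_trials)) {
      phi0 <- runif(1, -pi, pi)
      base_phase <- 2 * pi * f0 * time_s + phi0
      lag_t <- true_lag[tr] + lag_tc(time_s)
      noise <- function() (pink_noise(n_samp) + rnorm(n_samp)) / sqrt(2)
      dat[tr, 1L, ] <- amp * sin(base_phase) + noise()
      dat[tr, 2L, ] <- amp * sin(base_phase - lag_t) + noise()
      if (is.null(occ_coupling)) {
        f_occ <- 10
        dat[tr, 3L, ] <-
          amp * sin(2 * pi * f_occ * time_s + runif(1, -pi, pi)) + noise()
      } else {
        occ_lag <- rvonmises(1, occ_coupling$mean_lag, occ_coupling$kappa)
        f_occ <- sqrt(prod(occ_coupling$band))
        dat[tr, 3L, ] <- sqrt(2 * occ_coupling$snr) *
          sin(2 * pi * f_occ * time_s - occ_lag) + noise()
      }
    }

    structure(list(
      data = dat, time_s = time_s, fs = fs,
      sources = c("LSM1", "RSM1", "OCC"), alignment = "stimulus",
      trial_info = tibble::tibble(
        trial = seq_len(n_trials),
        mode = modes %||% rep(NA_character_, n_trials),
        true_lag = true_lag)
    ), class = "epoched_sources")
  })
}

#' @export
print.epoched_sources <- function(x, ...) {
  cat(sprintf(
    "<epoched_sources> %d trials x %d sources x %d samples @ %g Hz (%s-locked)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$alignment))
  invisible(x)
}

#' Write / read epoched sources as plain text
#'
#' Long-format TSV round trip for `epoched_sources` objects (one row per
#' trial-source-sample; metadata in a JSON sidecar next to the table).
#'
#' @param x An `epoched_sources` object.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `write_sources_tsv` returns `path` invisibly; `read_sources_tsv`
#'   returns the reconstructed `epoched_sources` object.
#' @export
write_sources_tsv <- function(x, path) {
  d <- dim(x$data)
  grid <- expand.grid(trial = seq_len(d[1]), source = x$sources,
                      sample = seq_len(d[3]), stringsAsFactors = FALSE)
  grid$value <- as.vector(x$data)
  readr::write_tsv(grid, path)
  meta <- list(fs = x$fs, alignment = x$alignment, sources = x$sources,
               time_s = x$time_s)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sources_tsv
#' @export
read_sources_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_tr <- max(tab$trial); n_s <- length(meta$sources)
  n_samp <- max(tab$sample)
  arr <- array(tab$value, dim = c(n_tr, n_s, n_samp),
               dimnames = list(NULL, meta$sources, NULL))
  structure(list(data = arr, time_s = meta$time_s, fs = meta$fs,
                 sources = meta$sources, alignment = meta$alignment,
                 trial_info = tibble::tibble(trial = seq_len(n_tr),
                                             mode = NA_character_,
                                             true_lag = NA_real_)),
            class = "epoched_sources")
}
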