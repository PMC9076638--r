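# Paradigm simulation: event schedules and paced tap streams.
#
# The simulated task alternates two bimanual tapping modes. Each trial is a
# start cue followed by a transition cue ("continue" keeps the current mode,
# "switch" toggles it) and a fixed-length pause. A thumb reaction-time (tRT)
# probe can occur instead of any scheduled event; it is always followed by a
# pause at a short fixed latency.

#' Generate a paradigm event schedule
#'
#' Builds the event stream of the motor-state transition paradigm: per trial a
#' start cue, a transition cue (switch with probability
#' `switch_ratio / (switch_ratio + 1)`, continue otherwise) and a 3000 ms
#' pause. Every scheduled event is independently replaced by a thumb
#' reaction-time (tRT) probe with probability `p_trt`; a pause follows each
#' tRT at a 1000 ms latency (inserted when the next scheduled event is not
#' already a pause). Non-pause events are separated by inter-stimulus
#' intervals jittered uniformly in `isi_range_ms`.
#'
#' @param n_trials Number of trials (start/transition/pause triplets) to lay
#'   out. Must be a positive integer.
#' @param p_trt Per-event probability that a tRT probe replaces the scheduled
#'   event; in `[0, 1)`. Default 0.05.
#' @param switch_ratio Expected ratio of switching to continuation transition
#'   cues. Default 5 (i.e. approximately 1:5 continuation:switching).
#' @param isi_range_ms Length-2 numeric, jitter range (ms) of the
#'   inter-stimulus interval after non-pause events. Default `c(5000, 8000)`.
#' @param pause_ms Pause duration in ms. Default 3000.
#' @param trt_pause_latency_ms Latency (ms) from a tRT cue to its mandatory
#'   pause. Default 1000.
#' @param seed Integer seed; the schedule is fully reproducible from it.
#'
#' @return A tibble with one row per event and columns `event` (one of
#'   `start`, `continue`, `switch`, `pause`, `tRT`), `onset_ms`, `side`
#'   (`left`/`right` for tRT cues, `none` otherwise), `trial`, `cued_mode`
#'   (`in_phase`/`anti_phase`; the mode to perform from that cue onwards,
#'   `NA` for pauses and tRT), and `inserted` (pauses added after a tRT).
#'   The attribute `session_length_ms` holds the schedule end time.
#' @export
#' @examples
#' sched <- generate_schedule(20, seed = 1)
#' table(sched$event)
generate_schedule <- function(n_trials, p_trt = 0.05, switch_ratio = 5,
                              isi_range_ms = c(5000, 8000), pause_ms = 3000,
                              trt_pause_latency_ms = 1000, seed = 1) {
  if (length(n_trials) != 1 || !is.finite(n_trials) || n_trials < 1)
    stop_invalid("`n_trials` must be a positive integer, got %s", n_trials)
  n_trials <- as.integer(n_trials)
  if (p_trt < 0 || p_trt >= 1)
    stop_invalid("`p_trt` must lie in [0, 1), got %s", p_trt)
  if (switch_ratio <= 0) stop_invalid("`switch_ratio` must be positive")
  stopifnot(length(isi_range_ms) == 2, diff(isi_range_ms) >= 0)

  with_seed(derive_seed(seed, "schedule"), {
    event <- rep(c("start", "transition", "pause"), n_trials)
    trial <- rep(seq_len(n_trials), each = 3L)

    # transition identity: per-trial Bernoulli, switch with p = r/(r+1)
    is_switch <- runif(n_trials) < switch_ratio / (switch_ratio + 1)
    event[event == "transition"] <-
      ifelse(is_switch, "switch", "continue")

    # tRT substitution: every scheduled event can be replaced
    to_trt <- runif(length(event)) < p_trt
    event[to_trt] <- "tRT"

    # mode bookkeeping: switch cues toggle the performed mode
    modes <- c("in_phase", "anti_phase")
    cur <- 1L
    cued_mode <- rep(NA_character_, length(event))
    for (k in seq_along(event)) {
      if (event[k] %in% c("start", "continue")) {
        cued_mode[k] <- modes[cur]
      } else if (event[k] == "switch") {
        cur <- 3L - cur
        cued_mode[k] <- modes[cur]
      }
    }

    # insert the mandatory pause after tRT events when needed
    ins_after <- which(event == "tRT" &
                         c(event[-1], "") != "pause")
    if (length(ins_after)) {
      idx <- sort(c(seq_along(event), ins_after + 0.5))
      new_event <- ifelse(idx %% 1 > 0, "pause", event[idx])
      inserted <- idx %% 1 > 0
      new_trial <- trial[ceiling(idx)]
      new_mode <- ifelse(inserted, NA_character_, cued_mode[idx])
      event <- new_event; trial <- new_trial; cued_mode <- new_mode
    } else {
      inserted <- rep(FALSE, length(event))
    }

    # onsets: gap depends on the *preceding* event
    n_ev <- length(event)
    gap <- numeric(n_ev - 1L)
    for (k in seq_len(n_ev - 1L)) {
      gap[k] <- switch(event[k],
        pause = pause_ms,
        tRT = trt_pause_latency_ms,
        runif(1, isi_range_ms[1], isi_range_ms[2])
      )
    }
    onset <- c(0, cumsum(gap))
    side <- ifelse(event == "tRT",
                   sample(c("left", "right"), n_ev, replace = TRUE), "none")

    out <- tibble::tibble(
      event = event, onset_ms = onset, side = side, trial = trial,
      cued_mode = cued_mode, inserted = inserted
    )
    attr(out, "session_length_ms") <-
      onset[n_ev] + if (event[n_ev] == "pause") pause_ms else 0
    attr(out, "params") <- list(
      n_trials = n_trials, p_trt = p_trt, switch_ratio = switch_ratio,
      isi_range_ms = isi_range_ms, pause_ms = pause_ms,
      trt_pause_latency_ms = trt_pause_latency_ms, seed = seed
    )
    out
  })
}

#' Simulate a paced tap stream for a schedule
#'
#' Emulates a subject tapping bimanually to an auditory pacing beat. Between a
#' start cue and the next pause, tap pairs occur at the pacing interval; the
#' performed mode follows the cued mode, changing after a switch cue at a
#' latency drawn from `latency_dist`. Erroneous (wrong-mode) pairs can be
#' injected inside the post-switch scoring window via `error_model`. tRT cues
#' elicit a single thumb press of the cued side.
#'
#' @param schedule An event schedule from [generate_schedule()].
#' @param tap_freq_hz Pacing frequency in Hz (pairs per second). Default 2.
#' @param latency_dist Transition latency model: `list(type = "fixed",
#'   value_ms = 500)` or `list(type = "gamma", shape = 9, scale_ms = 60)`.
#' @param error_model One of `list(type = "none")`, `list(type = "always",
#'   window_ms = 2000)` (every pair in the window is wrong-mode, giving a
#'   failed transition) or `list(type = "random", p = 0.1, window_ms = 2000)`.
#' @param async_sd_ms Within-pair left/right asynchrony SD in ms. Default 5.
#' @param trt_rt Thumb reaction time model, `list(shape, scale_ms)` for a
#'   gamma draw. Default `list(shape = 10, scale_ms = 30)`.
#' @param seed Integer seed.
#'
#' @return A tibble of taps with columns `time_ms`, `hand` (`L`/`R`),
#'   `finger` (`index`/`middle`/`thumb`), sorted by time.
#' @export
generate_tap_stream <- function(schedule, tap_freq_hz = 2,
                                latency_dist = list(type = "gamma",
                                                    shape = 9, scale_ms = 60),
                                error_model = list(type = "none"),
                                async_sd_ms = 5,
                                trt_rt = list(shape = 10, scale_ms = 30),
                                seed = 1) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0)
    stop_invalid("`schedule` must be a non-empty event schedule")
  if (tap_freq_hz <= 0) stop_invalid("`tap_freq_hz` must be positive")
  beat_ms <- 1000 / tap_freq_hz
  window_ms <- error_model$window_ms %||% 2000

  draw_latency <- function() {
    switch(latency_dist$type,
      fixed = latency_dist$value_ms,
      gamma = rgamma(1, shape = latency_dist$shape,
                     scale = latency_dist$scale_ms),
      stop_invalid("unknown latency_dist type '%s'", latency_dist$type)
    )
  }

  with_seed(derive_seed(seed, "taps"), {
    rows <- list()
    n_ev <- nrow(schedule)
    active <- FALSE
    cur_mode <- NA_character_
    pending_switch_at <- NA_real_   # time when the new mode takes over
    pending_new_mode <- NA_character_
    last_switch_time <- NA_real_
    last_switch_mode <- NA_character_

    emit_pair <- function(t, mode, phase_idx) {
      # in_phase: homologous fingers; anti_phase: index-middle across hands.
      # phase_idx alternates which finger set leads on successive beats.
      dt <- rnorm(1, 0, async_sd_ms)
      if (mode == "in_phase") {
        f <- if (phase_idx %% 2 == 0) "index" else "middle"
        data.frame(time_ms = c(t, t + dt), hand = c("L", "R"),
                   finger = c(f, f))
      } else {
        if (phase_idx %% 2 == 0) {
          data.frame(time_ms = c(t, t + dt), hand = c("L", "R"),
                     finger = c("index", "middle"))
        } else {
          data.frame(time_ms = c(t, t + dt), hand = c("L", "R"),
                     finger = c("middle", "index"))
        }
      }
    }
    other_mode <- function(m) if (m == "in_phase") "anti_phase" else "in_phase"

    for (k in seq_len(n_ev)) {
      ev <- schedule$event[k]
      t0 <- schedule$onset_ms[k]
      t1 <- if (k < n_ev) schedule$onset_ms[k + 1] else
        t0 + attr(schedule, "params")$pause_ms %||% 3000

      if (ev == "start") {
        active <- TRUE
        cur_mode <- schedule$cued_mode[k]
      } else if (ev == "continue") {
        cur_mode <- schedule$cued_mode[k]
      } else if (ev == "switch") {
        pending_switch_at <- t0 + draw_latency()
        pending_new_mode <- schedule$cued_mode[k]
        last_switch_time <- t0
        last_switch_mode <- pending_new_mode
      } else if (ev == "pause") {
        active <- FALSE
        pending_switch_at <- NA_real_
      } else if (ev == "tRT") {
        active <- FALSE
        rt <- rgamma(1, shape = trt_rt$shape, scale = trt_rt$scale_ms)
        rows[[length(rows) + 1L]] <- data.frame(
          time_ms = t0 + rt,
          hand = if (schedule$side[k] == "left") "L" else "R",
          finger = "thumb")
      }

      if (active && !is.na(cur_mode)) {
        beats <- seq(t0 + beat_ms / 2, t1 - 1e-9, by = beat_ms)
        for (b in seq_along(beats)) {
          tb <- beats[b]
          mode_b <- cur_mode
          if (!is.na(pending_switch_at) && tb >= pending_switch_at) {
            cur_mode <- pending_new_mode
            mode_b <- cur_mode
            pending_switch_at <- NA_real_
          }
          # error injection inside the post-switch scoring window
          if (!is.na(last_switch_time) &&
              tb >= last_switch_time && tb <= last_switch_time + window_ms) {
            if (identical(error_model$type, "always")) {
              mode_b <- other_mode(last_switch_mode)
            } else if (identical(error_model$type, "random") &&
                       runif(1) < (error_model$p %||% 0)) {
              mode_b <- other_mode(mode_b)
            }
          }
          rows[[length(rows) + 1L]] <- emit_pair(tb, mode_b, b)
        }
      }
    }

    out <- dplyr::arrange(
      tibble::as_tibble(dplyr::bind_rows(rows)), .data$time_ms)
    out$time_ms <- round(out$time_ms, 3)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
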