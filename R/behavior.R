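# Behavioral outcome coding: tap-pair classification, transition scoring
# (error fraction, latency, hurdle code), hurdle partitioning and thumb-RT
# trimming.

#' Classify a bimanual tap pair
#'
#' Homologous fingers across hands (index-index or middle-middle) tapped
#' within the synchrony tolerance are in-phase; index-middle across hands is
#' anti-phase. Thumb presses or unsynchronized taps classify as `error`
#' (never an exception).
#'
#' @param finger_l,finger_r Finger of the left / right tap (`index`,
#'   `middle`, `thumb`).
#' @param dt_ms Absolute time difference between the two taps, ms.
#' @param sync_tolerance_ms Largest `dt_ms` still counted as synchronous.
#' @return `"in_phase"`, `"anti_phase"`, or `"error"` (vectorized).
#' @export
classify_tap_pair <- function(finger_l, finger_r, dt_ms,
                              sync_tolerance_ms = 125) {
  ok <- abs(dt_ms) <= sync_tolerance_ms &
    finger_l %in% c("index", "middle") & finger_r %in% c("index", "middle")
  out <- rep("error", length(ok))
  out[ok & finger_l == finger_r] <- "in_phase"
  out[ok & finger_l != finger_r] <- "anti_phase"
  out
}

# Greedy nearest-in-time pairing of left and right taps. Each tap is used at
# most once; unpaired taps become error "pairs".
pair_taps <- function(taps) {
  lt <- taps[taps$hand == "L" & taps$finger != "thumb", , drop = FALSE]
  rt <- taps[taps$hand == "R" & taps$finger != "thumb", , drop = FALSE]
  pairs <- list()
  used_r <- rep(FALSE, nrow(rt))
  for (i in seq_len(nrow(lt))) {
    if (nrow(rt) == 0) break
    d <- abs(rt$time_ms - lt$time_ms[i])
    d[used_r] <- Inf
    j <- which.min(d)
    if (is.finite(d[j])) {
      used_r[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        time_ms = (lt$time_ms[i] + rt$time_ms[j]) / 2,
        finger_l = lt$finger[i], finger_r = rt$finger[j],
        dt_ms = abs(lt$time_ms[i] - rt$time_ms[j]))
    }
  }
  unpaired_l <- if (nrow(lt) > length(pairs)) nrow(lt) - length(pairs) else 0
  unpaired_r <- sum(!used_r)
  res <- if (length(pairs)) dplyr::bind_rows(pairs) else
    data.frame(time_ms = numeric(), finger_l = character(),
               finger_r = character(), dt_ms = numeric())
  attr(res, "n_unpaired") <- unpaired_l + unpaired_r
  res
}

#' Score one transition trial
#'
#' Within a window after the switch cue (default 2000 ms), tap pairs are
#' classified; the error fraction is the share of pairs not matching the
#' cued mode, the transition latency is the delay from cue onset to the
#' first pair in the cued mode, and the hurdle code partitions trials into
#' `failed` (error fraction 1, latency undefined), `fully_correct`
#' (error fraction 0) and `partial` otherwise.
#'
#' @param taps Tap tibble (`time_ms`, `hand`, `finger`) for the trial (taps
#'   outside the window are ignored).
#' @param cue_time_ms Switch-cue onset, ms.
#' @param cued_mode Target mode, `"in_phase"` or `"anti_phase"`.
#' @param window_ms Scoring window length after the cue. Default 2000.
#' @param sync_tolerance_ms Pair synchrony tolerance, ms; default 25% of the
#'   median inter-pair interval is a sensible setting, 125 ms here for the
#'   default 2 Hz pacing.
#' @return One-row tibble: `latency_ms` (`NA` for failed/missing),
#'   `error_fraction`, `hurdle_code`, `n_pairs`; `hurdle_code` is `missing`
#'   when no pair falls in the window.
#' @export
score_transition <- function(taps, cue_time_ms, cued_mode,
                             window_ms = 2000, sync_tolerance_ms = 125) {
  stopifnot(cued_mode %in% c("in_phase", "anti_phase"))
  inwin <- taps[taps$time_ms >= cue_time_ms &
                  taps$time_ms <= cue_time_ms + window_ms, , drop = FALSE]
  pr <- pair_taps(inwin)
  n_unpaired <- attr(pr, "n_unpaired")
  if (nrow(pr) + n_unpaired == 0) {
    return(tibble::tibble(latency_ms = NA_real_, error_fraction = NA_real_,
                          hurdle_code = "missing", n_pairs = 0L))
  }
  cls <- if (nrow(pr)) classify_tap_pair(pr$finger_l, pr$finger_r, pr$dt_ms,
                                         sync_tolerance_ms) else character()
  n_pairs <- nrow(pr) + n_unpaired
  n_err <- sum(cls != cued_mode) + n_unpaired
  err_frac <- n_err / n_pairs
  first_ok <- pr$time_ms[cls == cued_mode]
  latency <- if (length(first_ok)) min(first_ok) - cue_time_ms else NA_real_
  code <- if (err_frac >= 1) "failed" else if (err_frac == 0)
    "fully_correct" else "partial"
  tibble::tibble(latency_ms = latency, error_fraction = err_frac,
                 hurdle_code = code, n_pairs = as.integer(n_pairs))
}

#' Score all switch trials of a session
#'
#' Applies [score_transition()] at every switch cue of the schedule and adds
#' trial bookkeeping (transition mode, centered trial number).
#'
#' @param taps Full-session tap tibble.
#' @param schedule Event schedule from [generate_schedule()].
#' @inheritParams score_transition
#' @return Tibble, one row per switch trial: `trial`, `transition_mode`
#'   (`into_IP`/`into_AP`), `latency_ms`, `error_fraction`, `hurdle_code`,
#'   `n_pairs`, `n_trial_centered`.
#' @export
score_trials <- function(taps, schedule, window_ms = 2000,
                         sync_tolerance_ms = 125) {
  sw <- schedule[schedule$event == "switch", , drop = FALSE]
  res <- purrr::map2_dfr(sw$onset_ms, sw$cued_mode, function(t0, mode) {
    dplyr::mutate(
      score_transition(taps, t0, mode, window_ms, sync_tolerance_ms),
      transition_mode = ifelse(mode == "in_phase", "into_IP", "into_AP"),
      .before = 1)
  })
  res$trial <- sw$trial
  res$n_trial_centered <- seq_len(nrow(res)) - (nrow(res) + 1) / 2
  dplyr::relocate(res, "trial")
}

#' Partition scored trials by the hurdle structure
#'
#' Splits trials into the disjoint, exhaustive sets of the hurdle coding:
#' failed transitions (error fraction 1; removed before latency analyses),
#' fully correct transitions, and partial trials whose error fraction is
#' already inside the open unit interval suitable for beta modelling.
#'
#' @param trials Scored-trial tibble (needs `hurdle_code`).
#' @return Named list of tibbles `failed`, `fully_correct`, `partial`.
#' @export
split_hurdle <- function(trials) {
  trials <- trials[trials$hurdle_code != "missing", , drop = FALSE]
  list(failed = trials[trials$hurdle_code == "failed", , drop = FALSE],
       fully_correct = trials[trials$hurdle_code == "fully_correct", ,
                              drop = FALSE],
       partial = trials[trials$hurdle_code == "partial", , drop = FALSE])
}

#' Trim thumb reaction times
#'
#' Removes reaction times below 100 ms, then removes values above the
#' within-group mean + 3 SD, with mean and SD computed after the lower cut.
#' Values exactly at the upper bound are kept (so an all-equal sample with
#' zero SD is returned unchanged).
#'
#' @param rts Numeric reaction times, ms.
#' @param group Optional grouping factor (same length as `rts`); trimming is
#'   applied within group. Default: one group.
#' @param lower_ms Lower cut-off, ms. Default 100.
#' @param k_sd Upper cut-off in SD units above the group mean. Default 3.
#' @return Trimmed numeric vector (warns if empty).
#' @export
trim_trt <- function(rts, group = NULL, lower_ms = 100, k_sd = 3) {
  if (length(rts) == 0) stop_invalid("`rts` must be non-empty")
  if (is.null(group)) group <- rep(1L, length(rts))
  keep <- unlist(lapply(split(seq_along(rts), group), function(idx) {
    x <- rts[idx]
    idx <- idx[x >= lower_ms]
    x <- x[x >= lower_ms]
    if (!length(x)) return(integer())
    s <- sd(x)
    if (is.na(s)) s <- 0
    idx[x <= mean(x) + k_sd * s]
  }), use.names = FALSE)
  out <- rts[sort(keep)]
  if (!length(out)) warning("all reaction times trimmed away")
  out
}
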