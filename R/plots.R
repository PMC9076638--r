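# ggplot2 views of the main result types.

#' Plot an ISPC (or z) map
#'
#' Time-frequency raster of an `ispc_map` (raw ISPC, baseline-subtracted
#' change, or permutation z values).
#'
#' @param object An `ispc_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ispc_map
#' @export
autoplot.ispc_map <- function(object, ...) {
  df <- tidy.ispc_map(object)
  lab <- switch(object$variant, raw = "ISPC",
                baseline_subtracted = "ΔISPC", z = "z", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$ispc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(
      x = "time (s)", y = "frequency (Hz)",
      title = sprintf("%s-%s (%s-locked, %d trials)", object$pair[1],
                      object$pair[2], object$alignment, object$n_trials)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster permutation result
#'
#' t-map raster with significant cluster outlines.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(
    freq = rep(object$freqs, times = length(object$time_s)),
    time = rep(object$time_s, each = length(object$freqs)),
    t = as.vector(object$t_map),
    label = as.vector(object$labels))
  sig_ids <- object$clusters$cluster[object$clusters$significant]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "time", y = "frequency (Hz)", fill = "t") +
    ggplot2::theme_minimal()
  if (length(sig_ids))
    p <- p + ggplot2::geom_point(
      data = df[df$label %in% sig_ids, ],
      shape = ".", colour = "black")
  p
}

#' Plot posterior densities of mediation paths
#'
#' Density of the conditional indirect, direct and path draws at each
#' moderator level.
#'
#' @param object A `mediation_fit`.
#' @param effects Conditional-effect draws from [conditional_effects()];
#'   computed if missing.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mediation_fit
#' @export
autoplot.mediation_fit <- function(object, effects = NULL, ...) {
  ce <- effects %||% conditional_effects(object)
  long <- tidyr::pivot_longer(ce, c("alpha", "beta", "tau_prime", "indirect"),
                              names_to = "path", values_to = "draw_value")
  ggplot2::ggplot(long, ggplot2::aes(.data$draw_value,
                                     colour = factor(.data$w_level))) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~path, scales = "free") +
    ggplot2::labs(x = "posterior draw", colour = "moderator level") +
    ggplot2::theme_minimal()
}
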