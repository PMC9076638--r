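# MRS GABA+ preparation: tissue correction under the standard compartment
# assumptions (GABA+ negligible in CSF, twice as high in GM as in WM) and
# normalization to the outlier-trimmed group-mean voxel composition.

#' Default compartment constants for tissue correction
#'
#' Editable table of per-compartment water relaxation / visibility terms
#' used by [tissue_correct()]. Literature-style defaults; replace with
#' site-specific values as needed. `alpha` is the assumed WM:GM GABA+
#' ratio.
#'
#' @return Named list: `alpha` plus water terms `w_gm`, `w_wm`, `w_csf`.
#' @export
gaba_constants <- function() {
  list(alpha = 0.5, w_gm = 0.78, w_wm = 0.65, w_csf = 0.97)
}

#' Tissue-correct raw GABA+ values
#'
#' Alpha correction: the CSF compartment contributes no GABA+ and WM holds
#' `alpha` (default 0.5) times the GM concentration, while the water
#' reference signal mixes all three compartments through their
#' visibility/relaxation terms:
#' `corrected = raw * (fGM*w_gm + fWM*w_wm + fCSF*w_csf) /
#' (fGM + alpha*fWM)`.
#'
#' @param raw Raw GABA+ values (institutional units).
#' @param fGM,fWM,fCSF Tissue fractions (must sum to 1 within 0.01).
#' @param constants Constants table, see [gaba_constants()].
#' @return Corrected values, same length.
#' @export
tissue_correct <- function(raw, fGM, fWM, fCSF,
                           constants = gaba_constants()) {
  if (any(abs(fGM + fWM + fCSF - 1) > 0.01))
    stop_invalid("tissue fractions must sum to 1 (within 0.01)")
  if (any(c(fGM, fWM, fCSF) < 0) || any(c(fGM, fWM, fCSF) > 1))
    stop_invalid("tissue fractions must lie in [0, 1]")
  water <- fGM * constants$w_gm + fWM * constants$w_wm +
    fCSF * constants$w_csf
  raw * water / (fGM + constants$alpha * fWM)
}

#' Normalize corrected GABA+ to the group-mean voxel composition
#'
#' Rescales each subject's corrected value to the tissue composition an
#' average group member has: the correction factor is re-evaluated at the
#' group-mean fractions (computed after removing composition outliers
#' beyond `k_sd` SDs within group) and each value is multiplied by the
#' ratio of the group-mean factor to the subject's own factor. A subject
#' exactly at the group-mean composition is unchanged.
#'
#' @param corrected Tissue-corrected values.
#' @param fGM,fWM,fCSF Tissue fractions per subject.
#' @param group Group labels (>= 3 subjects per group).
#' @param constants Constants table.
#' @param k_sd Outlier cut for the composition average. Default 3.
#' @return Normalized values, same length.
#' @export
group_normalize <- function(corrected, fGM, fWM, fCSF, group,
                            constants = gaba_constants(), k_sd = 3) {
  if (any(table(group) < 3)) stop_invalid("need >= 3 subjects per group")
  cf <- function(g, w, c) {
    (g * constants$w_gm + w * constants$w_wm + c * constants$w_csf) /
      (g + constants$alpha * w)
  }
  out <- numeric(length(corrected))
  for (gl in unique(group)) {
    idx <- which(group == gl)
    keep <- idx
    for (fr in list(fGM, fWM, fCSF)) {
      x <- fr[idx]
      s <- sd(x)
      if (is.na(s) || s == 0) next
      keep <- intersect(keep, idx[abs(x - mean(x)) <= k_sd * s])
    }
    mg <- mean(fGM[keep]); mw <- mean(fWM[keep]); mc <- mean(fCSF[keep])
    out[idx] <- corrected[idx] * cf(mg, mw, mc) /
      cf(fGM[idx], fWM[idx], fCSF[idx])
  }
  out
}

#' Tissue-correct and normalize a long GABA+ table
#'
#' Convenience wrapper over [tissue_correct()] and [group_normalize()] for
#' the long table of [cohort_gaba_long()]; runs per voxel.
#'
#' @param gaba Long tibble with `subject`, `group`, `voxel`, `gaba_raw`,
#'   `fGM`, `fWM`, `fCSF`.
#' @param constants Constants table.
#' @return Input tibble with added `gaba_corrected`, `gaba_normalized`.
#' @export
prepare_gaba <- function(gaba, constants = gaba_constants()) {
  gaba |>
    dplyr::group_by(.data$voxel) |>
    dplyr::mutate(
      gaba_corrected = tissue_correct(.data$gaba_raw, .data$fGM, .data$fWM,
                                      .data$fCSF, constants),
      gaba_normalized = group_normalize(.data$gaba_corrected, .data$fGM,
                                        .data$fWM, .data$fCSF, .data$group,
                                        constants)) |>
    dplyr::ungroup()
}
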