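# Cohort simulation: subject-level tables generated by the moderated
# mediation data-generating process (outcome and mediator regressions with
# exGaussian residuals), plus group-structured GABA+ voxel measurements with
# tissue fractions and quality metrics.

#' Ground-truth coefficient set for the mediation data-generating process
#'
#' The mediator model is `M = i2 + a1*X + a2*W + a3*X*W + e2` and the outcome
#' model is `Y = i1 + c1*X + c2*W + c3*X*W + b1*M + b2*M*W + e1`, with
#' exGaussian residuals `e = Normal(0, sigma) + Exp(mean = beta_exg)`.
#'
#' @param a1,a2,a3 Mediator-model coefficients (X, W, X:W).
#' @param b1,b2 Outcome-model mediator coefficients (M, M:W).
#' @param c1,c2,c3 Outcome-model direct-path coefficients (X, W, X:W).
#' @param i1,i2 Intercepts of outcome and mediator models.
#' @param sigma1,beta1 Gaussian SD and exponential mean of the outcome
#'   residual; `sigma2`, `beta2` likewise for the mediator. Zero switches the
#'   corresponding component off.
#' @param gaba_base,gaba_sd,gaba_offset_iu Base level, between-subject SD and
#'   young-minus-older group offset (institutional units) of the simulated
#'   raw GABA+; the offset applies to the sensorimotor voxels only.
#' @return A named list of class `mediation_truth`.
#' @export
mediation_truth <- function(a1 = 0.5, a2 = 0, a3 = 0, b1 = -0.4, b2 = 0,
                            c1 = 0, c2 = 0, c3 = 0, i1 = 0, i2 = 0,
                            sigma1 = 0.5, beta1 = 0.3,
                            sigma2 = 0.5, beta2 = 0.3,
                            gaba_base = 2.5, gaba_sd = 0.2,
                            gaba_offset_iu = 0.6) {
  vals <- list(a1 = a1, a2 = a2, a3 = a3, b1 = b1, b2 = b2,
               c1 = c1, c2 = c2, c3 = c3, i1 = i1, i2 = i2,
               sigma1 = sigma1, beta1 = beta1, sigma2 = sigma2,
               beta2 = beta2, gaba_base = gaba_base, gaba_sd = gaba_sd,
               gaba_offset_iu = gaba_offset_iu)
  if (!all(vapply(vals, is.finite, logical(1))))
    stop_invalid("all ground-truth coefficients must be finite")
  if (sigma1 < 0 || sigma2 < 0 || beta1 < 0 || beta2 < 0)
    stop_invalid("noise scales must be non-negative")
  structure(vals, class = c("mediation_truth", "list"))
}

rexgauss_resid <- function(n, sigma, beta) {
  out <- numeric(n)
  if (sigma > 0) out <- out + rnorm(n, 0, sigma)
  if (beta > 0) out <- out + rexp(n, rate = 1 / beta)
  out
}

#' Generate a synthetic subject cohort
#'
#' Draws a cohort of young and older subjects whose mediator `M` and outcome
#' `Y` follow the moderated-mediation data-generating process of
#' [mediation_truth()] exactly (machine precision when all noise scales are
#' zero). `X` is a standardized connectivity summary, `W` the centered group
#' code (young `-0.5`, older `+0.5`). Per-voxel raw GABA+ values carry the
#' group offset in sensorimotor voxels only, alongside simulated tissue
#' fractions and quality metrics for the tissue-correction stage.
#'
#' @param n_young,n_older Subjects per group (each >= 2).
#' @param truth A [mediation_truth()] coefficient set.
#' @param seed Integer seed.
#' @return A tibble, one row per subject, with columns `subject`, `group`,
#'   `W`, `X`, `M`, `Y`, per-voxel `gaba_raw_*`, `fGM_*`, `fWM_*`, `fCSF_*`
#'   and quality metrics. The generating `truth` (with the seed) is attached
#'   as attribute `"truth"`.
#' @export
generate_cohort <- function(n_young, n_older, truth = mediation_truth(),
                            seed = 1) {
  if (n_young < 2 || n_older < 2)
    stop_invalid("need at least 2 subjects per group")
  stopifnot(inherits(truth, "mediation_truth"))
  n <- n_young + n_older

  with_seed(derive_seed(seed, "cohort"), {
    group <- c(rep("young", n_young), rep("older", n_older))
    W <- ifelse(group == "young", -0.5, 0.5)
    W <- W - mean(W)
    X <- rnorm(n)
    X <- as.numeric(X - mean(X))

    M <- truth$i2 + truth$a1 * X + truth$a2 * W + truth$a3 * X * W +
      rexgauss_resid(n, truth$sigma2, truth$beta2)
    Y <- truth$i1 + truth$c1 * X + truth$c2 * W + truth$c3 * X * W +
      truth$b1 * M + truth$b2 * M * W +
      rexgauss_resid(n, truth$sigma1, truth$beta1)

    voxels <- c("LEFT_SM1", "RIGHT_SM1", "OCC")
    gaba <- lapply(voxels, function(v) {
      offset <- if (v == "OCC") 0 else truth$gaba_offset_iu
      truth$gaba_base + ifelse(group == "young", offset / 2, -offset / 2) +
        rnorm(n, 0, truth$gaba_sd)
    })
    names(gaba) <- paste0("gaba_raw_", voxels)

    fracs <- lapply(voxels, function(v) {
      fGM <- pmin(pmax(rnorm(n, 0.45, 0.04), 0.2), 0.7)
      fCSF <- pmin(pmax(rnorm(n, 0.10, 0.03), 0.01), 0.3)
      fWM <- 1 - fGM - fCSF
      stats::setNames(
        tibble::tibble(fGM, fWM, fCSF),
        paste0(c("fGM_", "fWM_", "fCSF_"), v))
    })

    qual <- tibble::tibble(
      gaba_snr = rnorm(n, 20, 2), naa_snr = rnorm(n, 150, 15),
      gaba_fit_error = abs(rnorm(n, 5, 1)), drift = rnorm(n, 1, 0.3),
      frequency_offset = abs(rnorm(n, 0.01, 0.003)),
      naa_fwhm = rnorm(n, 5.5, 0.5))

    out <- dplyr::bind_cols(
      tibble::tibble(
        subject = sprintf("S%03d", seq_len(n)), group = group,
        W = W, X = X, M = M, Y = Y),
      tibble::as_tibble(gaba), fracs, qual)
    attr(out, "truth") <- c(unclass(truth), list(seed = seed))
    out
  })
}

#' Reshape per-voxel GABA+ columns to the long measurement table
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or one with the
#'   same wide per-voxel columns).
#' @return A tibble with one row per subject-voxel: `subject`, `group`,
#'   `voxel`, `gaba_raw`, `fGM`, `fWM`, `fCSF`.
#' @export
cohort_gaba_long <- function(cohort) {
  tidyr::pivot_longer(
    dplyr::select(cohort, "subject", "group",
                  dplyr::matches("^(gaba_raw|fGM|fWM|fCSF)_")),
    cols = -c("subject", "group"),
    names_to = c(".value", "voxel"),
    names_pattern = "^(gaba_raw|fGM|fWM|fCSF)_(.+)$")
}

#' Serialize / restore generation ground truth
#'
#' Lossless JSON round trip of the ground-truth list attached to a synthetic
#' cohort (full double precision).
#'
#' @param truth Ground-truth list (e.g. `attr(cohort, "truth")`).
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   the restored list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
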