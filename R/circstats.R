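# Circular statistics for the single-trial phase-behavior analysis:
# Rayleigh test, circular mean with confidence arc, circular-linear
# correlation (Mardia), Harrison-Kanji two-way circular ANOVA, BH-FDR, and
# within-group median dichotomization of GABA+.

#' Rayleigh test of circular uniformity
#'
#' `z = n * Rbar^2` with the small-sample-corrected exponential
#' approximation for the p-value.
#'
#' @param angles Angles in radians, `n >= 4`.
#' @return Tibble with `n`, `r_bar`, `z`, `p`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 4) stop_invalid("Rayleigh test needs n >= 4, got %d", n)
  rbar <- circ_r(angles)
  z <- n * rbar^2
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble::tibble(n = n, r_bar = rbar, z = z, p = min(max(p, 0), 1))
}

#' Circular mean direction with confidence arc
#'
#' Mean direction plus a symmetric confidence arc (Fisher/Zar dispersion
#' formula, with the high-concentration branch for `Rbar > 0.9`). Outside
#' the formula's validity region the arc is `NA` and flagged.
#'
#' @param angles Angles in radians.
#' @param confidence Coverage. Default 0.95.
#' @return Tibble with `mean_dir`, `ci_halfwidth` (radians; `NA` with
#'   `valid = FALSE` when undefined), `r_bar`, `n`.
#' @export
circ_mean_ci <- function(angles, confidence = 0.95) {
  n <- length(angles)
  rbar <- circ_r(angles)
  mu <- circ_mean(angles)
  R <- n * rbar
  chi <- qchisq(confidence, 1)
  hw <- NA_real_
  valid <- FALSE
  if (rbar >= 1 - 1e-12) {
    hw <- 0; valid <- TRUE
  } else if (rbar > 0.9) {
    arg <- sqrt(n^2 - (n^2 - R^2) * exp(chi / n)) / R
    if (is.finite(arg) && arg <= 1) { hw <- acos(arg); valid <- TRUE }
  } else if (rbar > sqrt(chi / (2 * n))) {
    arg <- sqrt((2 * n * (2 * R^2 - n * chi)) / (4 * n - chi)) / R
    if (is.finite(arg) && arg <= 1) { hw <- acos(arg); valid <- TRUE }
  }
  tibble::tibble(mean_dir = mu, ci_halfwidth = hw, valid = valid,
                 r_bar = rbar, n = n)
}

#' Circular-linear correlation (Mardia)
#'
#' Correlation between an angular and a linear variable through the
#' correlations of the linear variable with the sine and cosine components;
#' `rho` lies in `[0, 1]` and the p-value uses the chi-square approximation
#' `n * rho^2 ~ chisq(2)`.
#'
#' @param angles Angles in radians.
#' @param x Linear variable, same length, `n >= 5`, non-degenerate.
#' @return Tibble with `rho`, `p`, `n`.
#' @export
circ_linear_corr <- function(angles, x) {
  n <- length(angles)
  if (length(x) != n) stop_invalid("lengths differ")
  if (n < 5) stop_invalid("need n >= 5")
  if (sd(x) == 0) stop_invalid("`x` has zero variance")
  rxc <- cor(x, cos(angles))
  rxs <- cor(x, sin(angles))
  rcs <- cor(cos(angles), sin(angles))
  rho2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  rho2 <- min(max(rho2, 0), 1)
  p <- 1 - pchisq(n * rho2, df = 2)
  tibble::tibble(rho = sqrt(rho2), p = p, n = n)
}

#' Two-way ANOVA for circular data (Harrison-Kanji)
#'
#' Tests two factors and their interaction on an angular response. With a
#' concentrated sample (estimated kappa > 2) the high-concentration
#' decomposition with F statistics is used; otherwise the low-concentration
#' chi-square approximation based on component resultants. The branch taken
#' is recorded in the output.
#'
#' @param angles Angles in radians.
#' @param factor_a,factor_b Factors, >= 2 levels each, >= 5 observations
#'   per cell.
#' @return Tibble with one row per term (`A`, `B`, `A:B`): `statistic`,
#'   `df` (plus `df2` for the F branch), `p`, `branch`.
#' @export
circ_anova2 <- function(angles, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop_invalid("both factors need >= 2 levels")
  tabn <- table(fa, fb)
  if (any(tabn == 0)) {
    bad <- which(tabn == 0, arr.ind = TRUE)[1, ]
    stop_invalid("empty cell: %s x %s",
                 levels(fa)[bad[1]], levels(fb)[bad[2]])
  }
  if (any(tabn < 5))
    warning("cells with < 5 observations; approximations may be poor")
  n <- length(angles)
  p <- nlevels(fa); q <- nlevels(fb)

  if (circ_r(angles) >= 1 - 1e-12) {
    # identical angles: no variation to decompose
    return(tibble::tibble(
      term = c("A", "B", "A:B"), statistic = 0,
      df = c(p - 1, q - 1, (p - 1) * (q - 1)), df2 = NA_real_,
      p = 1, branch = "degenerate"))
  }

  Rlen <- function(idx) {
    length(idx) * circ_r(angles[idx])
  }
  tr <- n * circ_r(angles)
  pn <- as.numeric(table(fa)); qn <- as.numeric(table(fb))
  pr <- vapply(levels(fa), function(l) Rlen(which(fa == l)), numeric(1))
  qr <- vapply(levels(fb), function(l) Rlen(which(fb == l)), numeric(1))
  cn <- as.numeric(t(tabn)); cr <- numeric(p * q)
  k <- 0
  for (i in levels(fa)) for (j in levels(fb)) {
    k <- k + 1
    cr[k] <- Rlen(which(fa == i & fb == j))
  }

  kk <- circ_kappa(circ_r(angles))
  df1 <- p - 1; df2f <- q - 1; df12 <- (p - 1) * (q - 1)

  if (kk > 2) {
    # high-concentration branch: F ratios on resultant decomposition
    eff_a <- sum(pr^2 / pn) - tr^2 / n
    eff_b <- sum(qr^2 / qn) - tr^2 / n
    eff_ab <- sum(cr^2 / cn) - sum(pr^2 / pn) - sum(qr^2 / qn) + tr^2 / n
    eff_res <- n - sum(cr^2 / cn)
    df_res <- n - p * q
    corr <- 1 + 3 / (8 * kk)
    ms_res <- eff_res / df_res
    Fs <- corr * c(eff_a / df1, eff_b / df2f, eff_ab / df12) / ms_res
    Fs[!is.finite(Fs) | Fs < 0] <- 0
    pv <- stats::pf(Fs, c(df1, df2f, df12), df_res, lower.tail = FALSE)
    tibble::tibble(term = c("A", "B", "A:B"), statistic = Fs,
                   df = c(df1, df2f, df12), df2 = df_res, p = pv,
                   branch = "F_highkappa")
  } else {
    # low-concentration branch: chi-square on component resultants. Both
    # the cosine and sine components of each marginal resultant contribute
    # a chi-square(levels - 1), so each term carries twice the usual
    # between-levels df (a two-level factor is tested on 2 df).
    rr <- besselI(kk, 1) / besselI(kk, 0)
    f <- 2 / (1 - rr^2)
    chi_a <- f * (sum(pr^2 / pn) - tr^2 / n)
    chi_b <- f * (sum(qr^2 / qn) - tr^2 / n)
    chi_ab <- f * (sum(cr^2 / cn) - sum(pr^2 / pn) - sum(qr^2 / qn) +
                     tr^2 / n)
    stats <- pmax(c(chi_a, chi_b, chi_ab), 0)
    dfs <- 2 * c(df1, df2f, df12)
    pv <- pchisq(stats, dfs, lower.tail = FALSE)
    tibble::tibble(term = c("A", "B", "A:B"), statistic = stats,
                   df = dfs, df2 = NA_real_, p = pv,
                   branch = "chisq_lowkappa")
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction across one analysis run's family
#' of tests (all subgroup x band x condition tests).
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Dichotomize GABA+ at the within-group median
#'
#' Values at or below their own group's median are labelled `low`, above it
#' `high` (ties deterministically to `low`).
#'
#' @param values Numeric GABA+ values.
#' @param group Group labels, same length; >= 2 subjects per group.
#' @return Character vector `low`/`high`.
#' @export
dichotomize_gaba <- function(values, group) {
  stopifnot(length(values) == length(group))
  if (any(table(group) < 2)) stop_invalid("need >= 2 subjects per group")
  out <- character(length(values))
  for (g in unique(group)) {
    idx <- group == g
    out[idx] <- ifelse(values[idx] <= median(values[idx]), "low", "high")
  }
  out
}
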