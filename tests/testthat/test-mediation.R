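# exGaussian moderated mediation: density, posterior summaries, fitting,
# conditional effects, total-effect decomposition.

test_that("exGaussian density integrates to one and has the right mean", {
  x <- seq(-10, 30, by = 0.01)
  d <- ispcmed:::dexgauss(x, mu = 1, sigma = 0.8, beta = 2)
  expect_equal(sum(d) * 0.01, 1, tolerance = 1e-4)
  expect_equal(sum(x * d) * 0.01, 1 + 2, tolerance = 1e-3)
})

test_that("pd and its p-value conversion follow the definitions", {
  expect_equal(pd(rep(2, 1500)), 100)
  expect_equal(pd(c(-(1:750), 1:750)), 50)
  set.seed(61)
  expect_equal(pd(rnorm(2e5, 1, 1)), 100 * pnorm(1), tolerance = 0.005)
  expect_warning(p0 <- pd(rep(0, 1200)), "zero")
  expect_equal(p0, 50)

  expect_equal(pd_to_p(97.5), 0.05)
  expect_equal(pd_to_p(50), 1)
  expect_equal(pd_to_p(100), 0)
  expect_error(pd_to_p(40), class = "ispcmed_invalid_argument")
})

test_that("the highest density interval is the shortest mass interval", {
  set.seed(62)
  u <- runif(5e4)
  h <- hdi(u)
  expect_equal(unname(diff(h)), 0.89, tolerance = 0.02)
  z <- rnorm(1e5)
  hz <- hdi(z)
  expect_equal(unname(hz), c(-1.598, 1.598), tolerance = 0.03)
  expect_equal(unname(hdi(rep(3, 2000))), c(3, 3))
  expect_error(hdi(z, mass = 1.2), class = "ispcmed_invalid_argument")
})

test_that("pd and HDI transform correctly under rescaling and sign flip", {
  set.seed(63)
  d <- rnorm(5000, 0.4, 1)
  expect_equal(pd(d), pd(3.7 * d))
  expect_equal(pd(-d), pd(d))  # dominant side flips, value unchanged
  expect_gt(mean(-d < 0), 0.5)
  expect_equal(unname(hdi(2 * d)), unname(2 * hdi(d)), tolerance = 1e-9)
})

test_that("near-noiseless models are recovered almost exactly", {
  # the deterministic limit must be taken one model at a time: with *both*
  # residuals at zero the mediator is an exact linear function of X, W and
  # XW and the outcome model loses identifiability of (c1, b1).
  tr_out <- mediation_truth(a1 = 0.5, b1 = -0.4, c1 = 0.3,
                            sigma1 = 0.02, beta1 = 0.02)
  co <- generate_cohort(60, 60, tr_out, seed = 64)
  fit <- suppressWarnings(
    fit_mediation(co, chains = 2, iter = 3000, warmup = 1000, seed = 65))
  est <- tidy(fit)
  expect_lt(abs(est$mean[est$parameter == "b1"] - (-0.4)), 0.02)
  expect_lt(abs(est$mean[est$parameter == "c1"] - 0.3), 0.02)

  tr_med <- mediation_truth(a1 = 0.5, b1 = -0.4, a2 = 0.2,
                            sigma2 = 0.02, beta2 = 0.02)
  co2 <- generate_cohort(60, 60, tr_med, seed = 66)
  fit2 <- suppressWarnings(
    fit_mediation(co2, chains = 2, iter = 3000, warmup = 1000, seed = 67))
  est2 <- tidy(fit2)
  expect_lt(abs(est2$mean[est2$parameter == "a1"] - 0.5), 0.02)
  expect_lt(abs(est2$mean[est2$parameter == "a2"] - 0.2), 0.02)
})

test_that("Gaussian-limit posterior means match least squares", {
  tr <- mediation_truth(a1 = 0.5, b1 = -0.4, c1 = 0.2,
                        sigma1 = 0.5, beta1 = 0.01,
                        sigma2 = 0.5, beta2 = 0.01)
  co <- generate_cohort(200, 200, tr, seed = 66)
  fit <- suppressWarnings(
    fit_mediation(co, chains = 4, iter = 2000, warmup = 1000, seed = 67))
  est <- tidy(fit)
  ols_out <- coef(lm(Y ~ X * W + M + M:W, data = co))
  ols_med <- coef(lm(M ~ X * W, data = co))
  pairs <- list(c("c1", "X"), c("b1", "M"), c("a1", "X"))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    model <- if (p[1] %in% c("a1", "a2", "a3", "i2")) "mediator" else
      "outcome"
    ols <- if (model == "mediator") ols_med else ols_out
    row <- est[est$parameter == p[1] & est$model == model, ]
    post_sd <- (row$hdi89_hi - row$hdi89_lo) / (2 * qnorm(0.945))
    expect_lt(abs(row$mean - ols[[p[2]]]), 2 * post_sd)
  }
})

test_that("centering contract is enforced", {
  co <- generate_cohort(30, 30, seed = 68)
  co$X <- co$X + 5
  expect_error(
    fit_mediation(co, center = FALSE, chains = 1, iter = 500,
                  warmup = 200),
    "center")
  expect_error(fit_mediation(co[1:10, ]),
               class = "ispcmed_invalid_argument")
})

test_that("conditional effects respond to moderation as planted", {
  # no moderation: conditional effects identical across W levels
  tr0 <- mediation_truth(a1 = 0.5, b1 = -0.4, a3 = 0, b2 = 0, c3 = 0)
  co0 <- generate_cohort(60, 60, tr0, seed = 69)
  fit0 <- suppressWarnings(
    fit_mediation(co0, chains = 2, iter = 1500, warmup = 500, seed = 70))
  ce0 <- suppressWarnings(conditional_effects(fit0))
  lv <- unique(ce0$w_level)
  expect_length(lv, 2)
  # W is binary ±0.5: quintile levels equal the two group codes
  expect_equal(sort(lv), c(-0.5, 0.5), tolerance = 1e-9)
  d_alpha <- ce0$alpha[ce0$w_level == lv[1]] -
    ce0$alpha[ce0$w_level == lv[2]]
  # without moderation the level difference is -a3, centered on 0 within
  # its own posterior uncertainty
  expect_lt(abs(mean(d_alpha)), 3 * sd(d_alpha))

  # planted a3 > 0: alpha at the high-W level dominates
  tr1 <- mediation_truth(a1 = 0.3, a3 = 0.6, b1 = -0.4)
  co1 <- generate_cohort(100, 100, tr1, seed = 71)
  fit1 <- suppressWarnings(
    fit_mediation(co1, chains = 2, iter = 2000, warmup = 700, seed = 72))
  ce1 <- suppressWarnings(conditional_effects(fit1))
  hi <- ce1$alpha[ce1$w_level == max(ce1$w_level)]
  lo <- ce1$alpha[ce1$w_level == min(ce1$w_level)]
  expect_gt(mean(hi > lo), 0.95)
})

test_that("total effect decomposes into direct plus indirect", {
  tr <- mediation_truth(a1 = 0.5, b1 = -0.4, c1 = 0.3,
                        sigma1 = 0.3, beta1 = 0.05,
                        sigma2 = 0.3, beta2 = 0.05)
  co <- generate_cohort(150, 150, tr, seed = 73)
  fit <- suppressWarnings(
    fit_mediation(co, chains = 2, iter = 2500, warmup = 800, seed = 74))
  te <- suppressWarnings(
    total_effect(co, chains = 2, iter = 2500, warmup = 800, seed = 75))
  ce <- suppressWarnings(conditional_effects(fit, w_levels = 0))
  tau <- mean(te$draws[, "tau1"])
  tau_p <- mean(ce$tau_prime)
  ind <- mean(ce$indirect)
  # tau ~ tau' + alpha*beta at the moderator center
  expect_lt(abs(tau - (tau_p + ind)), 0.08)
  expect_lt(abs(tau - (0.3 + 0.5 * -0.4)), 0.15)
})

test_that("fit summaries expose diagnostics and fit quality", {
  co <- generate_cohort(40, 40, seed = 76)
  fit <- suppressWarnings(
    fit_mediation(co, chains = 2, iter = 1500, warmup = 500, seed = 77))
  g <- glance(fit)
  expect_true(all(c("converged", "max_rhat", "min_ess", "r2_outcome",
                    "r2_mediator") %in% names(g)))
  expect_gt(g$r2_mediator, 0)
  expect_lt(g$r2_mediator, 1)
  td <- tidy(fit)
  expect_true(all(c("pd", "p_equiv", "rhat", "ess") %in% names(td)))
  expect_equal(nrow(td), 14)
})
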