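# Rayleigh test, circular mean CI, circular-linear correlation, two-way
# circular ANOVA, FDR, GABA dichotomization.

test_that("Rayleigh statistic follows z = n * Rbar^2", {
  r1 <- rayleigh_test(rep(1.2, 10))
  expect_equal(r1$r_bar, 1)
  expect_equal(r1$z, 10)
  expect_lt(r1$p, 1e-3)

  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  r2 <- rayleigh_test(grid)
  expect_equal(r2$z, 0, tolerance = 1e-12)
  expect_gt(r2$p, 0.9)

  expect_error(rayleigh_test(c(0, 1, 2)),
               class = "ispcmed_invalid_argument")
})

test_that("Rayleigh p agrees with a uniform-null Monte-Carlo oracle", {
  n <- 10
  set.seed(31)
  null_z <- replicate(4000, {
    th <- runif(n, -pi, pi)
    n * circ_r(th)^2
  })
  # compare analytic p to the MC null tail at several quantiles
  for (q in c(0.5, 0.9, 0.95)) {
    zq <- unname(quantile(null_z, q))
    R <- sqrt(zq * n)
    p_analytic <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
    expect_lt(abs(p_analytic - (1 - q)), 0.02)
  }
})

test_that("Rayleigh rejection rate under von Mises matches the MC oracle", {
  n <- 50
  set.seed(32)
  crit <- unname(quantile(replicate(2000, n * circ_r(runif(n, -pi, pi))^2), 0.95))
  rej_mc <- 0; rej_an <- 0
  for (r in 1:400) {
    th <- ispcmed:::rvonmises(n, 0, 2)
    z <- n * circ_r(th)^2
    rej_mc <- rej_mc + (z > crit)
    rej_an <- rej_an + (rayleigh_test(th)$p < 0.05)
  }
  expect_lt(abs(rej_mc - rej_an) / 400, 0.02)
})

test_that("circular mean CI behaves at the boundaries and under wrap", {
  c1 <- circ_mean_ci(rep(0.4, 20))
  expect_equal(c1$ci_halfwidth, 0)
  expect_true(c1$valid)

  deg <- c(170, -170) / 180 * pi
  expect_equal(abs(circ_mean(deg)), pi, tolerance = 1e-12)

  # dispersed sample: CI undefined and flagged
  set.seed(33)
  c2 <- circ_mean_ci(runif(8, -pi, pi))
  if (!c2$valid) expect_true(is.na(c2$ci_halfwidth))
})

test_that("circular mean CI attains nominal coverage under von Mises", {
  set.seed(34)
  mu <- 30 / 180 * pi
  cover <- vapply(1:500, function(r) {
    th <- ispcmed:::rvonmises(200, mu, 5)
    ci <- circ_mean_ci(th)
    ci$valid && abs(wrap_pi(ci$mean_dir - mu)) <= ci$ci_halfwidth
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("circular-linear correlation matches its component formula", {
  set.seed(35)
  th <- runif(10, -pi, pi)
  x <- cos(th)
  expect_equal(circ_linear_corr(th, x)$rho, 1, tolerance = 1e-9)

  # worked dataset against the formula evaluated by brute force
  th2 <- runif(10, -pi, pi)
  y <- 0.3 * sin(th2) + rnorm(10, 0, 0.4)
  got <- circ_linear_corr(th2, y)
  rxc <- cor(y, cos(th2)); rxs <- cor(y, sin(th2))
  rcs <- cor(cos(th2), sin(th2))
  rho_oracle <- sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(got$p, 1 - pchisq(10 * rho_oracle^2, 2), tolerance = 1e-12)

  expect_error(circ_linear_corr(th2, rep(1, 10)),
               class = "ispcmed_invalid_argument")
  expect_error(circ_linear_corr(th2[1:4], y[1:4]),
               class = "ispcmed_invalid_argument")
})

test_that("circular-linear correlation p agrees with a permutation oracle
           on small samples", {
  set.seed(36)
  n <- 12
  th <- runif(n, -pi, pi)
  x <- 0.8 * cos(th) + rnorm(n, 0, 0.6)
  p_an <- circ_linear_corr(th, x)$p
  rho_obs <- circ_linear_corr(th, x)$rho
  perm <- replicate(3000, circ_linear_corr(th, sample(x))$rho)
  p_perm <- (sum(perm >= rho_obs) + 1) / 3001
  expect_lt(abs(p_an - p_perm), 0.06)
})

test_that("two-way circular ANOVA is calibrated and detects planted
           shifts", {
  # null: all four cells from the same von Mises
  set.seed(37)
  rej <- matrix(0, 200, 3)
  for (r in 1:200) {
    th <- ispcmed:::rvonmises(80, 0, 1.5)
    A <- rep(c("a1", "a2"), each = 40)
    B <- rep(rep(c("b1", "b2"), each = 20), 2)
    tab <- circ_anova2(th, A, B)
    rej[r, ] <- tab$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates < 0.12))   # nominal 0.05 within binomial noise

  # 90 degree shift on factor A only
  set.seed(38)
  hits <- replicate(50, {
    thA <- c(ispcmed:::rvonmises(40, 0, 3),
             ispcmed:::rvonmises(40, pi / 2, 3))
    A <- rep(c("a1", "a2"), each = 40)
    B <- rep(rep(c("b1", "b2"), each = 20), 2)
    tab <- circ_anova2(thA, A, B)
    c(tab$p[tab$term == "A"] < 0.05, tab$p[tab$term == "B"] < 0.05)
  })
  expect_gt(mean(hits[1, ]), 0.9)    # A detected
  expect_lt(mean(hits[2, ]), 0.15)   # B at the null rate

  # degenerate: identical angles everywhere
  tab0 <- suppressWarnings(
    circ_anova2(rep(1, 40), rep(c("x", "y"), 20),
                rep(c("u", "u", "v", "v"), 10)))
  expect_true(all(tab0$statistic == 0))

  expect_error(circ_anova2(runif(10), rep("a", 10), rep(c("u", "v"), 5)),
               class = "ispcmed_invalid_argument")
})

test_that("circular statistics are invariant to global rotation", {
  set.seed(39)
  th <- ispcmed:::rvonmises(60, 0.3, 2)
  x <- rnorm(60)
  rot <- wrap_pi(th + 1.234)
  expect_equal(rayleigh_test(th)$z, rayleigh_test(rot)$z,
               tolerance = 1e-10)
  expect_equal(circ_linear_corr(th, x)$rho, circ_linear_corr(rot, x)$rho,
               tolerance = 1e-10)
  expect_equal(wrap_pi(circ_mean(rot) - circ_mean(th)), 1.234,
               tolerance = 1e-10)
  A <- rep(c("a", "b"), 30); B <- rep(c("u", "u", "v", "v"), 15)
  expect_equal(circ_anova2(th, A, B)$statistic,
               circ_anova2(rot, A, B)$statistic, tolerance = 1e-8)
})

test_that("BH adjustment matches hand-computed values", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.04, 0.2)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.1, 1.2)), class = "ispcmed_invalid_argument")
})

test_that("GABA dichotomization splits at the within-group median", {
  expect_identical(dichotomize_gaba(c(1, 2, 3, 4), rep("g", 4)),
                   c("low", "low", "high", "high"))
  # two groups with disjoint ranges: labels depend only on in-group rank
  v <- c(1, 2, 3, 101, 102, 103)
  g <- rep(c("a", "b"), each = 3)
  expect_identical(dichotomize_gaba(v, g),
                   rep(c("low", "low", "high"), 2))
  # cohort proportions near 50/50 per group
  co <- generate_cohort(15, 16, seed = 40)
  lab <- dichotomize_gaba(co$gaba_raw_RIGHT_SM1, co$group)
  tab <- table(lab, co$group)
  expect_true(all(abs(tab["low", ] - tab["high", ]) <= 1))
})
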