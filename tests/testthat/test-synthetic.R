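# Paradigm schedule, tap stream, source and cohort generators.

test_that("schedule satisfies the paradigm event invariants", {
  s <- generate_schedule(300, seed = 11)
  expect_true(all(diff(s$onset_ms) > 0))
  # every tRT is followed by a pause at exactly 1000 ms
  trt <- which(s$event == "tRT")
  trt <- trt[trt < nrow(s)]
  expect_true(all(s$event[trt + 1] == "pause"))
  expect_true(all(abs(s$onset_ms[trt + 1] - s$onset_ms[trt] - 1000) < 1e-9))
  # pauses last 3000 ms before the next event
  pauses <- which(s$event == "pause")
  pauses <- pauses[pauses < nrow(s)]
  expect_true(all(abs(s$onset_ms[pauses + 1] - s$onset_ms[pauses] - 3000)
                  < 1e-9))
  # ISI after non-pause, non-tRT events within [5000, 8000]
  oth <- which(!s$event %in% c("pause", "tRT"))
  oth <- oth[oth < nrow(s)]
  isi <- s$onset_ms[oth + 1] - s$onset_ms[oth]
  expect_true(all(isi >= 5000 & isi <= 8000))
})

test_that("schedule edge cases and argument validation", {
  s0 <- generate_schedule(50, p_trt = 0, seed = 3)
  expect_identical(sum(s0$event == "tRT"), 0L)
  expect_error(generate_schedule(0), class = "ispcmed_invalid_argument")
  expect_error(generate_schedule(10, p_trt = 1),
               class = "ispcmed_invalid_argument")
})

test_that("design probabilities are recovered in a long session", {
  s <- generate_schedule(4000, seed = 5)   # ~12000 events
  n_ev <- nrow(s)
  frac <- mean(s$event == "tRT")
  se <- sqrt(0.05 * 0.95 / n_ev)
  expect_lt(abs(frac - 0.05), 3 * se + 0.05 * 0.05)  # small pause dilution
  n_sw <- sum(s$event == "switch"); n_co <- sum(s$event == "continue")
  ratio <- n_sw / n_co
  # delta-method SE of the count ratio p/(1-p) at p = 5/6
  n_tr <- n_sw + n_co
  se_r <- sqrt((5 / 6) / (1 / 6)^3 / n_tr)
  expect_lt(abs(ratio - 5), 3 * se_r)
})

test_that("regeneration with an identical seed is bit-identical", {
  expect_identical(generate_schedule(100, seed = 9),
                   generate_schedule(100, seed = 9))
  s <- generate_schedule(20, seed = 2)
  expect_identical(generate_tap_stream(s, seed = 4),
                   generate_tap_stream(s, seed = 4))
  expect_identical(generate_cohort(10, 10, seed = 6),
                   generate_cohort(10, 10, seed = 6))
  src1 <- generate_sources(3, coupling_spec(snr = 2), seed = 8)
  src2 <- generate_sources(3, coupling_spec(snr = 2), seed = 8)
  expect_identical(src1$data, src2$data)
})

test_that("tap stream round-trips fixed and stochastic latencies", {
  sched <- generate_schedule(80, p_trt = 0, seed = 21)
  taps <- generate_tap_stream(
    sched, latency_dist = list(type = "fixed", value_ms = 500),
    async_sd_ms = 1, seed = 22)
  sc <- score_trials(taps, sched)
  sc <- sc[sc$hurdle_code != "missing", ]
  beat <- 500   # ms at the default 2 Hz pacing
  expect_true(all(abs(sc$latency_ms - 500) <= beat + 5))

  # gamma(9, 60) latencies: scored median within 3 SE of the distribution
  # median (Monte-Carlo oracle)
  sched2 <- generate_schedule(400, p_trt = 0, seed = 31)
  taps2 <- generate_tap_stream(
    sched2, latency_dist = list(type = "gamma", shape = 9, scale_ms = 60),
    async_sd_ms = 1, seed = 32)
  sc2 <- score_trials(taps2, sched2)
  lat <- sc2$latency_ms[!is.na(sc2$latency_ms)]
  set.seed(33)
  oracle <- replicate(500, median(rgamma(length(lat), 9, scale = 60)))
  med_true <- median(rgamma(2e5, 9, scale = 60))
  tol <- 3 * sd(oracle) + beat   # quantized by the tap grid
  expect_lt(abs(median(lat) - med_true), tol)
})

test_that("always-wrong error model produces failed transitions", {
  sched <- generate_schedule(40, p_trt = 0, seed = 41)
  taps <- generate_tap_stream(sched, error_model = list(type = "always",
                                                        window_ms = 2000),
                              seed = 42)
  sc <- score_trials(taps, sched)
  sc <- sc[sc$hurdle_code != "missing", ]
  expect_true(all(sc$hurdle_code == "failed"))
  expect_true(all(is.na(sc$latency_ms)))
  expect_error(generate_tap_stream(sched[0, ], seed = 1),
               class = "ispcmed_invalid_argument")
})

test_that("source generator obeys the coupling specification", {
  # lag distribution converges to the von Mises parameters
  cp <- coupling_spec(band = c(15, 22), mean_lag = pi / 3, kappa = 6,
                      snr = 4)
  src <- generate_sources(500, cp, seed = 51)
  lags <- src$trial_info$true_lag
  se_mu <- 1 / sqrt(500 * 6 * circ_r(lags))
  expect_lt(abs(circ_mean(lags) - pi / 3), 3 * se_mu)
  kap_hat <- ispcmed:::circ_kappa(circ_r(lags))
  expect_lt(abs(kap_hat - 6) / 6, 0.3)
  expect_error(generate_sources(5, coupling_spec(band = c(15, 30)), fs = 50),
               class = "ispcmed_invalid_argument")
})

test_that("mean_lag = pi round-trips through the spectral pipeline", {
  cp <- coupling_spec(band = c(15, 22), mean_lag = pi, kappa = 50, snr = 10)
  src <- generate_sources(30, cp, seed = 61)
  bank <- design_bank(fmin = 10, fmax = 30, n = 10, fs = 250)
  pa <- tf_phase(decompose(src, bank, source = "LSM1"))
  pb <- tf_phase(decompose(src, bank, source = "RSM1"))
  lag <- extract_phase_lag(pa, pb, bank$freqs, src$time_s, c(15, 22), 0)
  ci <- circ_mean_ci(lag$lag_rad)
  expect_true(ci$valid)
  d <- abs(wrap_pi(ci$mean_dir - pi))
  expect_lt(d, max(3 * ci$ci_halfwidth, 0.25))
})

test_that("cohort with zero noise reproduces the model equations exactly", {
  tr <- mediation_truth(a1 = 0.5, a2 = 0.3, a3 = -0.2, b1 = -0.4,
                        b2 = 0.1, c1 = 0.25, c2 = -0.15, c3 = 0.05,
                        i1 = 1, i2 = 2, sigma1 = 0, beta1 = 0,
                        sigma2 = 0, beta2 = 0)
  co <- generate_cohort(20, 20, tr, seed = 71)
  M_pred <- 2 + 0.5 * co$X + 0.3 * co$W - 0.2 * co$X * co$W
  Y_pred <- 1 + 0.25 * co$X - 0.15 * co$W + 0.05 * co$X * co$W -
    0.4 * co$M + 0.1 * co$M * co$W
  expect_equal(co$M, M_pred, tolerance = 1e-12)
  expect_equal(co$Y, Y_pred, tolerance = 1e-12)
})

test_that("group GABA offset appears in sensorimotor but not occipital voxels", {
  co <- generate_cohort(40, 40, seed = 81)
  p_sm <- t.test(gaba_raw_RIGHT_SM1 ~ group, data = co)$p.value
  p_sm2 <- t.test(gaba_raw_LEFT_SM1 ~ group, data = co)$p.value
  p_occ <- t.test(gaba_raw_OCC ~ group, data = co)$p.value
  expect_lt(p_sm, 0.001)
  expect_lt(p_sm2, 0.001)
  expect_gt(p_occ, 0.05)
})

test_that("ground truth round-trips losslessly through JSON", {
  co <- generate_cohort(5, 5, seed = 91)
  truth <- attr(co, "truth")
  path <- tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back[names(truth)], truth, tolerance = 1e-15)
})

test_that("epoched sources round-trip through the TSV interchange", {
  src <- generate_sources(3, coupling_spec(), seed = 95)
  path <- tempfile(fileext = ".tsv")
  write_sources_tsv(src, path)
  back <- read_sources_tsv(path)
  expect_equal(back$data, src$data, tolerance = 1e-12)
  expect_equal(back$fs, src$fs)
  expect_equal(back$time_s, src$time_s, tolerance = 1e-12)
})
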