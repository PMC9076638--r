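# ISPC identities, baseline subtraction, response locking, band-pooled
# phase lags.

freqs3 <- c(10, 15, 20)
tax <- seq(0, 0.38, by = 0.02)

test_that("ISPC equals 1 for any constant lag and 0 for canceling lags", {
  set.seed(1)
  p <- make_phase_pair(rep(0, 8))
  m0 <- ispc(p$a, p$b, freqs3, tax, fs = 50, grid_hz = 50)
  expect_equal(max(abs(m0$values - 1)), 0, tolerance = 1e-12)

  p_pi <- make_phase_pair(rep(pi, 8))
  m_pi <- ispc(p_pi$a, p_pi$b, freqs3, tax, fs = 50, grid_hz = 50)
  expect_equal(max(abs(m_pi$values - 1)), 0, tolerance = 1e-12)

  p_c <- make_phase_pair(c(0, pi / 2, pi, 3 * pi / 2))
  m_c <- ispc(p_c$a, p_c$b, freqs3, tax, fs = 50, grid_hz = 50)
  expect_equal(max(abs(m_c$values)), 0, tolerance = 1e-10)

  expect_error(ispc(p$a[1, , , drop = FALSE], p$b[1, , , drop = FALSE],
                    freqs3, tax), class = "ispcmed_invalid_argument")
})

test_that("ISPC is symmetric in pair order and lag-invariant", {
  set.seed(2)
  p <- make_phase_pair(vm_sample(12, 0.5, 2, seed = 3))
  m_ab <- ispc(p$a, p$b, freqs3, tax, fs = 50, grid_hz = 50)
  m_ba <- ispc(p$b, p$a, freqs3, tax, fs = 50, grid_hz = 50)
  expect_equal(m_ab$values, m_ba$values, tolerance = 1e-12)

  shift <- wrap_pi(p$a + 1.1)
  m_shift <- ispc(shift, p$b, freqs3, tax, fs = 50, grid_hz = 50)
  expect_equal(m_shift$values, m_ab$values, tolerance = 1e-10)
})

test_that("ISPC grows monotonically with the lag concentration", {
  vals <- vapply(c(0, 1, 4, 16), function(kap) {
    lags <- vm_sample(200, 0, kap, seed = 100 + kap)
    set.seed(200 + kap)
    p <- make_phase_pair(lags)
    mean(ispc(p$a, p$b, freqs3, tax, fs = 50, grid_hz = 50)$values)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("uniform-lag ISPC matches the analytic resultant-length oracle", {
  set.seed(4)
  reps <- vapply(1:300, function(r) {
    Mod(mean(exp(1i * runif(100, -pi, pi))))
  }, numeric(1))
  # E|mean of n uniform unit vectors| = sqrt(pi)/(2 sqrt(n))
  expect_lt(abs(mean(reps) - sqrt(pi) / 2 / sqrt(100)),
            3 * sd(reps) / sqrt(300))
})

test_that("baseline subtraction removes the per-frequency baseline", {
  vals <- matrix(0.2, 3, 20)
  m <- ispcmed:::new_ispc_map(vals, freqs3, seq(-0.5, 1.4, by = 0.1),
                              "raw", c("A", "B"), "stimulus", 10)
  d0 <- baseline_subtract(m, baseline_window_ms = c(-500, -200))
  expect_equal(max(abs(d0$values)), 0)
  expect_identical(d0$variant, "baseline_subtracted")

  vals2 <- vals; vals2[2, 15] <- 0.5
  m2 <- ispcmed:::new_ispc_map(vals2, freqs3, seq(-0.5, 1.4, by = 0.1),
                               "raw", c("A", "B"), "stimulus", 10)
  d2 <- baseline_subtract(m2, baseline_window_ms = c(-500, -200))
  expect_equal(d2$values[2, 15], 0.3, tolerance = 1e-12)
  m3 <- m2; m3$freqs <- freqs3 + 1
  expect_error(baseline_subtract(m2, m3),
               class = "ispcmed_invalid_argument")
})

test_that("response locking recenters on the per-condition median latency", {
  src <- generate_sources(6, coupling_spec(), seed = 5)
  trials <- tibble::tibble(
    latency_ms = c(500, 500, 500, 900, 900, NA),
    transition_mode = c(rep("into_IP", 3), rep("into_AP", 2), "into_IP"))
  suppressMessages(rl <- response_lock(src, trials, half_window_ms = 260))
  expect_identical(rl$alignment, "response")
  expect_equal(dim(rl$data)[1], 5)   # failed trial dropped
  fs <- src$fs
  # uniform 500 ms shift for the IP trials
  c_idx <- which.min(abs(src$time_s - 0.5))
  half_n <- round(0.26 * fs)
  expect_equal(rl$data[1, 1, ],
               src$data[1, 1, (c_idx - half_n):(c_idx + half_n)])
  # AP trials recentered 400 ms later than IP trials
  c_idx2 <- which.min(abs(src$time_s - 0.9))
  expect_equal(rl$data[4, 1, ],
               src$data[4, 1, (c_idx2 - half_n):(c_idx2 + half_n)])
  # even-count median = midpoint of the central pair
  med <- attr(rl, "median_latency_ms")
  expect_equal(unname(med[["into_AP"]]), 900)
  tr2 <- tibble::tibble(latency_ms = c(400, 600, 400, 600, 400, 600),
                        transition_mode = "into_IP")
  rl2 <- response_lock(src, tr2)
  expect_equal(unname(attr(rl2, "median_latency_ms")[["into_IP"]]), 500)
})

test_that("band pooling uses the circular mean of per-bin lags", {
  set.seed(6)
  # single-bin band equals the raw difference
  p <- make_phase_pair(c(0.7, -0.3), n_freq = 3, n_time = 5)
  one <- extract_phase_lag(p$a, p$b, freqs3, seq(0, 0.4, 0.1),
                           band = c(14, 16), at_time_s = 0.2)
  expect_equal(one$lag_rad, c(0.7, -0.3), tolerance = 1e-10)

  # identical lag across bins -> that lag
  all_bins <- extract_phase_lag(p$a, p$b, freqs3, seq(0, 0.4, 0.1),
                                band = c(5, 25), at_time_s = 0.2)
  expect_equal(all_bins$lag_rad, c(0.7, -0.3), tolerance = 1e-10)

  # {+170, -170} degrees pools to 180, not 0
  a <- array(0, c(1, 2, 3))
  b <- array(0, c(1, 2, 3))
  b[1, 1, ] <- -170 / 180 * pi
  b[1, 2, ] <- 170 / 180 * pi
  lg <- extract_phase_lag(a, b, c(10, 20), c(0, 0.1, 0.2),
                          band = c(5, 25), at_time_s = 0.1)
  expect_equal(abs(lg$lag_rad), pi, tolerance = 1e-10)

  # masked edge sample errors
  edge <- matrix(TRUE, 2, 3)
  expect_error(extract_phase_lag(a, b, c(10, 20), c(0, 0.1, 0.2),
                                 band = c(5, 25), at_time_s = 0.1,
                                 edge = edge),
               class = "ispcmed_invalid_argument")
})
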