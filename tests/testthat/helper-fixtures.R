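# Shared fixtures built in code.

# A constructed tap stream: `pairs` is a data.frame with columns
# time_ms, mode ("in_phase"/"anti_phase"/"thumb"), optional dt_ms.
make_tap_stream <- function(pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    t <- pairs$time_ms[i]
    dt <- if ("dt_ms" %in% names(pairs)) pairs$dt_ms[i] else 0
    switch(pairs$mode[i],
      in_phase = data.frame(time_ms = c(t, t + dt), hand = c("L", "R"),
                            finger = c("index", "index")),
      anti_phase = data.frame(time_ms = c(t, t + dt), hand = c("L", "R"),
                              finger = c("index", "middle")),
      thumb = data.frame(time_ms = t, hand = "L", finger = "thumb"))
  })
  do.call(rbind, rows)
}

# Phase arrays [trial, freq, time] with a constant per-trial lag between the
# two "sources"; base phases are random.
make_phase_pair <- function(lags, n_freq = 3, n_time = 20) {
  n_tr <- length(lags)
  base <- array(runif(n_tr * n_freq * n_time, -pi, pi),
                c(n_tr, n_freq, n_time))
  list(a = base, b = wrap_pi(base - rep(lags, n_freq * n_time)))
}

# Small von Mises sample through the package's own simulator (seeded).
vm_sample <- function(n, mu, kappa, seed) {
  set.seed(seed)
  ispcmed:::rvonmises(n, mu, kappa)
}
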