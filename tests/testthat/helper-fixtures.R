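# shared fixtures: all synthetic, built in code

tone_trace <- function(freq, fs = 2000, dur = 2, amp = 1, phase = 0) {
  t <- seq(0, dur, by = 1 / fs)
  trace(amp * sin(2 * pi * freq * t + phase), fs)
}

# a short session config safe for unit tests (epochs below the standard
# windowing; the generator warns, which we silence here on purpose)
tiny_config <- function(seed = 1, ...) {
  suppressWarnings(sim_config(
    duration = 60, fs = 1250, quiet_pre_len = 25, gamma_len = 10,
    seed = seed, ...))
}

# one noise-free-ish trace holding a single hand-built SWR: Gaussian sharp
# wave (amplitude A mV, envelope SD sigma s) plus an n-cycle ripple burst
single_event_trace <- function(fs = 10000, A = 0.5, sigma = 0.0106,
                               ripple_amp = 0.25, ripple_freq = 180,
                               n_cycles = 7, noise_sd = 0.002, dur = 30,
                               center = dur / 2, seed = 42) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- A * exp(-(t - center)^2 / (2 * sigma^2))
  burst <- n_cycles / ripple_freq
  sig_r <- burst / 6
  x <- x + ripple_amp * exp(-(t - center)^2 / (2 * sig_r^2)) *
    cos(2 * pi * ripple_freq * (t - center))
  set.seed(seed)
  x <- x + rnorm(length(x), sd = noise_sd)
  trace(x, fs)
}

# brute-force Wilcoxon signed-rank two-sided p over all 2^n sign patterns
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# minimal valid event table with n sorted rows
empty_events_fixture <- function(n) {
  data.frame(
    t_start = seq_len(n), t_end = seq_len(n) + 0.05,
    area = rep(0.01, n), sw_amplitude = rep(0.5, n),
    duration_ms = rep(50, n), ripple_count = rep(5L, n),
    ripple_freq = rep(180, n), max_abs_coeff = rep(1, n),
    accepted = rep(TRUE, n), rejection_reason = rep("none", n)
  )[seq_len(n), ]
}
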