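test_that("band splitting separates sharp-wave and ripple components", {
  fs <- 10000
  slow <- tone_trace(20, fs = fs, dur = 4)
  fast <- tone_trace(200, fs = fs, dur = 4)
  both <- trace(slow$samples + fast$samples, fs)
  sp <- split_bands(both)
  core <- (fs):(3 * fs)
  expect_lt(abs(max(abs(sp$sw$samples[core])) - 1), 0.02)
  expect_lt(abs(max(abs(sp$ripple$samples[core])) - 1), 0.02)
  # cross-leakage
  only_slow <- split_bands(slow)
  expect_lt(max(abs(only_slow$ripple$samples[core])), 0.01)
  only_fast <- split_bands(fast)
  expect_lt(max(abs(only_fast$sw$samples[core])), 0.01)
  expect_error(split_bands(trace(rnorm(1000), 500)), "sampling rate")
})

test_that("baseline statistics recover the noise floor and exclude bursts", {
  fs <- 2000
  set.seed(31)
  noise <- trace(rnorm(30 * fs, sd = 0.02), fs)
  bl <- estimate_baseline(noise)
  expect_gt(sum(bl$mask) / length(bl$mask), 0.95)
  expect_lt(abs(bl$sd / 0.02 - 1), 0.05)
  expect_lt(abs(bl$mean), 0.002)

  # add 10 large bursts; their windows must leave the mask
  x <- noise$samples
  burst_at <- seq(2, 29, length.out = 10)
  t <- (seq_along(x) - 1) / fs
  for (b in burst_at)
    x <- x + 0.5 * exp(-(t - b)^2 / (2 * 0.005^2)) * cos(2 * pi * 180 * (t - b))
  bl2 <- estimate_baseline(trace(x, fs))
  for (b in burst_at) {
    idx <- round((b - 0.01) * fs):round((b + 0.01) * fs)
    expect_false(any(bl2$mask[idx]), label = sprintf("burst at %g s", b))
  }

  expect_error(estimate_baseline(trace(rep(1, 30 * fs), fs)), "degenerate")
  expect_error(estimate_baseline(trace(rnorm(fs), fs)), "10 s")
})

test_that("candidate detection finds bursts and honors the grouping rule", {
  fs <- 2000
  set.seed(17)
  sd0 <- 0.02
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mk_burst <- function(at, cycles = 8, f0 = 200, amp = 10 * sd0)
    amp * exp(-(t - at)^2 / (2 * (cycles / f0 / 6)^2)) *
      cos(2 * pi * f0 * (t - at))
  ripple_noise <- bandpass(trace(rnorm(length(t), sd = sd0), fs), 100, 300)

  one <- trace(ripple_noise$samples + mk_burst(15), fs)
  bl <- estimate_baseline(one)
  cand <- detect_ripple_candidates(one, bl)
  expect_equal(nrow(cand), 1)
  expect_true(cand$t_start < 15 && cand$t_end > 15)

  # noise-only trace: no candidates at the 6 SD threshold
  bl0 <- estimate_baseline(ripple_noise)
  expect_equal(nrow(detect_ripple_candidates(ripple_noise, bl0)), 0)

  # burst pairs: supra-threshold edge gap well under / well over 20 ms
  near <- trace(ripple_noise$samples + mk_burst(15) + mk_burst(15.03), fs)
  bl_n <- estimate_baseline(near)
  expect_equal(nrow(detect_ripple_candidates(near, bl_n)), 1)

  far <- trace(ripple_noise$samples + mk_burst(15) + mk_burst(15.09), fs)
  bl_f <- estimate_baseline(far)
  expect_equal(nrow(detect_ripple_candidates(far, bl_f)), 2)
})

test_that("spectral validation keeps genuine ripples and respects limits", {
  tr <- single_event_trace(fs = 2000)
  sp <- split_bands(tr)
  bl <- estimate_baseline(sp$ripple)
  cand <- detect_ripple_candidates(sp$ripple, bl)
  expect_equal(nrow(cand), 1)
  # append pseudo-candidates on pure-noise stretches
  fake <- data.frame(t_start = c(3, 6, 9, 12), t_end = c(3, 6, 9, 12) + 0.03,
                     n_crossings = 5L)
  all_cand <- rbind(cand, fake)[order(c(cand$t_start, fake$t_start)), ]
  val <- spectral_validate(sp$ripple, all_cand, bl)
  genuine <- which.min(abs(val$t_start - 15))
  expect_true(val$accepted[genuine])
  expect_gt(val$max_abs_coeff[genuine], 3 * max(val$max_abs_coeff[-genuine]))

  # spectral_k -> Inf rejects everything
  val_inf <- spectral_validate(sp$ripple, all_cand, bl,
                               detection_config(spectral_k = 1e9))
  expect_false(any(val_inf$accepted))
  expect_true(all(val_inf$rejection_reason[!val_inf$accepted] == "spectral"))
})

test_that("delimitation lands on flanking minima and flags monotone ramps", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  sigma <- 0.012
  bump <- trace(0.5 * exp(-(t - 2)^2 / (2 * sigma^2)), fs)
  d <- delimit_event(bump, c(1.97, 2.03))
  expect_equal(d$polarity, 1)
  expect_lt(abs(d$peak_t - 2), 2 / fs)
  seg <- trace_window(bump, d$t_start, d$t_end)
  mass <- sum(seg$samples) / fs
  expect_gt(mass, 0.95 * 0.5 * sigma * sqrt(2 * pi))

  ramp <- trace(seq(0, 1, length.out = length(t)), fs)
  dr <- delimit_event(ramp, c(1.9, 2.1))
  expect_true(dr$flagged)

  two <- trace(0.5 * exp(-(t - 2)^2 / (2 * sigma^2)) +
                 0.4 * exp(-(t - 2.06)^2 / (2 * sigma^2)), fs)
  d1 <- delimit_event(two, c(1.97, 2.03))
  d2 <- delimit_event(two, c(2.03, 2.09))
  # both delimited at (nearly) the shared valley between the bumps
  expect_lt(abs(d1$t_end - d2$t_start), 0.006)
  expect_true(d1$t_end > 2 && d1$t_end < 2.06)
})

test_that("negative-going sharp waves are delimited with inverted polarity", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  bump <- trace(-0.5 * exp(-(t - 2)^2 / (2 * 0.012^2)), fs)
  d <- delimit_event(bump, c(1.97, 2.03))
  expect_equal(d$polarity, -1)
  q <- quantify_event(bump, trace(numeric(length(t)), fs), d, NULL,
                      sw_level = 0)
  expect_gt(q$area, 0)
  expect_gt(q$sw_amplitude, 0.49)
})

test_that("event quantification matches closed-form areas", {
  fs <- 10000
  A <- 0.5; T <- 0.05
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  half_sine <- ifelse(t >= 0.475 & t < 0.475 + T,
                      A * sin(pi * (t - 0.475) / T), 0)
  sw <- trace(half_sine, fs)
  ev <- list(t_start = 0.475, t_end = 0.475 + T, polarity = 1)
  q <- quantify_event(sw, trace(numeric(length(t)), fs), ev, NULL,
                      sw_level = 0)
  expect_equal(q$area, 2 * A * T / pi, tolerance = 0.02)
  expect_equal(q$duration_ms, 50)
  expect_equal(q$ripple_count, 0)

  z <- quantify_event(trace(numeric(length(t)), fs),
                      trace(numeric(length(t)), fs), ev, NULL, sw_level = 0)
  expect_equal(z$area, 0)
})

test_that("ripple cycles are counted at their generated frequency", {
  tr <- single_event_trace(fs = 10000, n_cycles = 7, ripple_freq = 180)
  ev <- detect_swr(tr)
  acc <- ev[ev$accepted, ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$ripple_count, 7, tolerance = 1.01)  # +-1 cycle at the envelope tail
  expect_lt(abs(acc$ripple_freq / 180 - 1), 0.05)
})

test_that("detection is deterministic and supports manual curation", {
  sim <- simulate_session(tiny_config(seed = 9))
  a <- detect_swr(sim$trace)
  b <- detect_swr(sim$trace)
  expect_identical(a$t_start, b$t_start)
  expect_identical(a$accepted, b$accepted)
  expect_gt(nrow(a), 2)

  cur <- data.frame(event_index = 2L, action = "reject",
                    t_start = NA, t_end = NA)
  c <- detect_swr(sim$trace, curation = cur)
  expect_false(c$accepted[2])
  expect_equal(c$rejection_reason[2], "manual")
  expect_equal(c$accepted[-2], a$accepted[-2])
})

test_that("thresholds are scale-invariant and monotone", {
  sim <- simulate_session(tiny_config(seed = 14))
  base <- detect_swr(sim$trace)
  scaled <- detect_swr(trace(7.3 * sim$trace$samples, sim$trace$fs))
  expect_equal(scaled$t_start, base$t_start, tolerance = 1e-9)
  expect_equal(scaled$accepted, base$accepted)
  expect_equal(scaled$area, 7.3 * base$area, tolerance = 1e-6)

  sp <- split_bands(sim$trace)
  bl <- estimate_baseline(sp$ripple)
  n_cand <- vapply(c(4, 6, 8, 10), function(k)
    nrow(detect_ripple_candidates(sp$ripple, bl,
                                  detection_config(voltage_k = k))),
    numeric(1))
  expect_true(all(diff(n_cand) <= 0))

  cand <- detect_ripple_candidates(sp$ripple, bl)
  n_acc <- vapply(c(0, 1, 3, 1e9), function(k)
    sum(spectral_validate(sp$ripple, cand, bl,
                          detection_config(spectral_k = k))$accepted),
    numeric(1))
  expect_true(all(diff(n_acc) <= 0))
})

test_that("noise-only recordings yield no accepted events", {
  set.seed(51)
  fs <- 1250
  noise <- trace(rnorm(120 * fs, sd = 0.05), fs)
  ev <- detect_swr(noise)
  expect_equal(sum(ev$accepted), 0)
})
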