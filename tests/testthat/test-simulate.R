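test_that("identical configs give identical sessions", {
  cfg <- tiny_config(seed = 5)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("epochs partition the session and events stay in quiet epochs", {
  sim <- simulate_session(tiny_config(seed = 2))
  ep <- sim$truth$epochs
  expect_equal(ep$t_start[1], 0)
  expect_equal(ep$t_end[3], 60)
  expect_equal(ep$t_start[-1], ep$t_end[-3])
  ev <- sim$truth$events
  in_quiet <- (ev$t_end <= ep$t_end[1]) | (ev$t_start >= ep$t_start[3])
  expect_true(all(in_quiet))
  # refractoriness: no overlapping ground-truth events
  expect_true(all(diff(ev$t_start) >= ev$t_end[-nrow(ev)] - ev$t_start[-nrow(ev)]))
})

test_that("zero rate gives an event-free trace", {
  sim <- simulate_session(tiny_config(seed = 1, swr_rate = 0))
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("event counts follow the configured Poisson incidence", {
  # 1.33 Hz over a 120 s quiet window: expect ~159.6 events, tolerate 3*sqrt
  cfg <- suppressWarnings(sim_config(
    duration = 260, fs = 1250, quiet_pre_len = 125, gamma_len = 10, seed = 21))
  sim <- simulate_session(cfg)
  ev <- sim$truth$events
  lambda <- 1.33 * 120
  for (w in list(c(2, 122), c(138, 258))) {
    cnt <- sum(ev$t_start >= w[1] & ev$t_start < w[2])
    expect_lt(abs(cnt - lambda), 3 * sqrt(lambda),
              label = sprintf("window [%g, %g): %d events", w[1], w[2], cnt))
  }
})

test_that("injected area effect converges to post_area_scale", {
  ratios <- vapply(1:6, function(s) {
    sim <- simulate_session(compact_config(seed = 100 + s,
                                           post_area_scale = 1.7))
    ev <- sim$truth$events
    mean(ev$true_area[ev$epoch == "quiet_post"]) /
      mean(ev$true_area[ev$epoch == "quiet_pre"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1.7), 3 * stats::sd(ratios) / sqrt(6) + 0.03)
})

test_that("the gamma epoch spectrum peaks at the configured theta and gamma", {
  cfg <- suppressWarnings(sim_config(
    duration = 120, fs = 1250, quiet_pre_len = 15, gamma_len = 90, seed = 8))
  sim <- simulate_session(cfg)
  seg <- trace_window(sim$trace, 20, 100)      # interior of the gamma epoch
  sp <- welch_psd(seg, segment_s = 2)
  th <- spectral_peak(sp, c(4, 12))
  gm <- spectral_peak(sp, c(25, 90))
  expect_equal(th$peak_freq, cfg$theta_freq, tolerance = sp$resolution)
  expect_equal(gm$peak_freq, cfg$gamma_freq, tolerance = sp$resolution)
})

test_that("PSC traces carry one biexponential per SWR with the right polarity", {
  cfg <- tiny_config(seed = 3)
  e <- simulate_psc_trace(cfg, "EPSC", event_area_mean = 2, noise_sd_pA = 0)
  i <- simulate_psc_trace(cfg, "IPSC", event_area_mean = 2, noise_sd_pA = 0)
  expect_equal(nrow(e$truth$events), nrow(simulate_session(cfg)$truth$events))
  expect_lt(min(e$trace$samples), 0)
  expect_gt(max(i$trace$samples), 0)
  expect_match(e$trace$label, "-70 mV")
  expect_match(i$trace$label, "holding 0 mV")
})

test_that("noise-free PSC area matches the closed-form biexponential integral", {
  cfg <- suppressWarnings(sim_config(
    duration = 40, fs = 5000, quiet_pre_len = 18, gamma_len = 4,
    swr_rate = 0.08, seed = 12))
  psc <- simulate_psc_trace(cfg, "EPSC", event_area_mean = 2,
                            noise_sd_pA = 0)
  ev <- psc$truth$events
  expect_gt(nrow(ev), 0)
  for (k in seq_len(nrow(ev))) {
    seg <- trace_window(psc$trace, ev$t_start[k], ev$t_end[k])
    area <- abs(sum(seg$samples) / seg$fs)
    # trapezoid vs analytic integral A*(tau_d - tau_r), truncated at 8 tau_d
    expect_equal(area, ev$true_area[k], tolerance = 0.01,
                 label = sprintf("event %d", k))
  }
})

test_that("null PSC scaling leaves pre and post areas exchangeable", {
  psc <- simulate_psc_trace(compact_config(seed = 6), "IPSC",
                            event_area_mean = 2, post_scale = 1)
  ev <- psc$truth$events
  pre <- ev$true_area[ev$epoch == "quiet_pre"]
  post <- ev$true_area[ev$epoch == "quiet_post"]
  sem <- sqrt(stats::var(pre) / length(pre) + stats::var(post) / length(post))
  expect_lt(abs(mean(post) - mean(pre)), 3 * sem)
})

test_that("short epoch layouts warn and infeasible ones error", {
  expect_warning(sim_config(duration = 60, fs = 1000, quiet_pre_len = 25,
                            gamma_len = 10), "unit tests")
  expect_error(suppressWarnings(sim_config(duration = 100, quiet_pre_len = 90,
                                           gamma_len = 20)), "infeasible")
})
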