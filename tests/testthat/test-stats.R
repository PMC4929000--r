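test_that("analysis windows sit 10 s before and 30 s after the gamma epoch", {
  w <- make_windows(c(130, 310), window_spec(), c(0, 600))
  expect_equal(w$pre, c(0, 120))
  expect_equal(w$post, c(340, 460))

  expect_error(make_windows(c(100, 280), window_spec(), c(0, 600)),
               "too late")
  expect_error(make_windows(c(130, 500), window_spec(), c(0, 600)),
               "too early")

  w0 <- make_windows(c(100, 200), window_spec(60, 60, 0, 0), c(0, 300))
  expect_equal(w0$pre, c(40, 100))
  expect_equal(w0$post, c(200, 260))
})

test_that("window summaries compute incidence and flag empty windows", {
  ev <- empty_events_fixture(108)
  ev$t_start <- seq(0.5, 119.5, length.out = 108)
  ev$t_end <- ev$t_start + 0.05
  s <- summarize_window(ev, c(0, 120))
  expect_equal(s$incidence, 0.9)
  expect_equal(s$mean_area, 0.01)
  expect_false(s$empty)

  none <- summarize_window(ev, c(200, 320))
  expect_equal(none$incidence, 0)
  expect_true(none$empty)
  expect_true(is.na(none$mean_area))
})

test_that("exact Wilcoxon matches brute-force sign enumeration", {
  # all-positive n = 11: the smallest attainable two-sided p
  w <- wilcoxon_signed_rank(1:11)
  expect_equal(w$p_value, 2 / 2^11)
  expect_true(w$exact)

  d6 <- c(1, 2, 3, 4, 5, -1)
  expect_equal(wilcoxon_signed_rank(d6)$p_value, brute_wilcoxon_p(d6))

  set.seed(33)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    d <- sample(-8:8, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    expect_equal(wilcoxon_signed_rank(d)$p_value, brute_wilcoxon_p(d),
                 label = paste("d =", paste(d, collapse = ",")))
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test when ties are absent", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    d <- round(rnorm(n), 6)                  # continuous: no ties, no zeros
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("paired comparisons report percentage change and degeneracy", {
  pre <- c(2, 4, 3, 5)
  post <- c(3, 6, 4, 7)
  pc <- paired_compare(pre, post, metric_name = "area")
  expect_equal(pc$pct_change, 100 * (mean(post) - mean(pre)) / mean(pre))
  expect_equal(pc$normalized_post, post / mean(pre))
  expect_equal(pc$n, 4)

  same <- paired_compare(pre, pre)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$pct_change, 0)

  tt <- paired_compare(pre, post, test = "t_paired")
  expect_equal(tt$p_value, stats::t.test(post, pre, paired = TRUE)$p.value)
})

test_that("zero differences follow the drop-zeros convention", {
  d <- c(0, 0, 1, 2, 3)
  w <- wilcoxon_signed_rank(d)
  expect_equal(w$n, 3)
  expect_equal(w$n_zero, 2)
  expect_equal(w$p_value, brute_wilcoxon_p(c(1, 2, 3)))
})

test_that("normalization divides by the pre-gamma mean", {
  v <- normalize_series(c(2, 4, 6), c(TRUE, TRUE, FALSE))
  expect_equal(v, c(2, 4, 6) / 3)
  expect_equal(normalize_series(rep(5, 4), rep(TRUE, 4)), rep(1, 4))
  set.seed(55)
  for (rep in 1:5) {
    x <- runif(10)
    mask <- seq_len(10) <= 6
    expect_equal(mean(normalize_series(x, mask)[mask]), 1)
  }
  expect_error(normalize_series(c(0, 0, 1), c(TRUE, TRUE, FALSE)), "zero")
})

test_that("Spearman correlation matches rank formula and permutation null", {
  x <- 1:8
  expect_equal(correlate(x, 2 * x + 1)$rho, 1)
  expect_equal(correlate(x, rev(x))$rho, -1)

  set.seed(66)
  x <- rnorm(8); y <- rnorm(8)
  ours <- correlate(x, y)
  expect_equal(ours$rho, stats::cor(x, y, method = "spearman"))
  # sampled permutation oracle
  obs <- abs(ours$rho)
  perm <- replicate(2e4, abs(stats::cor(rank(x), sample(rank(y)))))
  expect_equal(ours$p_value, mean(perm >= obs - 1e-12), tolerance = 0.012)
  expect_true(ours$exact)

  big <- correlate(rnorm(30), rnorm(30))
  expect_false(big$exact)
  expect_true(big$p_value >= 0 && big$p_value <= 1)

  const <- correlate(rep(1, 5), rnorm(5))
  expect_true(const$constant_input)
})

test_that("PSC areas integrate baseline-subtracted current", {
  fs <- 10000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  pulse <- trace(ifelse(t >= 1 & t < 1.05, 100, 0) + 10, fs, units = "pA")
  a <- psc_area(pulse, c(1, 1.05))
  expect_equal(a$area, 5, tolerance = 0.01)   # 100 pA x 50 ms, baseline 10 pA
  expect_equal(a$baseline_current, 10)

  z <- psc_area(trace(numeric(length(t)), fs, units = "pA"), c(1, 1.05),
                baseline_current = 0)
  expect_equal(z$area, 0)

  # biexponential against its closed form
  tau_r <- 0.002; tau_d <- 0.02; A <- 150
  biexp <- ifelse(t >= 0.5, A * (exp(-(t - 0.5) / tau_d) -
                                   exp(-(t - 0.5) / tau_r)), 0)
  b <- psc_area(trace(biexp, fs, units = "pA"), c(0.5, 0.5 + 0.16),
                baseline_current = 0)
  expect_equal(b$area, A * (tau_d - tau_r), tolerance = 0.03)
  expect_error(psc_area(pulse, c(1.9, 2.2)), "outside")
})

test_that("holding-potential metadata mismatches warn but do not fail", {
  tr <- trace(rnorm(1000), 1000, units = "pA",
              label = "synthetic IPSC (holding 0 mV)")
  expect_warning(psc_area(tr, c(0.2, 0.4), polarity = "EPSC"), "-70")
  expect_silent(psc_area(tr, c(0.2, 0.4), polarity = "IPSC"))
})

test_that("EPSC-to-IPSC ratios respond homogeneously", {
  mk <- function(areas, t0) data.frame(t_start = t0 + seq_along(areas),
                                       area = areas)
  epsc <- rbind(mk(c(2, 2, 2), 0), mk(c(4, 4), 100))
  ipsc <- rbind(mk(c(2, 2), 0), mk(c(2, 2, 2), 100))
  r <- epsc_ipsc_ratio(epsc, ipsc, c(0, 50), c(100, 150))
  expect_equal(r$ratio_pre, 1)
  expect_equal(r$ratio_post, 2)
  expect_equal(r$ratio_change, 2)

  epsc2 <- epsc; epsc2$area <- 2 * epsc2$area
  r2 <- epsc_ipsc_ratio(epsc2, ipsc, c(0, 50), c(100, 150))
  expect_equal(r2$ratio_pre, 2 * r$ratio_pre)
  expect_error(epsc_ipsc_ratio(epsc, ipsc, c(200, 250), c(100, 150)),
               "no events")
})
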