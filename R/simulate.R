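#' Configuration of the synthetic LFP session generator
#'
#' A session is laid out as three contiguous epochs — `quiet_pre`, `gamma`,
#' `quiet_post` — partitioning `[0, duration)`. Quiet epochs carry
#' Poisson-timed SWR events (a Gaussian sharp-wave bump at `sw_halfwidth`
#' FWHM carrying a cosine ripple burst under the same kind of envelope); the
#' gamma epoch carries a theta-frequency carrier whose phase
#' amplitude-modulates a gamma-frequency component. 1/f-shaped Gaussian
#' noise and a 50 Hz line component are added throughout. In `quiet_post`,
#' sharp-wave amplitudes are multiplied by `post_area_scale`, the event rate
#' by `post_rate_scale`, and ripple cycle counts shifted by
#' `post_ripple_count_delta`, emulating gamma-induced plasticity.
#'
#' @param duration total session length, s.
#' @param fs sampling rate, Hz.
#' @param quiet_pre_len,gamma_len epoch lengths, s (`quiet_post` takes the
#'   remainder). Defaults mirror an in vivo protocol: >= 130 s quiet, ~3 min
#'   running-associated gamma, the rest quiet.
#' @param swr_rate SWR incidence in the pre epoch, Hz.
#' @param sw_amp_mean,sw_amp_sd mean and SD (mV) of the log-normal
#'   sharp-wave amplitude distribution.
#' @param sw_halfwidth sharp-wave full width at half maximum, ms.
#' @param ripple_freq_mean,ripple_freq_sd per-event ripple frequency, Hz.
#' @param ripples_per_event_mean mean ripple cycle count (Poisson, floored
#'   at 4 cycles — physiological ripples are multi-cycle).
#' @param ripple_amp_frac ripple peak amplitude as a fraction of the
#'   sharp-wave amplitude.
#' @param theta_freq,gamma_freq oscillation frequencies, Hz.
#' @param theta_amp gamma-epoch theta carrier amplitude, mV.
#' @param gamma_amp gamma component base amplitude, mV.
#' @param gamma_power_scale multiplies gamma *power* (amplitude scales by
#'   its square root).
#' @param noise_sd total SD of the 1/f background noise, mV.
#' @param noise_exponent spectral exponent of the background (1 = pink).
#' @param line_amp 50 Hz line amplitude, mV.
#' @param post_area_scale,post_rate_scale,post_ripple_count_delta injected
#'   post-gamma effect sizes.
#' @param seed integer; fixes the full sample path.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(duration = 600, fs = 10000,
                       quiet_pre_len = 130, gamma_len = 180,
                       swr_rate = 1.33,
                       sw_amp_mean = 0.5, sw_amp_sd = 0.15,
                       sw_halfwidth = 25,
                       ripple_freq_mean = 180, ripple_freq_sd = 20,
                       ripples_per_event_mean = 7,
                       ripple_amp_frac = 0.5,
                       theta_freq = 7.3, gamma_freq = 46.3,
                       theta_amp = 0.3, gamma_amp = 0.2,
                       gamma_power_scale = 1,
                       noise_sd = 0.05, noise_exponent = 1,
                       line_amp = 0.01,
                       post_area_scale = 1, post_rate_scale = 1,
                       post_ripple_count_delta = 0L,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(duration > 0, fs > 0, swr_rate >= 0, sw_halfwidth > 0,
              sw_amp_mean > 0, noise_sd >= 0, gamma_power_scale >= 0,
              post_area_scale > 0, post_rate_scale >= 0)
    if (gamma_freq < 25 || gamma_freq > 90)
      stop("gamma_freq must lie in the 25-90 Hz gamma band", call. = FALSE)
    if (ripple_freq_mean < 100 || ripple_freq_mean > 300)
      stop("ripple_freq_mean must lie in the 100-300 Hz ripple band",
           call. = FALSE)
    if (quiet_pre_len + gamma_len >= duration)
      stop("epoch layout infeasible: quiet_pre + gamma >= duration",
           call. = FALSE)
  })
  if (cfg$quiet_pre_len < 130 ||
      (cfg$duration - cfg$quiet_pre_len - cfg$gamma_len) < 150)
    warning("epochs too short for the standard 120 s windowing; ",
            "fine for unit tests only", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# run `expr` under a private RNG stream seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate an LFP session with ground truth
#'
#' @param config a [sim_config()].
#' @return a list with `trace` (a [trace()], mV) and `truth`: a list holding
#'   `events` (data frame `t_start,t_end,true_area,true_ripple_count,
#'   true_ripple_freq,epoch`), `epochs` (data frame `kind,t_start,t_end`)
#'   and `injected` (the effect multipliers).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_session_impl(config))
}

simulate_session_impl <- function(cfg) {
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  g0 <- cfg$quiet_pre_len
  g1 <- cfg$quiet_pre_len + cfg$gamma_len
  epochs <- data.frame(
    kind = c("quiet_pre", "gamma", "quiet_post"),
    t_start = c(0, g0, g1),
    t_end = c(g0, g1, cfg$duration)
  )

  sigma_env <- cfg$sw_halfwidth / 1000 / (2 * sqrt(2 * log(2)))  # FWHM -> SD
  margin <- 4 * sigma_env
  ev_pre <- draw_event_times(0 + margin, g0 - margin, cfg$swr_rate,
                             3 * cfg$sw_halfwidth / 1000)
  ev_post <- draw_event_times(g1 + margin, cfg$duration - margin,
                              cfg$swr_rate * cfg$post_rate_scale,
                              3 * cfg$sw_halfwidth / 1000)
  centers <- c(ev_pre, ev_post)
  epoch_of <- rep(c("quiet_pre", "quiet_post"),
                  c(length(ev_pre), length(ev_post)))
  n_ev <- length(centers)

  x <- numeric(n)
  events <- NULL
  if (n_ev > 0) {
    # log-normal amplitudes with the configured mean/SD
    cv <- cfg$sw_amp_sd / cfg$sw_amp_mean
    sdlog <- sqrt(log(1 + cv^2))
    amp <- stats::rlnorm(n_ev, log(cfg$sw_amp_mean) - sdlog^2 / 2, sdlog)
    post <- epoch_of == "quiet_post"
    amp[post] <- amp[post] * cfg$post_area_scale
    rip_f <- pmin(300, pmax(100, stats::rnorm(n_ev, cfg$ripple_freq_mean,
                                              cfg$ripple_freq_sd)))
    n_cyc <- pmax(4L, stats::rpois(n_ev, cfg$ripples_per_event_mean))
    n_cyc[post] <- pmax(4L, n_cyc[post] + cfg$post_ripple_count_delta)

    for (i in seq_len(n_ev)) {
      x <- add_swr_event(x, t, cfg$fs, centers[i], amp[i], sigma_env,
                         cfg$ripple_amp_frac * amp[i], rip_f[i], n_cyc[i])
    }
    events <- data.frame(
      t_start = centers - 3 * sigma_env,
      t_end = centers + 3 * sigma_env,
      true_area = amp * sigma_env * sqrt(2 * pi),
      true_ripple_count = n_cyc,
      true_ripple_freq = rip_f,
      epoch = epoch_of
    )
    events <- events[order(events$t_start), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(t_start = numeric(0), t_end = numeric(0),
                         true_area = numeric(0),
                         true_ripple_count = integer(0),
                         true_ripple_freq = numeric(0),
                         epoch = character(0))
  }

  # theta-nested gamma epoch
  ing <- t >= g0 & t < g1
  if (any(ing)) {
    tg <- t[ing]
    theta_phase <- 2 * pi * cfg$theta_freq * tg
    env <- 0.5 + 0.5 * sin(theta_phase)    # gamma amplitude locked to theta phase
    gam <- cfg$gamma_amp * sqrt(cfg$gamma_power_scale) * env *
      sin(2 * pi * cfg$gamma_freq * tg)
    ramp <- taper_ramp(length(tg), round(cfg$fs))  # 1 s cosine on/off ramps
    x[ing] <- x[ing] + (cfg$theta_amp * sin(theta_phase) + gam) * ramp
  }

  if (cfg$noise_sd > 0)
    x <- x + one_over_f_noise(n, cfg$fs, cfg$noise_sd, cfg$noise_exponent)
  if (cfg$line_amp > 0)
    x <- x + cfg$line_amp * sin(2 * pi * 50 * t)

  list(
    trace = trace(x, cfg$fs, t0 = 0, units = "mV", label = "synthetic LFP"),
    truth = list(events = events, epochs = epochs,
                 injected = config_injected(cfg))
  )
}

config_injected <- function(cfg) {
  list(post_area_scale = cfg$post_area_scale,
       post_rate_scale = cfg$post_rate_scale,
       post_ripple_count_delta = cfg$post_ripple_count_delta)
}

# hard-core renewal process with exact nominal intensity: gaps are
# min_gap + Exp(rate / (1 - rate * min_gap)), so the mean gap is 1/rate
draw_event_times <- function(from, to, rate, min_gap) {
  if (rate <= 0 || to <= from) return(numeric(0))
  if (rate * min_gap >= 1)
    stop("swr_rate too high for the refractory gap", call. = FALSE)
  r_eff <- rate / (1 - rate * min_gap)
  times <- numeric(0)
  t <- from + stats::rexp(1, rate)   # equilibrium-ish start
  while (t < to) {
    times <- c(times, t)
    t <- t + min_gap + stats::rexp(1, r_eff)
  }
  times
}

add_swr_event <- function(x, t, fs, center, amp, sigma_env,
                          ripple_amp, ripple_freq, n_cycles) {
  half <- 4 * sigma_env
  i0 <- max(1L, floor((center - half) * fs) + 1L)
  i1 <- min(length(x), ceiling((center + half) * fs) + 1L)
  tt <- t[i0:i1] - center
  bump <- amp * exp(-tt^2 / (2 * sigma_env^2))
  # ripple burst: n_cycles of a cosine under a Gaussian envelope sized to
  # hold the burst within +-3 SD
  burst_dur <- n_cycles / ripple_freq
  sig_r <- burst_dur / 6
  ripple <- ripple_amp * exp(-tt^2 / (2 * sig_r^2)) *
    cos(2 * pi * ripple_freq * tt)
  x[i0:i1] <- x[i0:i1] + bump + ripple
  x
}

taper_ramp <- function(n, ramp_len) {
  ramp_len <- min(ramp_len, floor(n / 2))
  r <- rep(1, n)
  if (ramp_len > 0) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(ramp_len) / ramp_len)
    r[seq_len(ramp_len)] <- up
    r[(n - ramp_len + 1L):n] <- rev(up)
  }
  r
}

# Gaussian noise with a 1/f^exponent power spectrum, rescaled to sd
one_over_f_noise <- function(n, fs, sd, exponent = 1) {
  white <- stats::rnorm(n)
  W <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) * fs / n        # avoid dividing DC by zero
  f <- pmin(f, fs - f + fs / n)             # symmetric two-sided grid
  W <- W * f^(-exponent / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Simulate an SWR-locked postsynaptic-current trace
#'
#' Builds the whole-cell current counterpart of [simulate_session()]: one
#' biexponential PSC, `A * (exp(-t/tau_decay) - exp(-t/tau_rise))`, per
#' ground-truth SWR event, onset at the event start. EPSCs (recorded at
#' -70 mV) are negative-going, IPSCs (at 0 mV) positive-going. The PSC
#' charge (area) is drawn log-normally around `event_area_mean` and
#' multiplied by `post_scale` for events in the post-gamma epoch.
#'
#' @param config a [sim_config()]; event timing and epoch layout are shared
#'   with the LFP session generated from the same config (same seed, same
#'   event times).
#' @param polarity `"EPSC"` or `"IPSC"`.
#' @param event_area_mean mean PSC charge magnitude, pA*s.
#' @param post_scale multiplier on PSC charge in `quiet_post`.
#' @param area_cv coefficient of variation of the charge distribution.
#' @param tau_rise,tau_decay biexponential time constants, ms.
#' @param noise_sd_pA white current-noise SD, pA.
#' @return list with `trace` (pA, label records the holding potential) and
#'   `truth` (`events` with `t_start,t_end,true_area,polarity,epoch`,
#'   `epochs`, `injected`).
#' @export
simulate_psc_trace <- function(config, polarity = c("EPSC", "IPSC"),
                               event_area_mean = 2, post_scale = 1,
                               area_cv = 0.25,
                               tau_rise = 2, tau_decay = 20,
                               noise_sd_pA = 1) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(config, "sim_config"), event_area_mean > 0,
            tau_rise > 0, tau_decay > tau_rise)
  lfp <- simulate_session(config)             # same seed -> same event times
  ev <- lfp$truth$events
  with_seed(config$seed + 1L, {
    n <- round(config$duration * config$fs)
    x <- numeric(n)
    sign <- if (polarity == "EPSC") -1 else 1
    hold <- if (polarity == "EPSC") -70 else 0
    tr_s <- tau_rise / 1000
    td_s <- tau_decay / 1000
    n_ev <- nrow(ev)
    areas <- numeric(n_ev)
    if (n_ev > 0) {
      sdlog <- sqrt(log(1 + area_cv^2))
      areas <- stats::rlnorm(n_ev, log(event_area_mean) - sdlog^2 / 2, sdlog)
      areas[ev$epoch == "quiet_post"] <- areas[ev$epoch == "quiet_post"] *
        post_scale
      for (i in seq_len(n_ev)) {
        i0 <- floor(ev$t_start[i] * config$fs) + 1L
        i1 <- min(n, i0 + ceiling(8 * td_s * config$fs))
        tt <- (seq(i0, i1) - i0) / config$fs
        # area of e^{-t/td} - e^{-t/tr} over [0, Inf) is td - tr
        A <- areas[i] / (td_s - tr_s)
        x[i0:i1] <- x[i0:i1] + sign * A * (exp(-tt / td_s) - exp(-tt / tr_s))
      }
    }
    if (noise_sd_pA > 0) x <- x + stats::rnorm(n, sd = noise_sd_pA)
    truth_ev <- data.frame(
      t_start = ev$t_start,
      t_end = pmin(config$duration, ev$t_start + 8 * td_s),
      true_area = areas, polarity = rep(polarity, n_ev),
      epoch = ev$epoch
    )
    list(
      trace = trace(x, config$fs, t0 = 0, units = "pA",
                    label = sprintf("synthetic %s (holding %g mV)",
                                    polarity, hold)),
      truth = list(events = truth_ev, epochs = lfp$truth$epochs,
                   injected = c(config_injected(config),
                                psc_post_scale = post_scale))
    )
  })
}
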