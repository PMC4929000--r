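---
title: "Detecting sharp wave-ripples and quantifying gamma-induced network plasticity"
author: "swrgamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sharp wave-ripples and quantifying gamma-induced network plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrgamma)
```

## The problem

Hippocampal local field potentials (LFPs) alternate between two mutually
exclusive network states: quiet periods rich in sharp wave-ripple complexes
(SWRs — a slow 2–50 Hz sharp-wave deflection carrying a 100–300 Hz ripple
burst) and active periods dominated by theta-nested gamma oscillations
(25–90 Hz gamma whose amplitude is modulated by the 4–12 Hz theta phase).
A gamma episode interposed between two quiet periods leaves a lasting mark:
SWRs after the episode ("p-SWRs") are enlarged, and the SWR-associated
excitatory and inhibitory synaptic currents recorded in single cells change
in a cell-type-specific way.

`swrgamma` implements the complete measurement chain needed to quantify such
effects: dual-criterion SWR detection, per-event quantification, gamma-epoch
spectral characterization, paired pre/post statistics, and EPSC/IPSC charge
analysis — together with a synthetic-data generator that produces sessions
with known ground truth, so every stage can be validated without access to
recordings.

## The detection algorithm

A raw trace is split by zero-phase (forward–backward) Butterworth band-pass
filters into a *sharp-wave* trace (2–50 Hz) and a *ripple* trace
(100–300 Hz). Zero-phase application matters: event boundaries and peak
times read off the filtered traces must not be delayed relative to the raw
recording. The filter is order 2 per pass (4 effective); traces are
reflect-padded by roughly three time constants of the slowest band edge
before filtering so that edges carry no transient.

Detection then proceeds in four stages:

1. **Event-free baseline.** The recording itself defines the noise floor.
   Pass 1 masks provisional events where the rectified ripple trace exceeds
   a robust threshold (median + 6·1.4826·MAD), expanded by a 100 ms guard;
   pass 2 computes the mean and SD of the ripple trace over the unmasked
   remainder. Because all later thresholds are expressed in these units,
   the detector is exactly invariant to amplitude rescaling of the input —
   absolute calibration never enters the logic.
2. **Voltage criterion.** The rectified ripple trace is thresholded at
   mean + 6 SD of the event-free baseline. Supra-threshold runs closer than
   `group_gap_ms` (default 20 ms, about 2–4 ripple cycles) are grouped into
   one candidate; candidates with fewer than `min_ripples` (default 3)
   supra-threshold rectified peaks are discarded. Peaks, not runs, are
   counted because at moderate sampling rates consecutive half-waves can
   share one threshold run.
3. **Spectral criterion.** For each candidate the 70 ms event-free cutout
   immediately preceding it is located, and the maximum absolute
   coefficient of a complex Morlet wavelet transform (cmor2-1
   parameterization: bandwidth 2, center frequency 1; 27 log-spaced scales
   spanning 100–300 Hz) is computed for every cutout. A candidate is
   accepted only if its own maximum coefficient exceeds the mean + 1 SD of
   that cutout distribution. The CWT uses L1 scale normalization, under
   which a pure tone produces the same coefficient magnitude at every scale;
   this makes the scale of maximal response localize the tone frequency
   without bias (verified to within one scale step across the band).
   On sparse recordings with fewer than three candidate-preceding cutouts,
   the distribution is supplemented with additional non-overlapping
   event-free windows.
4. **Delimitation and quantification.** The sign of the dominant sharp-wave
   deflection inside the candidate defines the event polarity (electrode
   position determines polarity in practice, so neither sign is privileged).
   From the sharp-wave peak the algorithm walks outward to the nearest
   *strict* local minima — strict over a 5 ms neighborhood, which suppresses
   single-sample noise minima — within 100 ms per side. If a side has no
   minimum, the boundary is placed at the search-window edge and the event
   is flagged for review. Event intervals are half-open `[t_start, t_end)`
   throughout, so abutting events never double-count a sample.

Manual curation — the programmatic equivalent of visual scrutiny — is an
edit table (`accept` / `reject` / `set_bounds`) applied after detection, so
a curated analysis is exactly reproducible from the trace plus the edit
table.

### Area measurement

The SWR area is the trapezoidal integral of the sharp-wave trace over the
event, measured relative to the **chord** joining the trace values at the
two boundaries. Two numerical details are deliberate:

* *Chord, not global baseline.* A band-pass filter with a 2 Hz high-pass
  edge forces the filtered trace to integrate to zero, so every sharp wave
  is repaid as a shallow negative sag spread over seconds between events.
  The sag depth tracks the local event rate and amplitude; subtracting one
  global baseline level therefore biases epochs with larger events. The
  chord is a local reference and cancels this term.
* *Noise-robust boundary references.* Boundaries are local minima, so the
  boundary samples themselves sit about one noise SD low, and a chord
  through them would inflate every area by a small constant; each boundary
  reference is therefore the median of its 5 ms neighborhood. A residual
  additive term remains because the chord anchors are still placed *at*
  noise dips; its expected magnitude (the mean depth of strict-local-minimum
  neighborhood medians below the event-free level, times the event
  duration) is estimated from event-free stretches and subtracted
  (`noise_area_correction`, on by default, floored at zero). The correction
  is a per-session constant rate, so it cannot manufacture pre/post
  differences; without it, ratio-based effect estimates are compressed by a
  few percentage points.

Ripple cycles are counted as supra-threshold local maxima of the signed
ripple trace (one per cycle); the ripple frequency is
`(count − 1) / (time between first and last counted peak)` — the cycle rate
— and is reported only when at least two peaks exist.

## Gamma-epoch characterization

Oscillation epochs can be supplied explicitly (drug application or running
periods) or found automatically: the band-limited power envelope (rectified,
low-passed at 1 Hz) is thresholded at median + 3 robust SDs, and
supra-threshold runs of at least 10 s are kept. Epoch spectra are estimated
by Welch's method (1 s Hann segments, 50% overlap — about 1 Hz resolution,
adequate for theta/gamma peaks) or by averaging consecutive FFTs (default 4
segments, a configurable choice since the segment count of this classic
estimate is a free parameter). The epoch summary is the peak frequency,
peak spectral density, duration, and the exposure metric
`power x duration` used to correlate gamma strength with subsequent SWR
changes; band-integrated power is attached as a diagnostic. Spectral-peak
ties are broken toward the lower frequency and flagged, so output is
deterministic.

## Paired statistics

The comparison windows follow the standard protocol: 120 s windows ending
10 s before gamma onset and starting 30 s after gamma offset. Window
summaries (mean area, incidence, ripple count/frequency, amplitude,
duration) enter paired tests at the session level.

The Wilcoxon signed-rank test is implemented with the exact permutation
null: the distribution of the statistic over all 2^n sign assignments,
computed by convolving the rank generating polynomial. With doubled ranks
this is exact under ties too (a case where the classical lookup tables do
not apply); zero differences are dropped and counted, following Wilcoxon's
convention. Above n = 25 a normal approximation with continuity correction
takes over. Spearman's rho uses average ranks, with a full-enumeration
permutation p-value for n ≤ 9 and the t-approximation above. All tests are
two-sided; no multiple-testing correction is applied by default.

For a *single* session, pre and post events are unpaired. The per-session
decision (`binned_area_test`) therefore cuts each window into 20 equal bins
(6 s each, about 8 events per bin at 1.33 Hz), pairs per-bin mean areas by
bin index, and applies the exact Wilcoxon. Under the null the bin
differences are iid symmetric, so the test holds its level; 20 bins were
chosen from the exact null distribution because the discrete achievable
level closest to 0.05 (0.0484) is reached there, not from pipeline runs.

PSC charge is the magnitude of the trapezoidal integral of the
baseline-subtracted current over the event window, with the baseline
current taken as the median of the 50 ms immediately preceding the event —
robust to overlap with the decay tail of a preceding PSC. The
EPSC-to-IPSC ratio (net-excitability index) is the ratio of mean EPSC to
mean IPSC charge per window.

## The synthetic generator

`simulate_session()` emulates the phenomenology the analysis assumes, not
the biophysics (no conductance-based network is simulated — a deliberate
non-goal):

* three epochs — quiet, gamma, quiet — partitioning the session; defaults
  130 s / 180 s (about the 3-minute running episodes of the standard
  protocol) / remainder;
* SWRs as Gaussian sharp-wave bumps (25 ms FWHM, log-normal amplitudes,
  mean 0.5 mV, SD 0.15 mV) carrying cosine ripple bursts (180 ± 20 Hz,
  Poisson cycle counts around 7, floored at 4 cycles — physiological
  ripples are multi-cycle) at half the sharp-wave amplitude. The Gaussian
  shape makes every true area analytically available to oracle tests;
* Poisson event timing at 1.33 Hz with a hard-core refractory gap of three
  sharp-wave half-widths, implemented as a renewal process whose mean rate
  still equals the nominal incidence;
* theta-nested gamma: a 7.3 Hz theta carrier (0.3 mV) whose phase modulates
  the amplitude of a 46.3 Hz gamma component (0.2 mV base), ramped on and
  off over 1 s;
* 1/f-shaped Gaussian noise (0.05 mV total SD) plus a 0.01 mV 50 Hz line
  component. At these defaults the ripple-band SNR (peak ripple amplitude
  over ripple-band baseline SD) is well above 8;
* injected effects: post-gamma sharp-wave amplitudes multiplied by
  `post_area_scale`, incidence by `post_rate_scale`, ripple counts shifted
  by `post_ripple_count_delta`. Because the sharp-wave area is linear in
  its amplitude, `post_area_scale` is also the true area effect.

The generator is seed-deterministic: identical configurations produce
identical traces and ground truth. `simulate_psc_trace()` shares the event
times of the LFP session from the same config and adds one biexponential
PSC per SWR (rise 2 ms, decay 20 ms; negative-going for EPSCs at −70 mV,
positive for IPSCs at 0 mV), with log-normal charges and an independent
post-epoch scale.

What passing tests on these data do *not* show: robustness to
non-stationary noise, movement artifacts, electrode drift, overlapping
events, state transitions gentler than the generator's, or sharp waves
whose shape departs strongly from a smooth bump. On real recordings the
curation pathway exists precisely because the local-minima rule can land on
the wrong dip in high-variance sharp-wave traces.

## Problem sizes used in validation

The validation suite runs entirely on synthetic data at 1250 Hz sampling
(Nyquist comfortably above the 300 Hz ripple-band top; the generator's
default is 10 kHz, the common digitization rate): 20 sessions of 600 s for
the detection benchmark (recall and precision ≥ 0.95 at 50% overlap
matching), 200 null sessions of 310 s for type-I calibration of the binned
paired test (rejection rate 5% ± 2 points at α = 0.05), and 20 sessions per
injected effect size (1.25 and 1.70) for recovery of the percentage area
change within ±5 points. These sizes were chosen so the full suite
completes in minutes while keeping Monte-Carlo error well below the
tolerances tested.

## A worked example

```{r example, eval = FALSE}
library(swrgamma)

cfg <- sim_config(duration = 600, fs = 1250, post_area_scale = 1.7, seed = 1)
sim <- simulate_session(cfg)

res <- analyze_session(sim$trace,
                       gamma_epoch = c(130, 310))  # known from the protocol
res$pre$mean_area    # mean SWR area before gamma, mV*s
res$post$mean_area   # after
res$pct_area_change  # percentage change

# per-session decision
bt <- binned_area_test(res$events, res$windows)
bt$p_value

# across sessions, the paired comparison works on per-session means
# paired_compare(pre_means, post_means, test = "wilcoxon")
```

## Known limitations

* The boundary rule inherits the sensitivity of "nearest local minimum" to
  sharp-wave shape; flagged events (`rejection_reason = "boundary"`) should
  be reviewed via the curation table.
* The spectral criterion assumes the pre-event cutout is representative
  noise; strongly non-stationary noise floors would call for a rolling
  baseline, which is not implemented.
* Area units are mV·s as measured on the filtered sharp-wave trace; the
  band-pass attenuates the bump (about 30% for a 25 ms FWHM bump in a
  2–50 Hz order-2 band-pass), so absolute areas are filter-dependent even
  though relative (pre/post) comparisons are not.
* Per-event pooling across sessions is available but the session is the
  unit of replication for all inferential defaults.
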