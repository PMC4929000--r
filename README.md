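# swrgamma

Analysis pipeline for hippocampal LFP recordings in which gamma-oscillation
episodes are interposed between quiet, sharp wave-ripple (SWR)-rich states,
and for the SWR-associated postsynaptic currents recorded alongside them.

Hippocampal sharp wave-ripples — a slow sharp-wave deflection (2–50 Hz)
carrying a fast ripple burst (100–300 Hz) — and theta-nested gamma
oscillations (25–90 Hz, amplitude-modulated at theta phase) are mutually
exclusive network states. A sustained gamma episode changes the SWRs that
follow it: their area grows, ripple counts and frequencies shift, and the
associated excitatory/inhibitory synaptic currents change cell-specifically.
Quantifying those changes requires a measurement chain that this package
implements end to end, for anyone analyzing in vivo or in vitro LFP traces
of this kind.

## What it computes

**SWR detection** (`detect_swr`) uses the classic dual criterion:

1. split the trace into sharp-wave (2–50 Hz) and ripple (100–300 Hz) bands
   with zero-phase Butterworth filters;
2. threshold the rectified ripple trace at *mean + 6 SD* of the event-free
   recording (found automatically by a robust two-pass procedure) and group
   adjacent supra-threshold ripples into candidate events;
3. accept a candidate only if its maximum absolute complex-Morlet wavelet
   coefficient (cmor2-1, 27 scales over 100–300 Hz) exceeds *mean + 1 SD*
   of the same statistic on 70 ms event-free cutouts preceding the events;
4. delimit each event at the flanking local minima of the sharp-wave trace
   and quantify it: area (chord-referenced ∫ of the sharp-wave deflection,
   mV·s), amplitude, duration, ripple count and ripple frequency.

Manual curation is supported as a reproducible edit table, not a GUI.

**Gamma analysis** (`find_oscillation_epochs`, `characterize_epoch`)
extracts epoch bounds, peak frequency/power (Welch or averaged-FFT spectra)
and the exposure metric *power × duration*.

**Plasticity statistics** (`make_windows`, `summarize_window`,
`paired_compare`, `correlate`, `psc_area`, `epsc_ipsc_ratio`) implement the
paired pre/post-gamma design: 120 s windows ending 10 s before and starting
30 s after the gamma episode, normalization to the pre-gamma mean,
percentage change ± SEM, an exact Wilcoxon signed-rank test (full 2^n sign
enumeration via rank-polynomial convolution, exact under ties), Spearman
correlation with permutation p-values, and EPSC/IPSC charge-transfer
ratios.

**Synthetic data** (`simulate_session`, `simulate_psc_trace`) generates
sessions with Poisson-timed SWRs (Gaussian sharp waves + ripple bursts),
theta-nested gamma, 1/f noise, 50 Hz line, SWR-locked biexponential PSCs,
configurable injected effect sizes, and full ground-truth annotation.

## Worked example

```r
library(swrgamma)

# a 600 s synthetic session: quiet [0,130) s, gamma [130,310) s, quiet rest;
# post-gamma sharp-wave amplitudes scaled by 1.7
cfg <- sim_config(duration = 600, fs = 1250, post_area_scale = 1.7, seed = 1)
sim <- simulate_session(cfg)

res <- analyze_session(sim$trace, gamma_epoch = c(130, 310))
res$pre; res$post; res$pct_area_change
bt <- binned_area_test(res$events, res$windows)
```

This prints (seed 1):

```
pre : n=160  incidence=1.33 Hz  mean area=0.01270 mV.s
post: n=162  incidence=1.35 Hz  mean area=0.02194 mV.s
pct_area_change = 72.8%
gamma peak 46.0 Hz, peak power 0.00295 mV^2/Hz, power x duration 0.53
binned Wilcoxon: V=210  p=1.9e-06  (n=20 bins)
```

The detector recovered the injected conditions: 1.33 Hz incidence in the
pre window, a ~70% area increase after the gamma episode (injected: +70%),
the 46.3 Hz gamma peak to within the 0.5 Hz spectral resolution, and a
per-session paired test that rejects the no-change null decisively.

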