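---
title: "Modelling noninvasive stimulation of the cortico-cerebello-thalamo-cortical loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noninvasive stimulation of the cortico-cerebello-thalamo-cortical loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctcsim)
```

## What the package models

Rhythmic interactions in the cortico-cerebello-thalamo-cortical (CCTC)
loop — cerebral cortex, thalamus, basal ganglia, and the deep cerebellar
nuclei (DCN) that relay the cerebellum's output — shape cortical
oscillations. Weak transcranial electrical stimulation of the cerebellum
can bias these rhythms: a constant current (tDCS) provides a tonic drive to
the DCN, while temporal-interference stimulation (tTIS) superposes two kHz
carriers whose difference frequency produces a deep, low-frequency
amplitude-modulated field. `cctcsim` packages three connected pieces of
machinery to study this quantitatively on purely synthetic data:

1. a seven-population neural-mass model of the CCTC loop with an external
   DCN drive, plus the stimulation waveform generators that feed it;
2. spectral tooling to classify the cortical rhythm (in particular the
   gamma-to-beta shift regarded as a marker of sensory gating);
3. a functional near-infrared spectroscopy (fNIRS) processing chain and a
   closed-loop controller in which the phase of infra-slow (0.01–0.10 Hz)
   prefrontal oxyhemoglobin drives the amplitude of 4 Hz cerebellar tACS,
   saturated at ±2 mA.

## The rate model

Each population $j \in$ {CTX, Vim, nRT, DCN, STN, GPe, GPi} carries a
firing rate $r_j(t)$ (spikes/s) obeying

$$\tau_j \dot r_j = -r_j + S_j\Big(\sum_i W_{ij}\, r_i + b_j + u_j(t)\Big),
\qquad S_j(x) = \frac{M_j}{1 + e^{-\beta_j (x - \theta_j)}},$$

where $u_j$ is nonzero only for the DCN (the stimulation target), $W$ is a
signed connection matrix whose rows obey Dale's principle (CTX, Vim, DCN
and STN project with non-negative weights; nRT, GPe and GPi with
non-positive ones), and $S_j$ is the logistic transfer with maximum rate
$M_j$. The circuit couples a fast thalamocortical negative loop
(CTX → nRT → Vim → CTX, time constants 6 ms) with a slower loop through the
basal ganglia (CTX → STN → GPi → Vim → CTX, 12–20 ms), the DCN exciting Vim.

All constants live in a versioned YAML file
(`system.file("extdata", "cctc_params.yaml", package = "cctcsim")`), never
in code. The parameterization is the package's own calibration, pinned to
three operating characteristics: the unforced DCN rate is 56.6 spikes/s
(the Purkinje-cell reference of 63 Hz motivates the 63 Hz beat frequency but
enters no equation); a constant DCN drive at the reference operating point
(2 mA at a gain of 10 input-units/mA) pushes the fast loop across its Hopf
bifurcation, giving a gamma-band (> 30 Hz) cortical limit cycle; and with a
zero-mean 63 Hz amplitude-modulated drive the slow loop dominates instead,
keeping the cortical rhythm in the beta band. Linear stability analysis of
the two loops guided the calibration; the background drives $b_j$ were then
solved so that the stated operating rates are an equilibrium of the coupled
system. Editing weights or operating rates therefore requires re-solving
the backgrounds.

Two facts about this nonlinear system are worth knowing. First, the
interior operating point coexists with saturated equilibria (all sigmoids
pinned near their rails); the default initial state — the decoupled fixed
point $S_j(b_j)$ — lies in the basin of the oscillatory attractor, which is
why it is the default. Second, on a limit cycle the phase direction is
neutrally stable, so numerical phase drift accumulates linearly; integrator
accuracy is therefore validated on a weakly coupled configuration (weights
scaled by 0.2, all loop gains subcritical) where the flow is contractive
and truncation error is measurable, while the oscillatory regimes are
validated spectrally.

### Numerics

Integration is fixed-step classical Runge–Kutta (RK4) at `dt = 1e-4` s,
compiled, and bit-reproducible given `(params, drive, dt, init)`; an
explicit Euler mode exists for oracle comparisons. Sampled drives are
linearly interpolated onto the step grid. Rates are bounded by the sigmoid
alone — there is no clamping — and a non-finite state aborts with the step
number (the cure is a smaller `dt`). The first 2 s of every trajectory are
discarded before spectral analysis to remove the transient from the
arbitrary initial state.

## Stimulation waveforms

`stim_tdcs()`, `stim_tacs()` and `stim_ttis()` generate sampled current
waveforms in mA (tTIS defaults: $f_1 = 1$ kHz, $f_2 = 1.063$ kHz at 100 kHz
sampling). For equal carrier amplitudes $A$ the summed field has envelope
$|2A\cos(\pi \Delta f\, t)|$, which oscillates at $\Delta f = 63$ Hz.
`extract_envelope()` computes it as the magnitude of the FFT-based analytic
signal.

A rate model cannot follow kHz carriers, and physiologically a neural mass
acts as a low-pass demodulator of an amplitude-modulated field. The default
coupling for tTIS is therefore `dcn_drive(mode = "demodulated")`: the
envelope, mean-removed and scaled by the mA-to-input gain. The explicit
carrier waveform is retained only for export. Five per cent of samples at
each envelope edge are replaced by the nearest interior value before use,
because the analytic signal is biased at record edges. The mA-to-input gain
(default 10 per mA) is a free calibration constant of the model — scalp
currents do not map to population drive in closed form — and lives in the
parameter file.

## Spectral analysis and band classification

`welch_psd()` is a Hann-windowed averaged periodogram (default 2 s segments,
50% overlap on traces decimated to 1 kHz, i.e. 0.5 Hz resolution — enough to
separate beta from gamma). `dominant_frequency()` takes the argmax above
1 Hz, excluding DC and slow drift. Band edges are declared explicitly:
delta (0, 4], theta (4, 8], alpha (8, 13], beta (13, 30], gamma (30, 100],
half-open on the left so that exactly 30 Hz classifies as beta and gamma is
strictly above 30 Hz. `detect_band_shift()` applies this to two runs and
reports whether the cortical rhythm moved, e.g. gamma → beta when the
constant drive is replaced by the 63 Hz beat.

```{r regimes, eval = FALSE}
p <- cctc_parameters()
g <- p$stimulation$dcn_gain_per_mA
tdcs <- cctc_simulate(p, drive = g * 2, duration = 12)
ttis <- dcn_drive(stim_ttis(1, 1000, 1, 1063, duration = 12, fs = 2e4),
                  gain = g, mode = "demodulated")
am <- cctc_simulate(p, drive = ttis, duration = 12)
detect_band_shift(tdcs, am, "CTX")
```

## The fNIRS chain

The processing chain mirrors standard continuous-wave practice. Raw
two-wavelength intensities (760/850 nm) become optical density
$OD = -\log_{10}(I/\bar I)$; motion artifacts (samples beyond 5 robust SDs
in amplitude or 3 SDs in gradient within a 0.5 s window — explicit defaults,
in the spirit of common toolbox settings) are spline-interpolated and the
trace smoothed with a 3rd-order Savitzky–Golay filter; a zero-phase
2nd-order Butterworth band-pass isolates 0.01–0.10 Hz where needed; and the
modified Beer–Lambert law converts OD to ΔHbO/ΔHbR using tabulated
extinction coefficients and a differential pathlength factor of 6.0 at both
wavelengths (the shipped constants file is versioned; devices are not
modelled). The band-pass is deliberately *not* applied before the
post-vs-pre change analysis — a sustained post-intervention shift is below
the 0.01 Hz edge and would be removed by it.

The hemodynamic response is deconvolved by ordinary least squares from the
single block onset with a consecutive Gaussian basis (sd 0.5 s, spacing
0.5 s over a 0–20 s window, hence 41 functions — the spacing and width are
interpreted in seconds), a 3rd-order polynomial drift (drift order is a
conservative default, not a measured quantity), and the nearest
short-separation channel of the same chromophore as a superficial nuisance
regressor. The block design defaults to 2.5 min baseline / 5 min
stimulation / 2.5 min post and is a configuration input, not a constant.

`post_pre_change()` computes, per long channel, the mean ΔHbO over the post
segment minus the mean over baseline, averages channels into regions for
reporting, and compares left- versus right-hemisphere channel values with a
two-sample Welch test at α = 0.01 (the level is a design constant; the test
is our choice, made because it assumes neither equal variances nor equal
group sizes).

A note on signal-to-noise: the obstacle to HRF recovery in this chain is
physiological interference, not shot noise, so the generator's SNR is
defined as HRF peak amplitude over the superficial component's SD in the
long channel (`hrf_amplitude / (superficial_weight * superficial_amp)`).
At SNR 1 with short-separation regression the median recovery correlation
across channels exceeds 0.95; a per-sample white-noise SNR of 1 would not
support deconvolution at 0.5 s resolution from a single block, and white
instrument noise defaults to a realistic 2e-7 M floor instead.

## The closed-loop controller

`run_closed_loop()` composes, causally: a forward-only (causal) 2nd-order
Butterworth band-pass to 0.01–0.10 Hz; a trailing 60 s sliding-window
estimate of the instantaneous infra-slow phase; a raised-cosine
phase-to-amplitude map $A(\varphi) = A_{\max}(1 + \cos(\varphi +
\text{lag}))/2$; and synthesis of the 4 Hz carrier at 100 Hz with the
amplitude held between 1 s updates. No stimulation is emitted until one
full window of history exists (warm-up); stream gaps hold the last
amplitude and are logged; saturation at $A_{\max}$ (default 2 mA, a pure
configuration constant — exploratory ±4 mA runs are just `a_max = 4`) is
enforced unconditionally. When the analytic amplitude of the window is
negligible the phase is undefined and the controller holds the mapping
midpoint $A_{\max}/2$, flagging the samples as low-confidence: a bounded,
continuous fallback.

Two design choices deserve their reasoning spelled out.

*The map.* "Phase drives amplitude" admits many realizations (linear ramp,
binary gating, raised cosine). The raised cosine is continuous, bounded,
2π-periodic and peaks at the crest of the infra-slow oscillation; an
optional lag offset accommodates a subject-specific phase delay without
changing the machinery. The mapping sits behind `phase_to_amplitude()` and
is trivially replaceable.

*The phase estimator.* The argument of the windowed analytic signal at the
window's trailing edge is the textbook estimator, but it is biased exactly
where it is read — at the edge — whenever the window does not contain an
integer number of cycles (at 0.04 Hz a 60 s window holds 2.4 cycles and the
endpoint error can exceed a radian). The default estimator therefore
regresses the window onto a single narrowband sinusoid plus a linear trend,
choosing the frequency by least squares inside the band, and evaluates
phase and amplitude analytically at the edge. On in-band tones it matches
the analytic-signal convention to within hundredths of a radian across the
whole 0.01–0.10 Hz band and stays causal; the raw windowed-Hilbert variant
is retained as `method = "hilbert"`. The estimator assumes one dominant
narrowband component per window — appropriate for band-passed infra-slow
HbO, not for broadband signals.

## The synthetic-session generator

`generate_raw_session()` forward-models ground-truth concentrations through
the Beer–Lambert law into two-wavelength intensities for a 13-channel
montage (10 long channels at 3.5 cm over left/right PFC, sensorimotor
cortex and left/right cerebellum; 3 short channels at 0.8 cm). Long
channels carry a block-onset-locked double-gamma response (peak-normalized,
default peak 5e-6 M, the constant-current-like magnitude; the
alternating-current-like regime is exercised at 1e-7–3e-7 M — generator
defaults, never claims about any real recording), a per-channel infra-slow
sinusoid, a weighted copy of the 0.01–0.5 Hz colored-noise
superficial/systemic component shared with the co-located short channel
(the structure short-separation regression assumes), and white noise; short
channels carry superficial signal and noise only. Optional motion
artifacts are brief square steps in OD. One seed fixes the session
bit-for-bit, and the generator restores the caller's RNG state.

What the generator deliberately does *not* emulate: photon transport
through tissue, optode-scalp coupling physics, heartbeat/respiratory bands,
device-specific noise spectra, or non-sinusoidal infra-slow dynamics.
Passing tests therefore demonstrate that the algorithms are correct under
the stated statistical structure, not that any physiological effect size
would be recovered from real recordings.

## Problem sizes and runtime choices

The test-suite and acceptance runs use 12 s simulations at `dt = 1e-4`
(2 s burn-in), 600 s synthetic sessions at 2–10 Hz, 200 seeded null
sessions for the type-I check of the α = 0.01 region test (the empirical
rate's binomial confidence interval must cover α), and 5–8 seeds for
GLM-recovery medians. These sizes keep every property estimable without
ceremony; all scale linearly if more precision is wanted.

## Known limitations

* The model is a rate description: no spiking, conductances, plasticity, or
  conduction delays, and no claim that the calibrated weights are uniquely
  identified by the three pinned operating characteristics.
* Electric-field modelling (which electrode montage produces which DCN
  drive) is out of scope; the mA-to-input gain subsumes it.
* SNIRF (HDF5) containers are not read; sessions travel as CSV with a YAML
  sidecar (`write_fnirs_csv()` / `read_fnirs_csv()`).
* The region comparison treats channels as exchangeable within hemisphere;
  shared superficial components across hemispheres make the Welch test
  conservative rather than anticonservative.
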