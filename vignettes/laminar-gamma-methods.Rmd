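---
title: "Methods: laminar gamma-oscillation analysis and the synthetic column"
author: "laminarGamma maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar gamma-oscillation analysis and the synthetic column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`laminarGamma` implements an analysis chain for trial-structured laminar-probe
recordings from primary visual cortex: current source density (CSD)
estimation, layer identification, gamma-power hotspot detection, dominant
gamma-frequency estimation, bias-corrected phase coherence between hotspot CSD
signals and spiking activity across depth, and the accompanying nonparametric
statistics. Because suitable public recordings with the required trial
structure are not available, the package ships a synthetic cortical-column
generator whose ground truth exercises every stage; all acceptance-level
checks are parameter-recovery experiments on that generator.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic column does and does not capture.

# The analysis chain

## Preprocessing

The broadband signal (5 kHz in the synthetic sessions; any integer multiple
of 1 kHz is accepted) is split into two streams:

* **LFP** — zero-phase FIR low-pass (pass < 160 Hz, stop 300 Hz, 80 dB
  suppression), then decimation to 1 kHz. The stop edge sits below the new
  Nyquist (500 Hz), so no further anti-alias stage is needed.
* **ESA** (entire spiking activity) — zero-phase FIR high-pass (pass
  > 400 Hz, stop 300 Hz, 80 dB), full-wave rectification, then the LFP
  low-pass and decimation to 1 kHz. ESA is a continuous envelope of
  population spiking that avoids spike thresholding.

Filters are designed with Kaiser windows from the (pass, stop, suppression)
triplets, interpreted as single-pass specifications; applying them forward
and backward doubles the stop-band attenuation and cancels the group delay
exactly. Two numerical choices matter:

* the design attenuation is at least 40 dB even where only 20 dB is
  requested (the gamma band-pass), keeping pass-band ripple below about 1%
  — the requested suppression remains a met lower bound;
* signals are reflect-padded by three filter lengths before the
  forward-backward pass, so the ~4.5 s trials have no visible edge
  transients.

## Spline inverse CSD

The volume-conductor model assumes current sources uniformly distributed on
discs of radius $R$ (default 500 µm) stacked along the column axis in an
isotropic medium of conductivity $\sigma$ (default 0.4 S/m). A disc at
vertical distance $\Delta z$ contributes a potential kernel

$$k(\Delta z) = \frac{1}{2\sigma}\left(\sqrt{\Delta z^2 + R^2} - |\Delta z|\right).$$

The CSD along depth is parameterized as a natural cubic spline through the
electrode depths, zero beyond the end knots. The forward matrix $F$ collects,
per electrode, the kernel integral of each cardinal spline basis element
(numerical quadrature at 5 µm steps; halving the step changes $F$ by less
than 0.1%). Inversion solves $F c = \phi$ per time sample; with LFP in volts
the CSD comes out in A/m³. The profile is then smoothed along depth with a
Gaussian (SD 200 µm, finite window 1,000 µm, kernel renormalized to unit sum
at every output position, including the probe ends). No diagonal
regularization is applied by default; the forward matrix is well conditioned
for 16–32 channels at 100 µm pitch.

Sign convention throughout: sinks negative, sources positive.

## Layer identification

The evoked-onset CSD map (trial-averaged LFP over the first 250 ms after
stimulus onset, from correct trials with a stimulus in the receptive field,
then inverted and smoothed) shows the early source-over-sink pattern at the
layer-III/IV border. The border is the midpoint between the most superficial
channel pair whose early-window (first 100 ms) means are positive above
negative.

The estimate is refined with the baseline correlation matrix: per trial the
CSD is low-passed (pass ≤ 15 Hz, stop 20 Hz, 35 dB, zero phase) and Pearson
correlations are computed between all channel pairs within 100 ms inside the
baseline edges; the matrix holds the medians across trials. The refinement
scans candidate borders (channel midpoints) within ±200 µm of the initial
estimate and keeps the adjacent channel pair with the *smallest* mutual
correlation — the literal "sharp decrease in correlation" — falling back to
the initial estimate on ties. A two-block contrast maximizer was tried
first and rejected: the 200 µm CSD smoothing turns the correlation blocks
into a smooth distance decay, on which the block-contrast optimum slides
systematically away from the true border, while the adjacent-pair
decorrelation stays pinned to it.

Domains: supragranular (SG) strictly above the border, granular (G) from the
border down to 500 µm below it (a channel exactly at the border counts as
granular), infragranular (IG) below that.

## Spectral analysis

Complex Morlet wavelets with $f_0/\sigma_f = 6$, $\sigma_t = 1/(\pi\sigma_f)$
and unit total energy; center frequencies on a geometric grid
$f_0[i] = 5 \cdot 2^{i/8}$ Hz truncated at 160 Hz (8 voices per octave — the
exact spacing of the original scheme is not reproduced anywhere, and a
geometric grid at this density supports the half-height interpolation below).
Power is $|W|^2$ divided by the Nyquist frequency (500 Hz); the 1/f bias is
corrected by multiplying each PSD value by its wavelet center frequency.
Samples within $3\sigma_t$ of a trial edge are flagged invalid per frequency
and excluded from all averages.

The gamma band is either the preset 42.5–130.5 Hz or re-derived as the
full-width-at-half-maximum interval around the gamma peak (search range
30–120 Hz, chosen to avoid low-frequency and line-noise peaks) of the mean
corrected PSD, with linear interpolation between grid frequencies.

## Hotspot detection

Per channel, gamma power is the band-mean corrected PSD over morph cycles 2
and 3 (MC2/3), averaged across attend-in trials. Within each domain the
hotspot is (1) an interior channel strictly above both same-domain
neighbors, ties resolved toward larger power then toward the surface; or
(2) a "hidden peak": on the first differences of the profile, an interior
local minimum with positive flanks (rising flank, first electrode of the
pair) or an interior local maximum with negative flanks (falling flank,
second electrode). Domain edge channels can never be rule-1 hotspots.
Electrodes whose MC2/3 gamma power is below 2.5 times their baseline gamma
power are excluded from coherence analyses; ESA sources are the
strongest-two-thirds (ceiling) of channels by attend-in ESA gamma power.

## Dominant gamma frequency

The hotspot CSD is band-passed (35–120 Hz pass, 25/140 Hz stops, 20 dB,
zero phase) and Hilbert-transformed; the envelope is smoothed with a
$\sigma$ = 10 ms Gaussian. Within maximal runs of at least 40 ms in which the
envelope exceeds the per-trial median over MC2/3, trough times are located
where the unwrapped phase crosses $\pi + 2\pi k$ (linear interpolation
between samples; unwrapping prevents double counting at the wrap boundary).
Cycle periods are successive trough differences within a run — never across
runs — and periods outside [1/120, 1/35] s are discarded. The dominant
frequency of a session × condition is the reciprocal of the median pooled
period (even counts use the midpoint of the central pair).

## Phase coherence

For a reference (hotspot) CSD signal and a target signal (ESA or another
CSD), the phase-locking value at time $t$ and frequency $f$ is the resultant
length of the per-trial phase-difference phasors. Its small-$N$ bias is
removed by subtracting the expected value for random phases,
$EV(N) = \sqrt{\pi}/(2\sqrt{N})$ — the analytic mean resultant length of $N$
uniform unit phasors, which the test suite verifies against Monte-Carlo
simulation. Negative corrected values are kept so that averages stay
unbiased. CSD–CSD profiles exclude the reference electrode and both
neighbors; profiles are summarized as the gamma-band mean per channel, and
domain preference divides, at each depth, each hotspot's value by the sum of
the three. Two gamma-band presets are kept side by side (42.5–130.5 Hz for
hotspot/attention analyses, 28–78 Hz for ESA preference profiles) because
both conventions appear in the literature this pipeline follows; the band is
always an explicit argument.

## Statistics

Independent groups: Kruskal–Wallis omnibus (p < 0.05), Dunn's rank-based
pairwise z tests (α = 0.05, no further correction at this stage), and
one-sided Wilcoxon rank-sum confirmation for Dunn-significant pairs with the
direction taken from the group medians. Paired conditions: Friedman omnibus,
then two-sided signed-rank tests with Tukey–Kramer (default) or Bonferroni
correction; the Tukey–Kramer correction maps each two-sided p to $|z|$ and
refers $\sqrt{2}|z|$ to the studentized range, which also works for exact
small-n p-values. Data from two animals are pooled only when a two-sided
rank-sum test finds no difference (p > 0.05). Session-value correlations are
Pearson with Bonferroni correction over the three domain pairs.

# The synthetic column

## What it emulates

A 16-channel probe at 100 µm pitch spans a 1.5 mm column with the
layer-III/IV border at 550 µm. Ground truth contains:

* **Three gamma oscillators** centered at 300 µm (SG), 800 µm (upper G) and
  1300 µm (IG) with base frequencies 67.0, 70.7 and 65.3 Hz, slow
  Ornstein–Uhlenbeck frequency drift (SD 2 Hz, τ = 200 ms), stochastic
  lognormal burst envelopes (log-SD 0.25, τ = 40 ms), and per-condition
  amplitude gains and frequency shifts. Defaults: attend-in amplitude gains
  $\sqrt{1.381}, \sqrt{1.285}, \sqrt{1.160}$ (so measured power rises by
  38.1%, 28.5% and 16.0% over attend-away), attend-nearby gains from 12.8%,
  7.5% and −4.1%, and SG frequency shifts (+1.2, −0.7, −1.0 Hz) so the SG
  condition medians are 68.2, 66.3 and 66.0 Hz. Oscillators turn on with a
  200 ms raised-cosine ramp at stimulus onset.
* **An evoked onset response**: source above sink (±150 µm around the
  border, SD 100 µm), alpha-function time course starting 30 ms after
  stimulus onset with a 50 ms decay — the polarity-inversion detector's
  target.
* **Phase-locked spiking**: per channel an inhomogeneous point process with
  rate $\propto \exp(\kappa\cos(\varphi_{dom} - \varphi_0))$ (κ = 1.2, weak
  cross-domain term 0.1), normalized to the channel's mean rate (50 Hz with
  a granular bump); each event adds a biphasic ~1 ms waveform with energy
  above 400 Hz. SG and IG phases are weakly pulled toward the granular
  phase (Kuramoto term, condition-dependent strength) so inter-domain
  coherence is small but attention-sensitive.
* **Within-domain shared baseline activity**: one slow (OU, τ = 40 ms)
  signal per domain, uniform across the domain depths — the target of the
  correlation-based border refinement.
* **1/f background noise** per fine-grid depth (SD 150 A/m³) and white
  sensor noise (0.5 µV) on the electrodes.

Electrode potentials are the depth integral of the fine-grid CSD (20 µm
steps) against the same disc kernel the inversion assumes, which makes
forward → inverse round-trips exact up to the spline interpolation error.

## The oscillator depth profile: a deliberate design choice

Each oscillator injects zero net current. The obvious implementation — a
compact center lobe with a concentric return ring — interacts badly with the
prescribed 200 µm CSD smoothing: any return confined to the 1.5 mm column
leaves ≥ 0.35 relative amplitude of each oscillator at its neighbors'
hotspot channels, which biases the trough-based frequency estimator by
roughly $\Delta f \cdot a/(1+a)$ (about 2 Hz here) and can push the deep
hotspot onto the edge channel. The package therefore closes each
oscillator's current loop through *distant* tissue: a compact Gaussian lobe
(SD 120 µm; 100 µm for IG) inside the column plus two far return lobes
(above the pia at −3 mm and in deep white matter at +4.5 mm, half the mass
each). The profile still integrates to zero over the generator grid, the far
returns produce only a small, smooth potential offset at the probe, and
residual leakage drops to 0.06–0.18 — recovered frequencies then match
ground truth within ~0.4 Hz. Physiologically this mimics return paths
through distant compartments rather than a fully local dipole; it is the one
place where the generator is tuned for the *analysis* to have a clean
target, and it is fixed, not a per-experiment dial.

## What passing tests do and do not show

The generator shares the inversion's volume-conductor model, so round-trip
accuracy statements are about the spline parameterization and numerics, not
about model mismatch in real tissue. Real recordings add electrode drift,
non-stationary artifacts, eye-movement covariates, laminar heterogeneity of
spike waveforms, and CSD generators that violate the disc/isotropy
assumptions; none of these are simulated. Passing the recovery suite shows
the pipeline implements its contracts and can recover known laminar
structure at realistic SNR — not that the biological conclusions transfer to
any particular dataset.

## Problem sizes and reproducibility

Default experiment sizes used by the test suite and the acceptance script:
100 attend-in trials for frequency recovery, 60 trials per condition for
attention contrasts and the end-to-end recovery run, 20 seeds × 6 trials for
border-detection coverage. Each simulated trial is ~4.6 s at 5 kHz — full
sessions are a few hundred megabytes in memory, which is why sessions are
simulated per run rather than stored. All randomness flows from a single
integer seed per session (`buildGroundTruth(list(seed = ...))`); identical
seeds give byte-identical session directories.

## Degenerate inputs and tie rules

* Channels exactly at the border are granular; two equal-power hotspot
  candidates resolve to the more superficial channel, as do ESA-selection
  ties.
* A flat PSD or a peak at the search boundary raises "no gamma peak" rather
  than returning an arbitrary band.
* Periods are never formed across separate above-median episodes; an empty
  cycle series is legal and excluded from pooling.
* Correlation-refinement ties (including the uniform matrix) fall back to
  the polarity-inversion border.
* Sessions below 65% behavioral performance still load and preprocess; only
  the attention contrasts are skipped and flagged.

# Known limitations

* The spline iCSD assumes zero CSD beyond the end knots; structure within
  ~2 lobes of the probe ends is attributed partly to the edge channels.
  The generator keeps its oscillators inside the span; real columns need
  probes that bracket the active laminae.
* The cycle-period frequency estimator remains amplitude-weighted: when a
  foreign rhythm is locally stronger than the domain rhythm, the median
  period follows the mixture.
* The Kuramoto coupling default is a free parameter of the generator — the
  inter-domain coherence magnitudes it produces are illustrative, not
  calibrated to any dataset.
* `attentionPhcContrast` compares exactly two conditions at the argmax
  partner electrode; it does not correct for selecting the partner on the
  attend-in data (the same selection convention as the analysis it mirrors).
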