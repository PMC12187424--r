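---
title: "Extracting the jugular venous pulse from 60 GHz FMCW radar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting the jugular venous pulse from 60 GHz FMCW radar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jvpradar)
```

## The problem

The jugular venous pulse (JVP) is the pressure waveform of the internal
jugular vein, visible at the neck. It mirrors right-atrial dynamics — the
a, c and v waves and the x and y descents of one cardiac cycle — and is a
non-invasive window on central venous pressure, whose invasive gold
standard is right-heart catheterization. `jvpradar` implements a complete,
hardware-free-testable processing chain that recovers this waveform from
the data cubes of a 60 GHz frequency-modulated continuous-wave (FMCW)
radar aimed at the skin over the vein: micrometre-scale surface
displacement modulates the phase of the radar echo, and careful phase
processing turns that modulation back into a displacement trace from which
individual venous pulses are detected.

## Signal model

An FMCW radar transmits linear frequency sweeps ("chirps") of bandwidth
$B$ and duration $T_c$. Mixing the echo of a target at range $R$ with the
transmitted sweep yields an intermediate-frequency (IF) tone at the beat
frequency

$$f_b = \frac{2 R B}{c\, T_c},$$

so a fast-time FFT of one chirp resolves range into bins of width
$c/(2B)$ (about 27 mm at $B = 5.5$ GHz). The receiver in this design has
an in-phase mixer only: the recorded IF signal is real, and complex data
arise solely through the FFT. For fast-time sample $n$, antenna $a$ and
frame $t$, the simulator generates exactly this model:

$$s_{t,a}(n) = A \cos\!\Big(2\pi f_b \frac{n}{f_s} + \frac{4\pi R(t)}{\lambda}
  + \phi_a\Big) + \text{noise},$$

with $R(t)$ the standoff plus the surface displacement,
$\lambda$ the carrier wavelength at band centre, and
$\phi_a = -2\pi d\, (a-1) \sin\alpha$ the inter-element phase of a pair
with spacing $d$ wavelengths receiving from direction $\alpha$. The phase
sign matches the steering-vector convention below, so that a source
simulated at $+\alpha$ is estimated at $+\alpha$.

The default configuration (`radar_config()`) is the one found to give the
best JVP visibility on the 58–63.5 GHz device: 128 samples/chirp at
1 MHz, 8 chirps/frame, 132.987 µs chirps, 250 Hz frame rate and the full
5.5 GHz sweep, giving $\lambda \approx 4.93$ mm at the 60.75 GHz band
centre.

## Range processing

`range_fft()` removes each chirp's mean before transforming. The DC spike
of a real-valued receiver otherwise dominates the low bins where the skin
echo lives; subtracting the chirp mean alters only bin 0. Windowing is
optional (`"hann"`), default off.

Averaging the FFT outputs across a frame's chirps reduces the noise floor
variance by the chirp count, but it also smooths slow-time detail of the
pulse. Both behaviours are implemented; the default keeps the first
chirp's spectrum (`average_chirps = FALSE`), and the averaging path is
exercised by tests that verify the expected variance reduction.

`select_target_bin()` picks the *first* local maximum of the
frame-and-antenna averaged magnitude spectrum at bin ≥ 1 that exceeds a
prominence floor — the closest obstacle is the skin, so the first spike,
not the strongest, is the echo of interest. The floor is three times the
median magnitude of the non-DC bins: a multiple of the median is robust
against noise-floor level shifts, and the factor is exposed as a
parameter. Bin indices are 0-based throughout (bin 0 = DC), following
radar convention; antenna indices are 1-based, following R convention.

The slow-time I/Q stream is simply the selected bin's complex value per
frame (`extract_iq()`). Inverse-transforming a one-bin-masked spectrum
and sampling it at a fixed fast-time index gives the same sequence up to a
constant factor, so nothing is lost by reading the bin directly.

`select_antennas()` scores each antenna by the ratio of 0.75–4 Hz power
to out-of-band power of its phase-difference signal, in dB, and keeps the
best two. One low-SNR channel entering the beamformer can destroy the
combined signal, which is why selection precedes combination.

## Eigen-beamforming

A single range bin of a nearly noise-free echo yields an almost perfectly
coherent two-channel observation, so the sample covariance

$$\hat{R} = \frac{X X^H}{N}$$

is rank one and ill-conditioned — its eigenvalue ratio blows up — and any
beamformer that inverts $\hat{R}$ is unstable. The implementation
therefore never inverts anything. With the steering vector of the
half-wavelength pair

$$A(\alpha) = \big[\,1,\; e^{-i\pi\sin\alpha}\,\big],$$

the steering vector is projected on the span of the dominant eigenvector
$e_1$ of $\hat{R}$, $A_\mathrm{proj} = e_1(e_1^H A(\alpha))$, and the
direction-of-arrival (DoA) spectrum is the quadratic form

$$\mathrm{PSD}(\alpha) = A_\mathrm{proj}^H\, \hat{R}\, A_\mathrm{proj},$$

which is real and non-negative for Hermitian positive semi-definite
$\hat{R}$; its argmax over a 1° grid in $[-90°, 90°]$ is the estimated
source angle (lowest angle on ties). The slow-time channels are combined
as $y(t) = e_1^H x(t)$ — maximal-ratio combination along the principal
signal direction.

Two conventions make this deterministic and testable. The eigenvector's
global phase is fixed so its first non-zero component is real-positive
(the decomposition's phase is otherwise arbitrary). And the covariance fed
to the beamformer is estimated on 256-sample windows (about 1 s at
250 Hz, hop 128) whose per-window covariances are averaged into a single
record-level estimate driving one eigenvector; combining with a separate
eigenvector per window would splice phase discontinuities into the very
series whose phase carries the signal.

## From phase to displacement

The I/Q constellation of a vibrating target is an arc of a circle;
DC offset and leakage translate that circle away from the origin, which
distorts the extracted phase. `fit_circle_taubin()` implements Taubin's
algebraic circular regression via an SVD of the centred design matrix.
On exact circle points the fit is exact at any scale (tested over radii
$10^{-3}$ to $10^3$); on noisy short arcs its radius bias is markedly
smaller than the plain algebraic least-squares (Kåsa) fit, which the test
suite verifies against an independently implemented Kåsa oracle. The
centre is fitted and subtracted per 256-sample block (the same window
length as the covariance estimate) so slow DC drifts are tracked; a block
whose constellation is degenerate — a static target collapses to a point —
is passed through unchanged rather than force-fitted. Exact
zero-magnitude samples abort phase extraction with the frame index;
silently interpolating a phase there could fabricate pulses.

The instantaneous phase is the unwrapped four-quadrant angle. Skin
displacement follows from the round-trip phase relation

$$d_\mathrm{skin} = \theta\,\frac{\lambda}{4\pi},$$

applied to *successive phase differences*, cumulatively summed and
mean-removed. Differencing discards the linear range-offset component of
the raw unwrapped phase, which carries no pulse information; the mean
removal replaces explicit detrending. $\lambda$ is evaluated at band
centre — the sweep spans 5.5 GHz and no single in-band frequency is
canonical, so the centre is the natural parameterization.

A known systematic of this conversion: the beat frequency itself moves
with $R(t)$, adding a small displacement-coherent phase term at an
off-bin-centre standoff (the residual video phase). At the default
geometry this inflates reconstructed amplitude by roughly 4%, well inside
the 10% round-trip tolerance the tests enforce, and it vanishes at
bin-centred standoffs.

## JVP band filtering and pulse detection

JVP component visibility lies below 4 Hz, and arterial pulsation
contaminates the band near the cardiac fundamental. The displacement
signal is therefore bandpass filtered to 0.75–4 Hz (1021-tap Hamming
window linear-phase FIR) and then bandstop filtered at 0.9–1.1 Hz
(511 taps). Filtering is causal, not zero-phase: the group-delay
transient while the delay line loads is a real property of the
measurement, and the combined group delay $(1021-1)/2 + (511-1)/2 = 765$
samples is marked as unusable at each record end. Detection operates only
between those trim bounds.

The bandstop design needed care. A 0.2 Hz-wide notch at a 250 Hz rate is
far below the frequency resolution of a 511-tap window-method design,
which would leave the notch about 1 dB deep. The implemented design is an
equality-constrained weighted least-squares fit of the symmetric (type-I)
amplitude response: unity outside the notch with a 0.45 Hz transition
band left unconstrained on each side, zero inside, with exact spectral
zeros pinned at 0.95 and 1.05 Hz. That yields ≥ 29 dB attenuation across
the whole 0.9–1.1 Hz band while leaving 1.8–4 Hz within about 0.5 dB,
at the same length and hence the same 765-sample combined delay. The
trade-off is intrinsic: a recording whose cardiac fundamental falls
inside the notch loses that line while its 1.8–4 Hz harmonics survive,
which a dedicated test asserts on generator output. The notch's
transition also partially attenuates fundamentals up to ≈ 1.5 Hz — the
price of suppressing arterial interference with a filter this short.

That transition attenuation is why the reference-pulse selector estimates
the cardiac period from the *autocorrelation* peak at physiological lags
(0.25–1.33 s) rather than from the dominant spectral line: with the
fundamental notched down, a spectral argmax locks onto a harmonic and
halves the period. Given the period, the usable recording is segmented
into consecutive cycles and the cycle with the highest mean Pearson
correlation against all others becomes the template (lowest index on
ties).

`detect_pulses()` slides the template over the usable signal and computes
the Pearson correlation (mean-removed, unit-energy) at every start.
Local maxima at or above the threshold (default 0.8; the choice of
threshold fixes how closely accepted pulses must resemble the reference)
are accepted greedily in decreasing correlation order, subject to a
minimum separation of 95% of the template length. Full-length exclusion
would be wrong in a subtle way: the true cardiac period is generally not
an integer number of samples, so successive true maxima can sit one or
two samples closer than the template length and jitter by a few samples
under noise — a strict rule then suppresses genuinely adjacent cycles.
The 5% allowance covers that jitter while keeping pulses essentially
disjoint. Raising the threshold can only remove candidates, so the
detection count is monotone non-increasing in the threshold (tested).
Each accepted pulse's maximum sample is marked as its peak.

## PPG synchronization

Radar JVP and finger photoplethysmography (PPG) are both driven by the
cardiac cycle; their spectra overlap most reliably between 0.8 and 2 Hz.
`common_frequency()` resamples the PPG from its native 273.1 Hz to the
radar frame rate by polyphase rational resampling, evaluates both
magnitude spectra on a shared zero-padded grid (0.02 Hz resolution), and
returns the argmax of their product over the band. Records shorter than
20 s are rejected — the spectral main lobes would be too wide for 0.05 Hz
discrimination — and a peak whose prominence over the in-band median
falls below a floor of 10 is flagged low-confidence, which is what
uncorrelated inputs produce.

## What the synthetic generator does and does not emulate

Everything in the package is testable without hardware because the
generator produces physically parameterized scenes:

* **JVP surface motion** (`jvp_waveform_spec()`): three positive Gaussian
  bumps (a, c, v) and two negative ones (x, y) per cycle, plus an
  arterial sinusoid at the cardiac fundamental, a respiratory sinusoid
  and white noise. The published literature gives the morphology only
  schematically and reports jugular pressure, not surface displacement,
  so the default amplitudes (60–150 µm waves, 100–130 µm descents,
  80 µm arterial, 200 µm respiratory) are plausible-but-uncalibrated
  choices at the micrometre scale radar phase can resolve. Centres
  (0.10, 0.25, 0.60 of the cycle; descents 0.18, 0.75) reproduce the
  classic biphasic pattern. Bump widths (0.13–0.16 of the cycle) were
  set once so the venous waveform satisfies the sub-4 Hz visibility
  constraint — no spectral line above 4 Hz exceeds 1% of the dominant
  line; sharper bumps violate it. The default cardiac rate is 1.13 Hz,
  the fundamental of the reference recording session that the
  synchronization stage is pinned against.
* **Speaker plate** (`speaker_signal_spec()`): the two-tone sensitivity
  fixture $a_1\cos 2\pi f_1 t + a_2\cos 2\pi f_2 t$ with $f_1 = 50$,
  $f_2 = 54$ Hz; drive amplitudes are unpublished, so the defaults are
  equal at 50 µm.
* **Scene** (`scene_spec()`): standoff, direction of arrival, echo
  amplitude, receiver SNR. The default standoff is 0.05 m rather than
  the hardware's 2 mm skin contact distance: at a 27 mm bin width a 2 mm
  target merges with the DC bin, which is precisely the known overlap
  problem of the real device; 0.05 m places the echo cleanly in a
  selectable bin so that bin selection itself is testable. The 2 mm case
  remains constructible as a degenerate configuration. Default receiver
  SNR is 30 dB per sample — a clean bench-scale echo.
* **Array**: the beamforming mathematics assumes a half-wavelength pair,
  while the hardware carries three orthogonally placed antennas. The
  simulator exposes exactly one linear pair plus a deliberately degraded
  auxiliary third channel (absolute SNR `aux_snr_db`, default 0 dB)
  whose role is to exercise the antenna-selection stage; `Inf` disables
  it.

Not modelled: electromagnetic propagation and tissue interaction (SAR /
power-density analysis belongs to full-wave simulation platforms),
multi-reflection body clutter beyond the single skin echo, posture-
and anatomy-dependent coupling (reduced to the scalar `posture_factor`),
and the real device's acquisition electronics. Passing tests on this
generator demonstrate the correctness of the processing mathematics under
the stated signal model — not robustness to real-body clutter, motion
artefacts or anatomical variability.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data
at the scales the method targets: 30 s records at 250 Hz for the
spectral-recovery and synchronization checks (the spectral resolution
arguments require them), 6–16 s records for pipeline round trips, and a
9-angle sweep of −20°…+20° in 5° steps for DoA localization. All
randomness flows through explicit integer seeds; `simulate_frames()` and
the trajectory generators restore the caller's RNG state.

## Known limitations

* The displacement amplitude calibration of the JVP generator is
  uncertain at the factor-of-a-few level; correlation-based detection is
  insensitive to it, but absolute amplitudes in metres inherit it.
* The amplitude bias from residual video phase (≈ 4% at the default
  standoff) is not compensated; bin-centred standoffs avoid it.
* The bandstop's transition attenuates cardiac fundamentals up to
  ≈ 1.5 Hz, which weakens (but does not defeat) template selection at
  common resting heart rates; the autocorrelation period estimate and
  correlation detection absorb this.
* Pulse sets may overlap by up to 5% of the template length by design
  (see the detection section).
* The real-valued mixer folds a negative-frequency image into the
  spectrum; off-bin-centre standoffs therefore leak a small conjugate
  component into the extracted I/Q, visible as constellation
  ellipticity. The circle recentring corrects the offset, not the
  ellipticity; at the default geometry the residual phase distortion is
  a few percent.
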