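# jvpradar

Non-contact extraction of the **jugular venous pulse (JVP)** from 60 GHz
frequency-modulated continuous-wave (FMCW) radar data.

The JVP — the pressure waveform of the internal jugular vein, with its a,
c, v waves and x, y descents per cardiac cycle — reflects right-atrial
dynamics and approximates central venous pressure without the
catheterization that is the invasive gold standard. A millimetre-wave
radar aimed at the skin over the vein sees that waveform as
micrometre-scale surface motion modulating the phase of its echo. This
package implements the full processing chain that turns raw radar data
cubes into detected JVP pulses, and a physically parameterized FMCW echo
simulator so every stage is testable without hardware. It is written for
signal-processing and biomedical-engineering researchers working on
contactless vital-sign monitoring.

## The method

For a target at range $R$, each chirp of bandwidth $B$ and duration $T_c$
produces an IF beat tone at $f_b = 2RB/(cT_c)$; a fast-time FFT resolves
range, the first spectral spike is the skin echo, and that bin's complex
value per frame is the slow-time I/Q signal of the surface. The stages:

1. **Range processing** — reshape the raw cube
   (frame × antenna × chirp × sample), per-chirp mean removal, fast-time
   FFT, first-peak range-bin selection, per-antenna I/Q extraction, and
   SNR-based selection of the best antenna pair.
2. **Eigen-beamforming** — the one-bin I/Q streams are nearly coherent, so
   the sample covariance $\hat R = XX^H/N$ is rank one and
   non-invertible; the beamformer uses only its dominant eigenvector
   $e_1$. With the half-wavelength steering vector
   $A(\alpha) = [1, e^{-i\pi\sin\alpha}]$, the DoA spectrum is
   $\mathrm{PSD}(\alpha) = A_\mathrm{proj}^H \hat R A_\mathrm{proj}$ with
   $A_\mathrm{proj} = e_1(e_1^H A(\alpha))$, and channels combine as
   $y(t) = e_1^H x(t)$. No matrix is ever inverted.
3. **Displacement** — Taubin SVD circular regression recentres the I/Q
   constellation; the unwrapped instantaneous phase converts to skin
   displacement via $d = \theta\,\lambda/(4\pi)$ (round-trip phase),
   applied to successive phase differences.
4. **JVP detection** — a causal 0.75–4 Hz FIR bandpass (1021 taps) plus a
   0.9–1.1 Hz bandstop (511 taps) isolate the venous band and suppress
   arterial pulsation; the combined 765-sample group delay is trimmed
   from both record ends; the most self-consistent cycle becomes a
   reference template and pulses are accepted by normalized
   cross-correlation against it.
5. **PPG synchronization** — the common cardiac line of the radar JVP and
   a finger photoplethysmogram is located in the 0.8–2 Hz overlap band
   from the product of their magnitude spectra.

The methods vignette (`vignettes/jvp-radar-methods.Rmd`) documents the
model, every tunable parameter and the design decisions in detail.

## Worked example

Simulate 30 s of a default scene (synthetic JVP at 1.13 Hz observed by
the default radar configuration) and run the whole chain:

```r
library(jvpradar)

cfg <- pipeline_config(duration = 30, seed = 42)
res <- run_pipeline(cfg)

res$selected_bin
#> [1] 2
res$antenna_selection
#> selected antennas: (1, 2); per-antenna SNR [dB]: -7.6, -7.6, -24.6
res$doa
#> DoA spectrum: peak at 0 deg (eigenvalue ratio 1.11e+05)
res$pulses
#> JVP pulses: 26 accepted at threshold 0.80 (template 221 samples)
head(res$pulses$pulses, 3)
#>   start correlation peak_index   peak_value
#> 1   985   0.9956448       1003 4.702391e-05
#> 2  1207   0.9797057       1224 4.289963e-05
#> 3  1426   0.9974015       1443 3.375740e-05
```

The skin echo is found in range bin 2 (the 0.05 m standoff at ~27 mm bin
width), the deliberately degraded third antenna is rejected, the DoA scan
peaks at the scene's true 0°, the huge eigenvalue ratio flags the
rank-one covariance the eigen-beamformer is built for, and 26 pulses of
the ~27 usable cardiac cycles are accepted with correlations near 1;
`peak_value` is the pulse amplitude in metres (tens of µm). Synchronizing
against a simultaneously generated PPG:

```r
ppg <- synth_ppg(cfg$jvp$cardiac_rate, 30, seed = 43)
common_frequency(res$displacement, ppg)
#> common frequency: 1.120 Hz (confident, prominence 2008.0)
```

1.12 Hz is the generator's 1.13 Hz cardiac fundamental at the 0.02 Hz
spectral grid.

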