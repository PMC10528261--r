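---
title: "Dynamic microwave angiography: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic microwave angiography: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mwangio` simulates and images a bench-top stand-in for arterial
imaging: a cylindrical oil–gelatin phantom with elastic hoses whose
radius is modulated pneumatically at a heartbeat-like rate, observed
by a two-ring UWB MIMO radar array. This vignette documents the
physical model, the tunable parameters, the numerical choices, and the
places where the design was genuinely open and we had to choose.

## 1. Signal model

### Static scattering

For transmitter $i$ and receiver $j$, a point scatterer $\kappa$ at
distances $r_{i\kappa}$, $r_{j\kappa}$ contributes

$$ b_{ji,\kappa}(t) = a(t) * T_i(t) *
   \frac{\delta(t - r_{i\kappa}/c)}{2\pi r_{i\kappa}} * \Lambda_\kappa(t) *
   \frac{\delta(t - r_{j\kappa}/c)}{2\pi r_{j\kappa}} * R_j(t), $$

i.e. the sounding signal $a(t)$ convolved with the transmit antenna
response, delayed and attenuated by spherical spreading on each leg,
scaled by the scatterer reflectivity, and convolved with the receive
antenna response. Angular dependence, polarization and propagation
loss beyond $1/(2\pi r)$ are deliberately neglected. The wave speed is
$c = c_0/\sqrt{\varepsilon_r}$; with the gel's $\varepsilon_r = 30$,
$c \approx 5.47\times 10^7$ m/s, so half a wavelength at the 3.25 GHz
center frequency is about 8.4 mm — the natural resolution scale of
every localization statement below.

The sounding signal is a maximal-length binary sequence. Its circular
autocorrelation is $N$ at lag zero and exactly $-1$ elsewhere, so
circular correlation of the received chip stream with the sequence
("pulse compression") returns the radar path impulse response on a
$-1/N$ pedestal. `generate_msequence()` builds the sequence from a
Fibonacci LFSR with known primitive taps for orders 2–16 and verifies
maximality at generation time (a non-primitive feedback polynomial
errors out).

### Pulsating arteries

An artery of rest radius $d_0$ driven by the sinusoidal pressure
$P = P_0 + \Delta P \cos(2\pi\nu T)$ with wall stiffness $K$ changes
radius by $\Delta d(T) = (\Delta P/K)\cos(2\pi\nu T)$. To first order
the reflectivity becomes

$$ \Lambda(t, T) \approx \Lambda_0(t) + \Delta d(T)\,\Pi(t), $$

time-variant in the *observation* time $T$ (seconds) while remaining
a fast-time ($t$, nanoseconds) impulse response. The exact functional
forms of $\Lambda_0$ and $\Pi$ for a dielectric cylinder are out of
scope here; the simulator uses a **declared point-scatterer
stand-in**: each artery is a vertical line of point scatterers (5 mm
spacing by default) with

* $\Lambda_0$ = Fresnel amplitude of the gel/fill interface,
  $(\sqrt{\varepsilon_{gel}} - \sqrt{\varepsilon_{fill}})/
   (\sqrt{\varepsilon_{gel}} + \sqrt{\varepsilon_{fill}})$:
  about $+0.69$ for air-filled and $-0.23$ for water-filled tubes;
* $\Pi = \Lambda_0 / d_0$ per metre of radius change, i.e. the echo
  strength varies in proportion to the relative radius excursion.

This keeps the first-order structure exactly while being fully
specified. Consequences worth knowing: the model is *linear* in
$\Delta d$ (the simulator exploits this by synthesizing one static and
one modulation trace per channel and spanning slow time with the
cosine — algebraically identical to simulating every slow-time sample
independently), and image values scale as $\Delta d^2$ after the
squared-magnitude beamformer. The relative amplitude relationship
between air- and water-filled scenarios is a *model input* (the
Fresnel contrast), not a prediction.

## 2. The stated world of the generator

Defaults encode the phantom experiment:

| parameter | default | why |
|---|---|---|
| phantom | 13 cm diameter × 10 cm height, $\varepsilon_r = 30$ | gel permittivity at 3.25 GHz |
| arteries | 5 mm diameter at (5,0), (0,4), (−3,0), (0,−2) cm | printed tube coordinates |
| pulsation | $\nu = 0.08$ Hz, $\Delta d = 0.15$ mm | measured excursion is below 0.2 mm |
| array | 32 antennas, rings at z = −4, −6 cm, 16 TX + 16 RX | 256 bistatic channels |
| fast time | 13 GHz chip rate, order-9 M-sequence (511 chips) | 2 × the 6.5 GHz bandwidth; 4 samples ≈ λ/2 in the gel |
| slow time | 0.8 Hz × 125 s = 100 samples | exactly 10 pulsation periods → the 0.08 Hz line falls on FFT bin 10 with zero leakage |
| antenna IRF | Gaussian-windowed 3.25 GHz pulse, 10 samples | stated impulse-response support |
| noise | off (SNR = ∞); AWGN at a configured SNR with a mandatory seed | acceptance runs are noiseless and deterministic |
| clutter | ring of 16 static scatterers at 0.85 × phantom radius | exercises background removal |

Choices the experiment did not state, fixed once here:

* **Antenna ring radius** equals the phantom radius (antennas on the
  mold wall); **TX/RX layout** alternates TX, RX, TX, … at equal
  angular spacing, with the pattern offset by one slot between the two
  rings for azimuthally uniform bistatic coverage.
* **Scenario clip table**: scenario 1 all four arteries pulsating;
  scenarios 2–5 exactly one artery clipped, cycling through arteries
  1–4; scenario 6 all pulsating, water-filled. Any subset is
  configurable via `custom_scenario()`.
* **Artery geometry**: a vertical line of scatterers through the full
  phantom height at the printed (x, y); the U-turns of the physical
  hoses beneath the bowl are outside the imaged region and ignored.
* **Stiffness/pressure units** are arbitrary; only the ratio
  $\Delta P/K = \Delta d$ matters and it is enforced by construction.

What the generator does **not** emulate — so what a green test does
not establish: full-wave (Mie-type) cylinder scattering and creeping
waves, antenna dispersion and mutual coupling, frequency-dependent
tissue permittivity, hardware timing jitter, and non-stationary
clutter such as temperature drift. Detection scores on synthetic cubes
quantify the *pipeline*, not the hardware.

## 3. Numerical choices

* **Fractional delays** are linearly interpolated on the fast-time
  grid, both when placing scatterer impulses and when the beamformer
  samples a trace at $t + \tau_v$; positions outside the record read
  zero. Linear interpolation is monotone and adequate at 13 GHz
  sampling, but it splits a Dirac between adjacent samples, which can
  modulate a compressed peak's height by a few percent depending on
  the fractional part — tests that check the $1/r^2$ closed form use
  integer-sample geometries for this reason.
* **Delay calibration.** The compressed zero-range point response
  peaks a fixed number of samples late (the combined TX/RX IRF group
  delay). This system delay is computed once per acquisition and
  carried in the cube metadata; the beamformer and M-mode add it to
  $\tau_v$. For measured data this would be a calibration constant.
* **Gating window** $w(t)$: rectangular, default 4 samples
  (≈ λ/2), centered on the zero-residual-delay sample after shifting;
  with an even length the extra sample is taken on the *earlier* side.
  Argmax locations are insensitive to lengths 4–10.
* **Slow-time FFT scaling** is forward $1/n$: a unit cosine at a bin
  frequency gives magnitude $1/2$ at its two bins, and Parseval reads
  $\sum_T |y|^2 = n \sum_F |Y|^2$.
* **$F_p$ bin selection** is nearest-bin. With the default acquisition
  the bin is exact; off-grid requests more than half a bin from any
  bin warn about leakage, and DC is refused outright (statics live
  there).
* **Background averaging** over non-whole-period records warns and
  truncates to the largest whole number of pulsation periods when
  $\nu$ is known (the cosine then averages to exactly zero).
* **Incoherent DAS** interprets "sum of absolute values" as per-channel
  magnitude *after* delay interpolation, summed, then squared. This
  makes the single-channel coherent and incoherent images identical
  and guarantees incoherent ≥ coherent voxelwise (triangle
  inequality).
* **Post-filter**: per-pixel local mean/variance over a 5 × 5
  neighborhood with *edge replication* (a constant image stays
  constant), noise power = mean local variance, Wiener gain
  $\max(\sigma^2 - \nu^2, 0)/\sigma^2$; then min-max normalization to
  [0, 1] and a power of 3. A constant image has degenerate
  normalization and is defined to map to all zeros.
* **Detection**: strict 8-neighborhood local maxima above 10% of the
  global maximum, greedily matched (globally nearest first) to truth
  positions within 10 mm — about λ/2 plus voxel-grid slack; both
  thresholds are configuration-exposed. The matched count is invariant
  under global image rescaling.
* **Ordering equivalence.** Beamforming per slow-time sample then
  FFT, versus FFT then beamforming, are algebraically identical on the
  complex path (both operators are linear); the package keeps the slow
  reference implementation as a test oracle and asserts agreement to
  1e−9 relative on small grids. The fast ordering is the production
  path purely for cost reasons.
* **Voxel size** defaults to 2 mm for desk-scale full-array runs; 1 mm
  is configurable and changes nothing but cost.

## 4. Serialization and provenance

No HDF5 bindings are available in the supported R environment, so the
cube container is an R-native `.rds` holding the same named members an
HDF5 layout would (`data`, `fast_time_s`, `slow_time_s`,
`channel_tx`, `channel_rx`, attributes), with a long-format CSV +
JSON-sidecar export for small cubes. Run configurations are JSON; every
pipeline artifact embeds an FNV-1a hash of the canonical config JSON,
and identical configurations (including the seed) reproduce
byte-identical reports.

## 5. Known limitations

* The point-scatterer reflectivity is a stand-in: absolute image
  amplitudes and air-vs-water amplitude ratios should not be read
  quantitatively.
* The phantom is small and the four arteries are 2–4.5 cm from any
  probe point, so M-mode "artery-free" controls are suppressed but not
  zero: time-domain DAS has no slow-frequency selectivity and inherits
  sidelobe cross-talk from neighboring pulsating tubes.
* Coherent DAS assumes the permittivity (hence $c$) is known exactly;
  a mismatched $c$ defocuses the image. The incoherent mode is the
  robust fallback, at lower resolution.
* Slow-time sampling at 0.8 Hz is far below realistic heart rates;
  scaling to ~1 Hz pulsation requires proportionally faster
  acquisition, which changes nothing in the algorithms but is not
  explored here.
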