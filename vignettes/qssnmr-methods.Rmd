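---
title: "Quantitative carbon-13 solid-state NMR of fat-based products: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative carbon-13 solid-state NMR of fat-based products: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qssnmr)
```

## The measurement and its model

Cocoa butter and chocolate contain triacylglycerides (TAGs) split between
a crystalline solid phase and a liquid phase. Under magic-angle spinning
with direct carbon-13 excitation and high-power proton decoupling, the
inner methylene carbons of the fatty-acid chains appear twice: a sharp
line at ~30 ppm from mobile liquid chains and a broad line at ~34.5 ppm
from rigid all-*trans* solid chains. Because both lines come from the same
carbon population, their area ratio is a chemically specific solid fat
content (SFC):

$$A_C = A_{ii} - (A_3 + A_2), \qquad
  \mathrm{SFC}(\%) = 100\,\frac{A_C}{A_C + A_i}$$

where $A_{ii}$ (38–31.7 ppm) is the solid-window area, $A_i$ (31.7–29 ppm)
the liquid inner-methylene area, and $A_3$ (27–24 ppm), $A_2$ (24–22 ppm)
are the β and ω2 chain-end methylene areas. The subtraction exists because
the liquid α (34.5 ppm) and ω3 (32 ppm) lines overlap the solid window;
each fatty-acid chain contributes exactly one CH₂ to each of α, ω3, β and
ω2, so the β + ω2 areas count the same one-per-chain population and cancel
the contamination. `corrected_solid_area()` enforces $A_C \ge 0$ strictly;
the full chain `sfc_from_spectrum()` instead clamps a small negative $A_C$
to zero with a recorded warning, because for samples with little solid the
corrected area is a small difference of noisy integrals and a negative
draw is statistically consistent with zero.

A second conflict worth recording: the prose around the corrected-area
definition could be read as subtracting from the *liquid* area. We follow
the displayed equation (subtract from $A_{ii}$); the other reading sends
the full-recovery SFC away from the generator's known truth, so it cannot
be the intended formula.

## Steady-state magnetization and acquisition schemes

Repeated excitation at flip angle $\beta$ with repetition time
$T = D_1 + AQ$ drives the longitudinal magnetization to a steady state
whose per-scan transverse signal is

$$\frac{M_{xy}}{M_0} = \frac{(1 - E)\,\sin\beta}{1 - \cos\beta\,E},
  \qquad E = e^{-T/T_1}.$$

Everything scheme-related derives from this single relation
(`mxy_steady_state()`): the Ernst angle $\cos\beta_E = E$, the
quantitation bias between signals of different $T_1$
(`relative_intensity_error()`), SNR rescaling between schemes
(`predict_snr()`, with $\sqrt{N}$ scan averaging), and the apparent SFC
under partial saturation (`predict_sfc_bias()`). Two schemes are
preloaded: `scheme_90m()` (β = 90°, D1 = 850 s, AQ = 0.05 s, 4 scans) and
`scheme_lam()` (β = 23°, D1 = 25 s, AQ = 0.05 s, 128 scans); both take
just under an hour, but the low-flip-angle scheme roughly doubles the
liquid-signal SNR while under-reading SFC by a few points because the
slow-relaxing solid line recovers less between scans. $T$ always includes
AQ, small as it is. Angles are degrees at every interface and radians
internally.

For multiexponential signals the model needs one effective $T_1$ per
signal. The default convention collapses each signal to its
amplitude-weighted mean $T_1$ (`weighted_t1()`), which is the convention
under which the worked liquid/solid intensity pairs (0.173/0.166 at
β = 10°) arise; `predict_sfc_bias(convention = "per-component")` instead
averages the recovery factor $(1-E)/(1-\cos\beta\,E)$ over components,
which is physically truer when components differ by orders of magnitude
and gives a slightly milder predicted bias (≈58.7% apparent at a true
63.1% under the LAM scheme with the dark-chocolate reference components).
Both are kept because the two conventions answer different questions:
parity with the single-T1 intensity analysis versus the better physical
estimate.

One reported intensity pair is excluded throughout: the β = 20° values
0.399/0.287 exceed the hard bound $\sin 20^\circ = 0.342$ that the
steady-state expression cannot cross, so no model evaluation can (or
should) reproduce them.

## Inversion-recovery fitting

`fit_ir()` models an inversion-recovery series as
$M(\tau) = \sum_k A_k\,(1 - 2 f e^{-\tau/T_{1k}})$ with a shared inversion
efficiency $f$ (fixed at 1 by default — an ideal 180° pulse — or fitted on
request). The amplitudes enter linearly, so the fit uses variable
projection: Levenberg–Marquardt iterates only over $\log T_1$ (and
optionally $f$) while the amplitudes are solved exactly by least squares
at each step. Eight deterministic restarts from log-spaced $T_1$ grids
shifted across the delay range make the optimum reproducible without
randomness. Candidate solutions with materially negative amplitudes are
rejected as unphysical splits.

The component count (1–3) is selected as the smallest model that an extra
component fails to improve by at least 2% in residual sum of squares,
with an absolute floor (RSS below $10^{-16}\sum y^2$ counts as exact) so
noiseless fixtures do not over-fit. Components closer than 5% in $T_1$
are merged with a warning: such pairs are not identifiable from 23
points. Reported amplitudes are normalized to sum to 1; the pre-normalization
scale is kept as an attribute. The reference parameter sets shipped in
`cocoa_t1_models()` — cocoa butter and 70%-cocoa dark chocolate, solid
and liquid methylene signals, e.g. 156 s carrying 59% of the solid signal
in cocoa butter against 0.36 s carrying 67% of the liquid — drive the
synthetic presets and the scheme comparisons. The delay protocol is 23
logarithmically spaced values from 0.01 to 1000 s (`make_tau_grid()`).

## Processing chain

* **Apodization**: multiply sample $k$ by $e^{-\pi\,LB\,t_k}$, so the
  added Lorentzian FWHM equals `LB` in Hz (the standard convention; the
  default 20 Hz matches routine practice for these samples).
* **Transform**: DFT with the first point halved and scaled by the dwell
  time, so a fully decayed, well-sampled FID approximates the continuous
  Fourier integral; a damped exponential transforms to the complex
  Lorentzian $1/(R + 2\pi i(\nu - \nu_0))$, and the tests hold the real
  part to the closed form within $10^{-6}$ of peak height. The ppm axis
  is built from the spectral width, carrier position and spectrometer
  frequency (100.5 MHz for carbon-13 at 9.4 T by default), stored
  strictly descending (downfield left, TMS = 0).
* **Phasing**: points are multiplied by
  $e^{i(\varphi_0 + \varphi_1 (\delta - \delta_{pivot})/SW)}$.
  `auto_phase()` minimizes the squared negative excursions of the real
  part over $\varphi_0$ (1° grid scan refined by golden-section search;
  $\varphi_1$ fixed at 0). Real spectra are usually phased manually; the
  automatic criterion exists so synthetic pipelines are deterministic,
  and it is scale-invariant by construction.
* **Integration**: trapezoidal on the native grid, treating the spectrum
  as piecewise linear and interpolating at window edges, which makes
  integration exactly additive over adjacent windows. Windows are
  `(high, low)` pairs, closed at the high (downfield) edge and open at
  the low edge, so the canonical 38–31.7 and 31.7–29 ppm pair never
  double-counts a grid point. No peak fitting or deconvolution is
  attempted — the method is direct area integration. Baseline modes:
  `"none"` (default) and `"offset"`, which subtracts the median intensity
  of two signal-free flanks (45–40 and 20–18 ppm); whether the original
  workflow baseline-corrected is unstated, so both are available.
* **SNR**: peak height over the standard deviation of a signal-free
  window (single-sided). The definition is not standardized in the
  source material, but every prediction the package makes depends only
  on SNR *ratios*, which are definition-invariant.

## The synthetic-sample generator

`generate_spectrum()` / `generate_fid()` render an average cocoa-butter
TAG from the fatty-acid composition 36% stearic, 33% oleic, 26% palmitic,
3% linoleic (linoleic folded into the oleic-like counts, as its lines
overlap at 130 ppm). Inner methylenes number 12, 8 and 10 per S/O/P chain,
giving $3(0.36\cdot12 + 0.26\cdot10 + 0.36\cdot8) = 29.4$ carbons per TAG
at 30 ppm; α, ω3, β and ω2 carry one carbon per chain; CH₃, allylic,
glycerol, olefinic and carboxyl lines complete the liquid spectrum. One
broad Gaussian at 34.5 ppm carries the solid-phase inner-methylene + α +
ω3 population (35.4 carbons), scaled by the preset's solid fraction while
the corresponding sharp lines scale by its complement — this reproduces
exactly the overlap that the corrected-area subtraction removes.

Choices the source material does not fix, made once and kept:

* **Linewidths**: liquid Lorentzians 20 Hz FWHM, solid Gaussian 250 Hz
  FWHM. The constraint is that the canonical windows must separate the
  phases: at 250 Hz over 99.5% of the solid line stays inside 38–31.7
  ppm, and at these widths the noiseless full-chain SFC recovery closes
  within 1 percentage point across solid fractions 0.1–0.8 (wider lines
  leak enough area across window edges to break that bookkeeping).
* **Chain-end relaxation**: the ω2/β lines stay sharp at full
  multiplicity in both phases (chain-end librational mobility persists in
  the crystal) but their steady-state attenuation is the solid-fraction-
  weighted mixture of the solid and liquid factors. This is what makes
  the $A_3 + A_2$ subtraction cancel the liquid α/ω3 overlap under *any*
  scheme, so the measured 90M−LAM SFC gap matches `predict_sfc_bias()`
  within a point; with purely liquid relaxation the cancellation would
  hold only at full recovery.
* **Sucrose**: four resolved 1-carbon Lorentzians at 103, 93, 83, 82 ppm
  (the quantification window 104–81 ppm) plus an 8-carbon cluster at
  60–75 ppm excluded from it; a single 60 s T1 stands in for sucrose's
  slow relaxation, which is why TAG/SUC output is flagged
  semiquantitative. Chocolate presets scale sucrose to nominal TAG/SUC
  ratios of 8.3 (dc70), 3.3 (mc) and 1.7 (dc40) at full recovery.
* **Solid fractions**: dc70 uses 0.631, motivated by the measured value
  for a 70%-cocoa sample; cb 0.75 and cl 0.70 are realistic tempered
  values at 23 °C; dc40 0.60, mc 0.55 (milk fat lowers SFC); melted 0;
  defatted has no aliphatic components at all.
* **Noise**: per-scan Gaussian noise in the frequency domain, calibrated
  per preset so the 30 ppm peak shows SNR ≈ 19 under the reference
  90°/4-scan acquisition; spectra accumulate as $N$ scans of signal and
  $\sqrt{N}$ of noise, so the LAM scheme realizes its predicted ≈2.2×
  SNR gain without further tuning.
* **Grid**: 32768 points over 250 ppm (axis 225 to −25 ppm), chosen so
  integral noise and discretization are negligible against the 1-point
  SFC tolerances; the digital resolution of the original experiments is
  not stated.
* **Sidebands**: `add_spinning_sidebands()` displaces a fraction of the
  centerband region by the spinning rate (29.85 ppm at 3 kHz/100.5 MHz),
  conserving total intensity exactly by shifting whole grid points; it
  warns if a (unphysically slow) spinning rate would fold sidebands into
  the 38–29 ppm quantification region.

### What the generator does and does not emulate

It reproduces the features the quantification chain is sensitive to:
line positions and phase-dependent intensities, steady-state attenuation,
scan averaging, noise level, sucrose interference, sideband placement.
It does **not** model chemical-shift anisotropy (sideband intensities are
parametric, not physical), temperature-dependent melting, probe
background, baseline roll, or pulse imperfections beyond a scalar
inversion efficiency. Passing round-trip tests therefore demonstrates the
internal consistency of the analysis chain — integration, correction,
steady-state model and fitting agree with each other and with closed
forms — not that real instrument data will be free of the artifacts the
generator omits. Real-sample quantities reported alongside the method
(SFC pairs such as 63.1/60.4, TAG/SUC ratios 8.3/3.3/1.7, Pearson r of
0.97/0.91 against the time-domain reference) depend on those instrument
details and are used here only to parameterize fixtures, never asserted
as recoverable numbers.

## Numerical notes and limitations

* Problem sizes in the shipped tests: 32768-point spectra (8192 where
  many replicates are averaged), 100-replicate noise studies for T1 and
  SFC scatter, 50-replicate SNR calibration — enough for the stated
  tolerances while keeping the suite quick.
* The merged-component rule (5% in T1) and the 2% RSS selection rule are
  identifiability guards, not statistical tests; with very noisy data
  `fit_ir()` can still prefer a smaller model than the truth.
* `estimate_snr()` returns `Inf` with a warning on noiseless input
  ("no measurable noise") rather than failing, since noiseless synthetic
  spectra are routine inputs.
* The JCAMP-DX support is deliberately minimal: `##XYPOINTS=(XY..XY)`
  written losslessly, plus the equidistant `(X++(Y..Y))` form with X/Y
  factors on read. Vendor raw directories, compressed JCAMP encodings
  (DIF/DUP/SQZ), 2-D data and absolute referencing are out of scope.
* Sucrose quantification uses one combined 104–81 ppm window by default;
  per-peak windows are configurable. The exact limits are an
  interpretation (the resolved signals sit between 103 and 82 ppm).
* The β-polymorph call is a one-class test on the solid-line apex
  (34.2–34.8 ppm, configurable): only the stable β form has a pinned
  shift here; other polymorphs are reported as unassigned rather than
  guessed.
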