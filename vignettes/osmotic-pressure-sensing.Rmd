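---
title: "Methods: liposome FRET sensing of osmotic pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liposome FRET sensing of osmotic pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmofret)
```

## The sensing principle

A liposome sensor is a roughly micron-sized unilamellar vesicle whose
semipermeable bilayer encloses two highly water-soluble dyes, a FRET donor
and acceptor at 1:1 stoichiometry, optionally together with NaCl. When the
external osmotic pressure $\Pi$ exceeds the internal one, water leaves the
vesicle, the internal dye concentration rises, the mean donor–acceptor
distance shrinks, and the FRET efficiency increases. The operational
efficiency index is the FRET ratio $R$ (in percent): the ratio of
sensitized acceptor emission to donor emission, read either from an
emission spectrum as $F_{562}/F_{520}$ (spectrofluorometer) or from the
FRET and donor channels of a confocal image as
$F_\mathrm{FRET}/F_\mathrm{donor}$. The measurand is recovered by
inverting a measured $R$–$\Pi$ calibration curve.

Two physical regularities anchor everything downstream:

* $R(\Pi)$ is monotone non-decreasing — first approximately linear, then
  progressively flatter as deflation stiffens the response;
* the intraliposomal salt load sets both the start of the sensing range
  (the sensor is osmotically turgid, and mechanically vulnerable, below
  its internal pressure) and, through ion screening of the
  donor–acceptor attraction, the initial ratio $R_0$.

## Unit conversions

`nacl_osmotic_pressure()` implements the van't Hoff law
$\Pi = i\,\varphi\,c\,R_\mathrm{gas}T$ with dissociation number $i = 2$
and osmotic coefficient $\varphi = 0.93$ by default, the standard value
near isotonic strength; with $\varphi = 1$ the physiological 154 mM would
map to 0.76 MPa rather than the conventional ≈0.7 MPa.
`osmolality_to_pressure()` converts osmometer readings with the solvent
density approximated as 1 kg/L. Mass fraction is interpreted throughout as
mass-per-volume percent (g per 100 mL) — the clinical convention under
which 0.9% NaCl is 154 mM; with a true mass-per-mass reading the printed
equivalence would not hold. Default temperature is 298.15 K (room
temperature); pass 310.15 K for incubator conditions.

## The forward response model

No functional form for $R(\Pi)$ follows from first principles, so the
forward model is deliberately phenomenological and minimal: one or more
linear segments followed, where the characterization reports saturation,
by an exponential approach to a plateau,

$$R(\Pi) = R_\mathrm{knee} + S\,\lambda\left(1 -
  e^{-(\Pi - \Pi_\mathrm{knee})/\lambda}\right), \qquad
  \Pi > \Pi_\mathrm{knee},$$

which is the simplest monotone form that is $C^1$ at the knee and
reproduces the tabulated linear-range slopes exactly. Below the intrinsic
pressure $\Pi_0$ the model returns a flat $R_0$: vesicles swell rather
than deflate there and the regime is out of scope.

Per-sensor defaults in `builtin_specs()`:

* the knee sits at the stated end of the linear range where one is given
  (0.2 MPa for Lip-DA-0, 0.15 MPa for the first segment of cLip-DA-0),
  otherwise at 2/3 of the printed upper sensing bound;
* the decay scale is $\lambda = (\Pi_\mathrm{upper} -
  \Pi_\mathrm{knee})/\ln 10$, so that the 10% slope floor used by
  `sensing_range()` closes the range exactly at the printed upper bound;
* sensors whose upper bound is open-ended (Lip-DA-0.2/0.45/0.9) are
  modeled linear over the whole domain $[\Pi_0, 1.3\ \mathrm{MPa}]$ —
  treating an unreported saturation point as absent rather than guessing
  one;
* cLip-DA-0 keeps its two tabulated linear slopes (150 then 60 %/MPa with
  the break at 0.15 MPa) and saturates beyond 0.3 MPa with
  $\lambda = 0.05$ MPa, a rapid-saturation scale chosen once for
  plausibility; its initial ratio is not tabulated anywhere, so a nominal
  $R_0 = 100\%$ is used — no slope or pressure anchor depends on it;
* the microscopy-mode sensor Lip-PEG10-DA-0.05 is anchored at its two
  confocal calibration endpoints ($R \approx 43\%$ at 0.05 MPa,
  $R \approx 80\%$ at 0.93 MPa) and interpolated linearly between them,
  the least committal monotone choice.

`mechanistic_dye_factor()` carries the deflation argument quantitatively:
with entrapped solute conserved ($cV$ constant) and the internal pressure
equilibrating to the external one, the dye concentration rises by
$\Pi_\mathrm{ext}/\Pi_0$, floored at 1. Consistent with a response slope
inversely proportional to $\Pi_0$, the product $S \cdot \Pi_0$ for the
salt-loaded library stays within a single decade (roughly 7–11 %).

## Calibration fitting and inversion

`fit_curve()` pools replicates to per-pressure means, applies isotonic
regression (monotonicity is asserted by the physics, not a fitted shape),
and interpolates the isotonic values with a monotone shape-preserving
cubic (Hyman filtering). Noiseless monotone input is therefore reproduced
exactly at the nodes. The sensitivity $\hat S$ is an ordinary
least-squares slope in an explicit user-chosen window — the
characterization does not state how its per-sensor linear windows were
chosen, so they are inputs here, not estimates.

`sensing_range()` declares saturation where the local model slope drops
below 10% of the initial slope (scanned at 1 mPa); the floor fraction is a
package convention chosen so the detected upper bounds agree with the
tabulated ones under the forward model's $\lambda$ defaults.

`invert()` uses bracketing bisection (31 halvings, i.e. well below the
10⁻⁶ MPa reporting tolerance). A ratio landing on a flat isotonic step is
resolved to the step midpoint — unbiased under symmetric noise — with the
step width reported as `ambiguous_width_MPa`. Out-of-range ratios are
clamped to the nearest range endpoint and flagged `below_range` /
`above_range`; downstream maps never report an out-of-range pressure with
an `ok` status. Spectrofluorometer- and microscopy-derived ratios are on
systematically different scales (different excitation and read-out
conventions), so curves carry an `instrument` tag and inversion refuses
cross-instrument use.

## Spectra

The spectral ratio reads single nearest grid points at 562 and 520 nm
(ties toward the lower wavelength), matching the peak-intensity definition
of $F_{562}/F_{520}$, on the 480–640 nm recording range at a 1 nm default
step. Background spectra (medium without sensors) are subtracted
pointwise; negative residuals are kept, not clamped — clamping would bias
the ratio upward — and flagged `low_signal`. The generator
`synth_spectrum()` places two Gaussian bands at 520/562 nm and solves the
acceptor amplitude in closed form so the noiseless ratio equals the target
exactly, including each band's overlap at the other read-out point; it
refuses targets that the overlap makes unrealizable.

## Synthetic confocal fields and the image-analysis chain

`synth_field()` emulates the three-channel acquisition: sub-resolution
liposomes become Gaussian point-spread blobs (default $\sigma = 2$ px) in
the donor and FRET channels, with the FRET/donor amplitude split set by
the calibration ratio at each spot's pressure; the acceptor channel is
proportional to the FRET signal and is carried but never used in
segmentation (its role in the original masking protocol is not stated, so
the mask uses only the two channels that enter $R$). Poisson photon noise,
Gaussian read noise (default sd 3 counts), rounding, and clipping to the
bit depth (default 12) follow; clipped pixels are saturated and excluded
downstream. The default background of 2 counts represents a dark confocal
background; it is small enough that the background term biases the
ROI-sum ratio by well under a percentage point at masked-pixel signal
levels.

The analysis chain mirrors the acquisition protocol: `noise_threshold()`
sets each channel's threshold one count above the brightest pixel of a
sensor-free control (the smallest representable increment, hence zero
false positives on the control by construction); `segment()` requires
both 458 nm-excitation channels above threshold and unsaturated;
`ratio_map()` computes per-pixel $100 \cdot
F_\mathrm{FRET}/F_\mathrm{donor}$; `roi_average_ratio()` computes the
ROI-sum ratio over a centered square (default 150 µm, converted by the
pixel size with floor rounding, half-open bounds), which equals the
donor-intensity-weighted mean of the pixel ratios. The ROI-sum is the
quantitative estimator: individual pixel ratios near the detection
threshold carry a small positive bias (noise in the denominator), which
is why per-pixel maps are best summarized by medians and the package's
recovery guarantees are stated for the ROI-sum.

`timelapse_monitor()` reproduces the medium-exchange protocol: per frame,
the matching cell-only background is subtracted (floored at zero), the
background frame doubles as the noise control for thresholding, and the
ROI ratio is inverted to a mean pressure at the default 21 s frame
interval. The change-point rule — first frame exceeding the running
pre-exchange median by more than 3 normal-consistent MADs, after a
5-frame baseline — is a package addition; the original observation of the
pressure step was qualitative.

## Scales used by the shipped checks

The test suite and the acceptance script generate everything they consume.
Calibration recovery runs on noiseless 8–51-point curves and on noisy
recovery at $\sigma = 2\%$ ratio noise with 100 replicates at 101
pressures per sensor, which puts the slope standard error comfortably
inside the 2% relative recovery criterion even for the shallowest sensor
(13.2 %/MPa). Imaging checks use 512 × 512 frames with 200 spots for the
anchor-recovery runs and 128–192 px frames elsewhere; synthetic fields use
0.4 µm pixels — the low-magnification monitoring scale — so the 150 µm ROI
(375 px) fits the frame, whereas at the 0.2 µm high-resolution scale it
would not.

## What the generators do and do not emulate

The synthetic data reproduce: monotone saturating calibration shapes with
the tabulated parameterizations, two-band spectra with exact target
ratios, sparse diffraction-limited spots in three detector channels with
realistic count statistics, control frames for thresholding, and stepwise
medium exchanges. They do not emulate: dye photophysics (Förster radius,
bleed-through, photobleaching), serum-lipoprotein-induced dye leakage,
cell autofluorescence or motion, focus drift, uneven illumination, or
spatial pressure gradients within a frame. Passing tests therefore
demonstrate the correctness and calibration-consistency of the analysis
chain, not robustness to those real-data effects.

## Known limitations

* The saturating branch is one admissible $C^1$ monotone form; data
  sampled only in the linear range cannot distinguish it from
  alternatives, and the open-range sensors' behavior beyond 1.3 MPa is
  unmodeled.
* Pressure-map uncertainty is limited to the inversion round-trip
  tolerance and range flags; no per-pixel error propagation is attempted.
* The outlier-exclusion step of the original pixel-mapping protocol is
  unspecified there; the package deliberately omits it rather than guess.

## A worked example

```{r example, eval = FALSE}
spec <- builtin_spec("Lip-PEG10-DA-0.05")
curve <- fit_curve(simulate_calibration(spec, seq(0.05, 1.3, by = 0.05)),
                   pi_lo = 0.05)
sc <- random_scene(200, c(512, 512), pressure = 0.35, seed = 1)
field <- synth_field(sc, curve, seed = 2, pixel_size_um = 0.4)
control <- synth_field(scene(c(512, 512), matrix(numeric(0), 0, 2)),
                       seed = 3, pixel_size_um = 0.4)
mask <- segment(field$stack, noise_threshold(control$stack))
r <- roi_average_ratio(field$stack, mask, roi_um = 150)
invert(curve, r)
```
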